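#' Variance-component score statistic for the interaction
#'
#' Quadratic-form score for \eqn{H_0\colon \tau = 0} in the model with
#' interaction coefficients \eqn{\gamma \sim N(0, \tau I_q)}:
#' \deqn{U_\tau = \tfrac12 (\tilde{Y} - \tilde{X}\hat\beta)^T \Sigma^{-1}
#'   S S^T \Sigma^{-1} (\tilde{Y} - \tilde{X}\hat\beta)}
#' evaluated at the REML estimates of the null fit. Computed as
#' \eqn{\tfrac12 \lVert S^T \Sigma^{-1} r \rVert^2} (never via the n x n
#' outer product).
#'
#' @param fit A converged `fge_null`.
#' @param S Interaction matrix (n x q), row-aligned with the fit.
#' @return Scalar `U_tau >= 0`.
#' @export
score_statistic <- function(fit, S) {
  stopifnot(inherits(fit, "fge_null"))
  S <- as.matrix(S)
  if (nrow(S) != fit$n) stop("S has ", nrow(S), " rows but the fit has n = ", fit$n)
  # Sigma^-1 (ytilde - X beta) equals P ytilde since beta is the GLS solution
  0.5 * sum(crossprod(S, fit$Py)^2)
}

#' Efficient information of the variance-component score
#'
#' Mean and efficient variance of \eqn{U_\tau} under the null, following
#' the efficient-score construction for REML nuisance variance parameters:
#' \deqn{e = \tfrac12 \mathrm{tr}(\hat{P} S S^T), \qquad
#'   I_\tau = \tfrac12 \mathrm{tr}(P S S^T P S S^T) - J^T M^{-1} J}
#' (the \eqn{\tfrac12} on the mean matches the \eqn{\tfrac12} the score
#' statistic itself carries; \eqn{E[\tfrac12 \varepsilon^T P S S^T P
#' \varepsilon] = \tfrac12 \mathrm{tr}(P S S^T)} since \eqn{P\Sigma P = P}).
#' with \eqn{J_k = \tfrac12 \mathrm{tr}(P S S^T P \Sigma_k)},
#' \eqn{M_{kl} = \tfrac12 \mathrm{tr}(P \Sigma_k P \Sigma_l)} over the
#' nuisance components \eqn{\Sigma_1 = GG^T}, \eqn{\Sigma_2 = KK^T} and,
#' when the dispersion is estimated, \eqn{\Sigma_3 = W^{-1}} (so `J` is a
#' 2-vector and `M` 2 x 2 when phi is known, 3-dimensional otherwise).
#'
#' @param fit A converged `fge_null`.
#' @param S Interaction matrix (n x q).
#' @return List with `I_tau`, `e`, and the `J` vector and `M` matrix.
#' @export
efficient_information <- function(fit, S) {
  stopifnot(inherits(fit, "fge_null"))
  S <- as.matrix(S)
  if (nrow(S) != fit$n) stop("dimension mismatch between S and fit")
  P <- null_projection(fit)
  PS <- P %*% S
  StPS <- crossprod(S, PS)            # q x q
  e <- 0.5 * sum(diag(StPS))
  Itt <- 0.5 * sum(StPS * t(StPS))    # 1/2 tr((S'PS)^2) = 1/2 tr(PSS'PSS')
  comps <- names(fit$pi)
  k <- length(comps)
  J <- numeric(k)
  M <- matrix(0, k, k, dimnames = list(comps, comps))
  # P Sigma_k applied where needed; exploit tr(P SS' P Sigma_k) = tr(S'P Sigma_k P S)
  PC <- lapply(comps, function(nm) comp_mult(fit$state, nm, P))  # Sigma_k P (sym)
  for (a in seq_len(k)) {
    J[a] <- 0.5 * sum(PS * (comp_mult(fit$state, comps[a], PS)))
    for (b in a:k) {
      # tr(P Sigma_a P Sigma_b) = sum over elements of (Sigma_a P) * (Sigma_b P)'
      M[a, b] <- M[b, a] <- 0.5 * sum(PC[[a]] * t(PC[[b]]))
    }
  }
  Minv_J <- tryCatch(solve(M, J), error = function(e2) {
    warning("nuisance information matrix numerically singular; using pseudo-inverse")
    drop(MASS_ginv(M) %*% J)
  })
  I_tau <- Itt - sum(J * Minv_J)
  if (I_tau <= 0) {
    stop("efficient information is non-positive (", format(I_tau),
         "); the null model appears misfit")
  }
  list(I_tau = I_tau, e = e, J = J, M = M)
}

# Moore-Penrose pseudo-inverse via eigendecomposition (symmetric input)
MASS_ginv <- function(m, tol = 1e-10) {
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  pos <- es$values > tol * max(abs(es$values))
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  es$vectors[, pos, drop = FALSE] %*%
    (t(es$vectors[, pos, drop = FALSE]) / es$values[pos])
}

#' Satterthwaite scaled chi-square calibration
#'
#' Matches the first two moments of \eqn{U_\tau} to \eqn{\kappa \chi^2_\xi}:
#' \eqn{\kappa = I_\tau / (2e)}, \eqn{\xi = 2 e^2 / I_\tau}, and returns the
#' upper-tail p-value \eqn{P(\chi^2_\xi > U_\tau/\kappa)} (\eqn{\xi} may be
#' non-integer).
#'
#' @param U_tau Score statistic.
#' @param I_tau Efficient information (variance of the score).
#' @param e Mean of the score, \eqn{\tfrac12 \mathrm{tr}(\hat{P} S S^T)}.
#' @return List with `kappa`, `xi`, `p_value`.
#' @export
satterthwaite_pvalue <- function(U_tau, I_tau, e) {
  if (e <= 0) stop("trace term e must be positive")
  if (I_tau <= 0) stop("efficient information must be positive")
  kappa <- I_tau / (2 * e)
  xi <- 2 * e^2 / I_tau
  p <- stats::pchisq(U_tau / kappa, df = xi, lower.tail = FALSE)
  list(kappa = kappa, xi = xi, p_value = p)
}

#' Gene-based variance-component test of SNP-set x environment interaction
#'
#' Fits the null GLMM (random SNP main effects + kinship random effect),
#' computes the variance-component score statistic for the interaction
#' variance \eqn{\tau}, its efficient information, and the Satterthwaite
#' scaled chi-square p-value.
#'
#' @param design A `fge_design`.
#' @param kin A `fge_kinship` aligned with the design.
#' @param fam A `fge_family`.
#' @param control A `fge_control`.
#' @param fit Optionally, a pre-computed null fit (to share one fit across
#'   several tests).
#' @return A `fge_vct` with `U_tau`, `e`, `I_tau`, `kappa`, `xi`,
#'   `p_value`, `lambda_hat`, and the underlying `fit`.
#' @export
vct <- function(design, kin, fam = fge_family("binomial"),
                control = fit_control(), fit = NULL) {
  if (is.null(fit)) fit <- fit_null(design, kin, fam, control)
  S <- design$S
  U <- score_statistic(fit, S)
  info <- efficient_information(fit, S)
  sat <- satterthwaite_pvalue(U, info$I_tau, info$e)
  # moment-matching identities, asserted on every result
  stopifnot(abs(sat$kappa * sat$xi - info$e) <= 1e-8 * max(1, abs(info$e)),
            abs(2 * sat$kappa^2 * sat$xi - info$I_tau) <=
              1e-8 * max(1, abs(info$I_tau)))
  structure(list(U_tau = U, e = info$e, I_tau = info$I_tau,
                 kappa = sat$kappa, xi = sat$xi, p_value = sat$p_value,
                 lambda_hat = fit$lambda, pi = fit$pi, n = fit$n,
                 q = ncol(design$G), fit = fit),
            class = "fge_vct")
}

#' @export
print.fge_vct <- function(x, ...) {
  cat("Variance-component interaction test (n = ", x$n, ", q = ", x$q, ")\n",
      sep = "")
  cat("  U_tau = ", signif(x$U_tau, 5), ", kappa = ", signif(x$kappa, 5),
      ", xi = ", signif(x$xi, 4), "\n", sep = "")
  cat("  p-value = ", format.pval(x$p_value, digits = 4),
      "   (ridge penalty lambda = ", signif(x$lambda_hat, 4), ")\n", sep = "")
  invisible(x)
}
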