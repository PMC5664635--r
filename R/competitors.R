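#' Fixed-effect q-DF score test of the interaction
#'
#' Treats the interaction coefficients \eqn{\gamma} as fixed and tests
#' \eqn{H_0\colon \gamma = 0} with the multivariate score
#' \eqn{U_\gamma = S^T \Sigma^{-1}(\tilde{Y} - \tilde{X}\hat\beta)},
#' efficient variance \eqn{V = S^T P S}, and statistic
#' \eqn{U_\gamma^T V^{-1} U_\gamma \sim \chi^2_{\mathrm{rank}(V)}} under
#' the null. Rank deficiency of `V` (e.g. constant interaction columns) is
#' handled by a pseudo-inverse with rank-adjusted degrees of freedom.
#'
#' @param fit A converged `fge_null`.
#' @param S Interaction matrix (n x q).
#' @return A `fge_competitor` with `statistic`, `df`, `p_value`.
#' @export
fixed_score_test <- function(fit, S) {
  stopifnot(inherits(fit, "fge_null"))
  S <- as.matrix(S)
  if (nrow(S) != fit$n) stop("dimension mismatch between S and fit")
  U <- drop(crossprod(S, fit$Py))
  P <- null_projection(fit)
  V <- crossprod(S, P %*% S)
  es <- eigen((V + t(V)) / 2, symmetric = TRUE)
  pos <- es$values > 1e-10 * max(abs(es$values), .Machine$double.eps)
  df <- sum(pos)
  if (df == 0L) stop("interaction variance matrix has rank 0")
  z <- crossprod(es$vectors[, pos, drop = FALSE], U)
  stat <- sum(z^2 / es$values[pos])
  structure(list(test_name = "score_qdf", statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)),
            class = "fge_competitor")
}

#' Effective number of independent SNPs
#'
#' Eigenvalue-based correction: the number of principal components of the
#' SNP correlation matrix needed to reach 99.5% of the total variation.
#' Monomorphic (zero-variance) SNPs are dropped before the correlation is
#' computed; for mutually independent SNPs the result is (approximately)
#' the number of SNPs.
#'
#' @param G Genotype dosage matrix (individuals x SNPs).
#' @param threshold Cumulative-variance threshold (default 0.995).
#' @return Integer `M_eff` in `[1, q]`.
#' @export
effective_snp_number <- function(G, threshold = 0.995) {
  G <- as.matrix(G)
  if (ncol(G) < 1L) stop("at least one SNP required")
  v <- apply(G, 2, stats::var, na.rm = TRUE)
  keep <- which(v > 0)
  if (!length(keep)) stop("all SNPs are monomorphic")
  if (length(keep) == 1L) return(1L)
  R <- stats::cor(G[, keep, drop = FALSE], use = "pairwise.complete.obs")
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  which(cumsum(ev) / sum(ev) >= threshold)[1]
}

#' MinP single-SNP interaction scan
#'
#' For each SNP the GLMM is refit with that SNP's dosage and its
#' interaction with the exposure as fixed effects (kinship random effect
#' retained; no random SNP-set term), and the interaction coefficient is
#' tested. The minimum p-value across SNPs is adjusted by the effective
#' number of independent SNPs: `p_adj = min(1, min_p * M_eff)`.
#'
#' @param design A `fge_design`.
#' @param kin A `fge_kinship`.
#' @param fam A `fge_family`.
#' @param control A `fge_control`.
#' @param method `"wald"` (default; one fit per SNP) or `"score"` (score
#'   test of the interaction column from the fit without it).
#' @return A `fge_competitor` with `raw_min_p`, `M_eff`, adjusted
#'   `p_value` and the per-SNP table `per_snp`.
#' @export
minp_test <- function(design, kin, fam = fge_family("binomial"),
                      control = fit_control(), method = c("wald", "score")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "fge_design"))
  G <- design$G
  v <- apply(G, 2, stats::var)
  keep <- which(v > 0)
  if (!length(keep)) stop("all SNPs are monomorphic")
  TwoPhi <- kinship_matrix(kin, "twophi")
  sizes <- vapply(kin$blocks, function(b) length(b$ids), integer(1))
  blocks <- split(seq_len(nrow(TwoPhi)), rep(seq_along(sizes), sizes))
  pvals <- rep(NA_real_, length(keep))
  names(pvals) <- colnames(G)[keep]
  for (i in seq_along(keep)) {
    j <- keep[i]
    gj <- G[, j]
    sj <- design$S[, j]
    pvals[i] <- tryCatch({
      if (method == "wald") {
        Xt <- cbind(design$Xtilde, snp = gj, snp_e = sj)
        fit <- fit_null_work(design$Y, Xt, NULL, TwoPhi, fam, control,
                             blocks = blocks)
        # Wald test of the interaction coefficient from the working GLS
        covb <- chol2inv(fit$chX)
        z2 <- fit$beta[["snp_e"]]^2 / covb[ncol(Xt), ncol(Xt)]
        stats::pchisq(z2, df = 1, lower.tail = FALSE)
      } else {
        Xt <- cbind(design$Xtilde, snp = gj)
        fit <- fit_null_work(design$Y, Xt, NULL, TwoPhi, fam, control,
                             blocks = blocks)
        fixed_score_test(fit, matrix(sj, ncol = 1))$p_value
      }
    }, error = function(e) {
      warning("single-SNP fit failed for ", colnames(G)[j], ": ",
              conditionMessage(e))
      NA_real_
    })
  }
  ok <- !is.na(pvals)
  if (!any(ok)) stop("all single-SNP fits failed")
  M_eff <- effective_snp_number(G[, keep, drop = FALSE])
  raw <- min(pvals[ok])
  structure(list(test_name = "minp", raw_min_p = raw, M_eff = M_eff,
                 p_value = min(1, raw * M_eff),
                 per_snp = data.frame(snp = names(pvals), p_value = pvals,
                                      row.names = NULL)),
            class = "fge_competitor")
}

#' @export
print.fge_competitor <- function(x, ...) {
  if (x$test_name == "score_qdf") {
    cat("Fixed-effect score test: statistic = ", signif(x$statistic, 5),
        ", df = ", x$df, ", p = ", format.pval(x$p_value, digits = 4),
        "\n", sep = "")
  } else {
    cat("MinP single-SNP scan: min p = ", format.pval(x$raw_min_p, digits = 4),
        ", M_eff = ", x$M_eff, ", adjusted p = ",
        format.pval(x$p_value, digits = 4), "\n", sep = "")
  }
  invisible(x)
}
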