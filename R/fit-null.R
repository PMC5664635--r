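#' Control parameters for the null-model fit
#'
#' @param max_iter Maximum outer (PQL) iterations.
#' @param tol Convergence tolerance: relative change of every variance
#'   component and absolute change of every fixed effect must fall below it.
#' @param init_variance Starting value for both variance components.
#' @param max_halvings Step-halvings allowed per REML update.
#' @param on_nonconvergence `"error"` (default) or `"warn"`.
#' @param verbose Print the iteration trajectory.
#' @return A `fge_control` list.
#' @export
fit_control <- function(max_iter = 200, tol = 1e-5, init_variance = 0.1,
                        max_halvings = 10, on_nonconvergence = c("error", "warn"),
                        verbose = FALSE) {
  structure(list(max_iter = max_iter, tol = tol,
                 init_variance = init_variance, max_halvings = max_halvings,
                 on_nonconvergence = match.arg(on_nonconvergence),
                 verbose = verbose),
            class = "fge_control")
}

chol_solve <- function(ch, b) backsolve(ch, backsolve(ch, b, transpose = TRUE))

# ---- dense Sigma machinery (finalization and downstream tests) --------------
# state: list(GGt (or NULL), TwoPhi, winv, phi_fixed (NULL if phi estimated))
# pi: named vector over active components c(sigma2_theta?, sigma2, phi?)

build_sigma <- function(pi, state) {
  Sig <- pi[["sigma2"]] * state$TwoPhi
  if (!is.null(state$GGt)) Sig <- Sig + pi[["sigma2_theta"]] * state$GGt
  phi <- if (is.null(state$phi_fixed)) pi[["phi"]] else state$phi_fixed
  diag(Sig) <- diag(Sig) + phi * state$winv
  Sig
}

# Full dense decomposition pieces at pi for the current working model.
sigma_pieces <- function(pi, state, Xt, yt) {
  Sig <- build_sigma(pi, state)
  cholS <- chol(Sig)
  Sigi <- chol2inv(cholS)
  SigiX <- Sigi %*% Xt
  XtSX <- crossprod(Xt, SigiX)
  chX <- chol(XtSX)
  Sigiy <- drop(Sigi %*% yt)
  beta <- drop(chol_solve(chX, crossprod(Xt, Sigiy)))
  names(beta) <- colnames(Xt)
  Py <- Sigiy - drop(SigiX %*% beta)
  ll <- -0.5 * (2 * sum(log(diag(cholS))) + 2 * sum(log(diag(chX))) +
                  sum(yt * Py))
  list(pi = pi, Sig = Sig, cholS = cholS, Sigi = Sigi, SigiX = SigiX,
       XtSX = XtSX, chX = chX, beta = beta, Py = Py, ll = ll)
}

# multiply component k of Sigma by columns v (dense state)
comp_mult <- function(state, name, v) {
  switch(name,
         sigma2_theta = state$GGt %*% v,
         sigma2 = state$TwoPhi %*% v,
         phi = state$winv * v)
}

# ---- blockwise Sigma machinery (iteration engine) ---------------------------
# Exploits Sigma = A + sigma2_theta G G' with A = sigma2 * 2Phi + phi W^-1
# block-diagonal over families (Woodbury identity, rank-q correction).
# istate: list(G, q, idxs (list of row-index vectors), phiblocks (list of
#   per-family 2Phi), winv, phi_fixed)

make_istate <- function(G, TwoPhi, blocks, winv, phi_fixed) {
  if (is.null(blocks)) blocks <- list(seq_len(nrow(TwoPhi)))
  phiblocks <- lapply(blocks, function(ix) TwoPhi[ix, ix, drop = FALSE])
  list(G = G, q = if (is.null(G)) 0L else ncol(G), idxs = blocks,
       phiblocks = phiblocks, winv = winv, phi_fixed = phi_fixed)
}

# blockwise 2Phi %*% B
phimult <- function(istate, B) {
  B <- as.matrix(B)
  out <- matrix(0, nrow(B), ncol(B))
  for (f in seq_along(istate$idxs)) {
    ix <- istate$idxs[[f]]
    out[ix, ] <- istate$phiblocks[[f]] %*% B[ix, , drop = FALSE]
  }
  out
}

# component-matrix multiply in blockwise form
icomp_mult <- function(istate, name, v) {
  switch(name,
         sigma2_theta = istate$G %*% crossprod(istate$G, v),
         sigma2 = phimult(istate, v),
         phi = istate$winv * v)
}

# Decomposition pieces at pi; `full = FALSE` computes only the REML
# log-likelihood (used during step-halving).
iops_build <- function(pi, istate, Xt, yt, full = TRUE) {
  s2 <- pi[["sigma2"]]
  phi <- if (is.null(istate$phi_fixed)) pi[["phi"]] else istate$phi_fixed
  have_g <- istate$q > 0L
  s2t <- if (have_g) pi[["sigma2_theta"]] else 0
  n <- length(yt)
  p <- ncol(Xt)
  q <- istate$q
  B <- cbind(Xt, yt, istate$G)            # solve A^-1 against everything at once
  AB <- matrix(0, n, ncol(B))
  diagAinv <- numeric(n)
  trA_phi <- 0
  logdetA <- 0
  for (f in seq_along(istate$idxs)) {
    ix <- istate$idxs[[f]]
    Af <- s2 * istate$phiblocks[[f]]
    diag(Af) <- diag(Af) + phi * istate$winv[ix]
    chf <- chol(Af)
    Ainvf <- chol2inv(chf)
    logdetA <- logdetA + 2 * sum(log(diag(chf)))
    AB[ix, ] <- Ainvf %*% B[ix, , drop = FALSE]
    if (full) {
      diagAinv[ix] <- diag(Ainvf)
      trA_phi <- trA_phi + sum(Ainvf * istate$phiblocks[[f]])
    }
  }
  AX <- AB[, seq_len(p), drop = FALSE]
  Ay <- AB[, p + 1L]
  if (have_g) {
    AG <- AB[, p + 1L + seq_len(q), drop = FALSE]
    Cq <- diag(1 / s2t, q) + crossprod(istate$G, AG)
    Rc <- chol(Cq)
    logdetS <- logdetA + 2 * sum(log(diag(Rc))) + q * log(s2t)
    solve_sigma <- function(v, Av = NULL) {
      if (is.null(Av)) {
        Av <- matrix(0, NROW(v), NCOL(v))
        v <- as.matrix(v)
        for (f in seq_along(istate$idxs)) {
          ix <- istate$idxs[[f]]
          Af <- s2 * istate$phiblocks[[f]]
          diag(Af) <- diag(Af) + phi * istate$winv[ix]
          Av[ix, ] <- solve(Af, v[ix, , drop = FALSE])
        }
      }
      Av - AG %*% chol_solve(Rc, crossprod(istate$G, Av))
    }
  } else {
    AG <- Rc <- NULL
    logdetS <- logdetA
    solve_sigma <- function(v, Av = NULL) {
      if (!is.null(Av)) return(Av)
      v <- as.matrix(v)
      Av <- matrix(0, NROW(v), NCOL(v))
      for (f in seq_along(istate$idxs)) {
        ix <- istate$idxs[[f]]
        Af <- s2 * istate$phiblocks[[f]]
        diag(Af) <- diag(Af) + phi * istate$winv[ix]
        Av[ix, ] <- solve(Af, v[ix, , drop = FALSE])
      }
      Av
    }
  }
  SigiX <- solve_sigma(Xt, AX)
  Sigiy <- drop(solve_sigma(yt, matrix(Ay, ncol = 1)))
  XtSX <- crossprod(Xt, SigiX)
  chX <- chol(XtSX)
  beta <- drop(chol_solve(chX, crossprod(Xt, Sigiy)))
  names(beta) <- colnames(Xt)
  Py <- Sigiy - drop(SigiX %*% beta)
  ll <- -0.5 * (logdetS + 2 * sum(log(diag(chX))) + sum(yt * Py))
  out <- list(pi = pi, phi = phi, ll = ll, beta = beta, Py = Py,
              SigiX = SigiX, chX = chX, solve_sigma = solve_sigma)
  if (full) {
    out$SigiG <- if (have_g) solve_sigma(istate$G, AG) else NULL
    out$trA_phi <- trA_phi
    out$AG <- AG
    out$Rc <- Rc
    out$diagAinv <- diagAinv
  }
  out
}

# tr(Sigma^-1 %*% Sigma_k) from blockwise pieces
itr_sigi <- function(istate, name, ops) {
  switch(name,
    sigma2_theta = sum(istate$G * ops$SigiG),
    sigma2 = {
      tr <- ops$trA_phi
      if (istate$q > 0L) {
        M2 <- crossprod(ops$AG, phimult(istate, ops$AG))
        tr <- tr - sum(diag(as.matrix(chol_solve(ops$Rc, M2))))
      }
      tr
    },
    phi = {
      d <- ops$diagAinv
      if (istate$q > 0L) {
        AGR <- t(backsolve(ops$Rc, t(ops$AG), transpose = TRUE))  # AG Rc^-1
        d <- d - rowSums(AGR^2)
      }
      sum(d * istate$winv)
    })
}

# tr(P %*% Sigma_k) from blockwise pieces
itr_p <- function(istate, name, ops) {
  CX <- icomp_mult(istate, name, ops$SigiX)
  itr_sigi(istate, name, ops) -
    sum(diag(as.matrix(chol_solve(ops$chX, crossprod(ops$SigiX, CX)))))
}

# One AI-REML update with step-halving; returns new pi (possibly unchanged).
ai_reml_step <- function(pi, istate, Xt, yt, ops, lb, max_halvings) {
  comps <- names(pi)
  k <- length(comps)
  u <- vapply(comps, function(nm) drop(icomp_mult(istate, nm, ops$Py)),
              numeric(length(ops$Py)))
  Su <- ops$solve_sigma(u)
  Pu <- Su - ops$SigiX %*% chol_solve(ops$chX, crossprod(ops$SigiX, u))
  grad <- vapply(seq_len(k), function(j) {
    -0.5 * (itr_p(istate, comps[j], ops) - sum(ops$Py * u[, j]))
  }, numeric(1))
  AI <- 0.5 * crossprod(u, Pu)
  AI <- (AI + t(AI)) / 2
  delta <- tryCatch(solve(AI, grad), error = function(e) grad / pmax(diag(AI), 1e-8))
  if (any(!is.finite(delta))) delta <- grad / pmax(diag(AI), 1e-8)
  # small interior steps are accepted outright (the AI direction is an
  # ascent direction); only large proposals pay for a likelihood check
  if (all(pi + delta > lb) && max(abs(delta) / (abs(pi) + 1e-3)) < 0.5) {
    return(pi + delta)
  }
  ll0 <- ops$ll
  for (h in seq_len(max_halvings)) {
    cand <- pmax(pi + delta, lb)
    cll <- tryCatch(iops_build(cand, istate, Xt, yt, full = FALSE)$ll,
                    error = function(e) -Inf)
    if (cll >= ll0 - 1e-10) return(cand)
    delta <- delta / 2
  }
  pi
}

# ---- the fitter -------------------------------------------------------------

#' Fit the null GLMM by PQL with REML variance components
#'
#' Fits \eqn{g(\mu) = \tilde{X}\beta + d_1 + d_2} where
#' \eqn{d_1 = G\theta} with \eqn{\theta \sim N(0, \sigma_\theta^2 I_q)}
#' (random SNP main effects, equivalent to a ridge penalty
#' \eqn{\lambda = \phi/\sigma_\theta^2} on \eqn{\theta}) and
#' \eqn{d_2 = Kb} with \eqn{b \sim N(0, \sigma^2 I_n)} (kinship-structured
#' family effect, \eqn{KK^T = 2\Phi}). Each outer iteration linearises the
#' response (working vector \eqn{\tilde{Y}} and weights \eqn{W}), updates
#' \eqn{\beta} and the BLUPs at the current variance components, and takes
#' one average-information REML step with step-halving on the variance
#' components; iteration continues to joint convergence. The covariance
#' \eqn{\Sigma = \sigma_\theta^2 GG^T + \sigma^2 KK^T + \phi W^{-1}} is
#' handled through its family-block-diagonal part plus a rank-q Woodbury
#' correction; dense \eqn{\Sigma^{-1}} and projection matrices are
#' materialised once at convergence for the score tests.
#'
#' @param design A `fge_design`.
#' @param kin A `fge_kinship` row-aligned with the design.
#' @param fam A `fge_family`.
#' @param control A `fge_control`.
#' @param random_snps If `FALSE`, drop the random SNP main-effect term
#'   (used by single-SNP fits where the main effect is a fixed covariate).
#' @return A `fge_null` fit with fixed effects `beta`, variance components
#'   `pi` (`sigma2_theta`, `sigma2` and, for gaussian, `phi`), the implied
#'   ridge penalty `lambda`, working quantities, and the matrices needed by
#'   the downstream tests.
#' @export
fit_null <- function(design, kin, fam = fge_family("binomial"),
                     control = fit_control(), random_snps = TRUE) {
  stopifnot(inherits(design, "fge_design"), inherits(kin, "fge_kinship"))
  if (!identical(paste(design$ids$fid, design$ids$iid),
                 paste(kin$ids$fid, kin$ids$iid))) {
    stop("design and kinship structure are not row-aligned")
  }
  TwoPhi <- kinship_matrix(kin, "twophi")
  sizes <- vapply(kin$blocks, function(b) length(b$ids), integer(1))
  blocks <- split(seq_len(nrow(TwoPhi)), rep(seq_along(sizes), sizes))
  fit <- fit_null_work(design$Y, design$Xtilde,
                       if (random_snps) design$G else NULL,
                       TwoPhi, fam, control, blocks = blocks)
  fit$design <- design
  fit$kin <- kin
  fit
}

# Workhorse on raw matrices; G may be NULL (no random SNP term); `blocks`
# is an optional list of row-index vectors delimiting the diagonal blocks
# of TwoPhi (one block spanning everything when NULL).
fit_null_work <- function(Y, Xt, G, TwoPhi, fam, control, blocks = NULL) {
  n <- length(Y)
  p <- ncol(Xt)
  if (n <= p + 2) stop("too few observations (n <= p + 2)")
  if (fam$family == "binomial") {
    if (!all(Y %in% c(0, 1))) stop("binomial response must be 0/1")
    if (length(unique(Y)) < 2L) {
      stop("degenerate response: all phenotypes identical")
    }
  }
  q <- if (is.null(G)) 0L else ncol(G)
  have_g <- q > 0L

  # initial fixed-effects-only GLM
  glm_fam <- if (fam$family == "binomial") stats::binomial() else stats::gaussian()
  fit0 <- suppressWarnings(stats::glm.fit(Xt, Y, family = glm_fam))
  beta <- fit0$coefficients
  beta[is.na(beta)] <- 0
  eta <- drop(Xt %*% beta)
  mu <- fam$clip(fam$linkinv(eta))

  comps <- c(if (have_g) "sigma2_theta", "sigma2",
             if (!fam$phi_known) "phi")
  pi <- stats::setNames(rep(control$init_variance, length(comps)), comps)
  if (!fam$phi_known) pi[["phi"]] <- max(stats::var(Y - mu), 1e-3)

  phi_fixed <- if (fam$phi_known) fam$phi else NULL
  traj <- list()
  converged <- FALSE
  at_bound_count <- stats::setNames(rep(0L, length(comps)), comps)
  bound_warned <- FALSE
  w <- yt <- NULL

  for (it in seq_len(control$max_iter)) {
    w <- working_weights(mu, fam)
    yt <- working_response(eta, Y, fam)
    lb <- 1e-8 * stats::var(yt)
    istate <- make_istate(G, TwoPhi, blocks, 1 / w, phi_fixed)
    ops <- iops_build(pi, istate, Xt, yt)

    # beta / BLUP update at current pi
    beta_new <- ops$beta
    d1 <- if (have_g) pi[["sigma2_theta"]] *
      drop(G %*% crossprod(G, ops$Py)) else 0
    d2 <- pi[["sigma2"]] * drop(phimult(istate, ops$Py))
    eta <- drop(Xt %*% beta_new) + d1 + d2
    mu <- fam$clip(fam$linkinv(eta))

    # variance-component update
    pi_new <- ai_reml_step(pi, istate, Xt, yt, ops, lb, control$max_halvings)

    at_b <- pi_new <= lb * (1 + 1e-12)
    at_bound_count <- ifelse(at_b, at_bound_count + 1L, 0L)
    if (!bound_warned && any(at_bound_count >= 3L)) {
      warning("variance component(s) ",
              paste(comps[at_bound_count >= 3L], collapse = ", "),
              " pinned at the lower bound; reported as effectively zero")
      bound_warned <- TRUE
    }

    dpi <- max(abs(pi_new - pi) / pmax(abs(pi), 1e-4))
    dbeta <- max(abs(beta_new - beta))
    traj[[it]] <- c(pi_new, dbeta = dbeta)
    if (control$verbose) {
      message("iter ", it, ": pi = ", paste(signif(pi_new, 5), collapse = " "),
              ", max|dbeta| = ", signif(dbeta, 3))
    }
    beta <- beta_new
    pi <- pi_new
    if (dpi < control$tol && dbeta < control$tol) {
      converged <- TRUE
      break
    }
  }

  if (!converged) {
    msg <- paste0("PQL did not converge in ", control$max_iter, " iterations")
    if (control$on_nonconvergence == "error") {
      cond <- structure(class = c("fge_convergence_error", "error", "condition"),
                        list(message = msg, call = sys.call(-1),
                             trajectory = do.call(rbind, traj)))
      stop(cond)
    }
    warning(msg)
  }

  # final consistent dense pieces at the converged (pi, working model)
  w <- working_weights(mu, fam)
  yt <- working_response(eta, Y, fam)
  state <- list(GGt = if (have_g) tcrossprod(G) else NULL, TwoPhi = TwoPhi,
                winv = 1 / w, phi_fixed = phi_fixed)
  pieces <- sigma_pieces(pi, state, Xt, yt)
  beta <- pieces$beta
  phi_hat <- if (fam$phi_known) fam$phi else pi[["phi"]]

  out <- list(
    beta = beta,
    pi = pi,
    phi = phi_hat,
    lambda = if (have_g) phi_hat / pi[["sigma2_theta"]] else NA_real_,
    ytilde = yt, w = w, eta = eta, mu = mu,
    residuals = yt - drop(Xt %*% beta),
    Py = pieces$Py,
    Sigi = pieces$Sigi, SigiX = pieces$SigiX, chX = pieces$chX,
    Xtilde = Xt, G = G, GGt = state$GGt, TwoPhi = TwoPhi,
    state = state,
    family = fam,
    n = n, q = q,
    converged = converged, iter = it,
    trajectory = do.call(rbind, traj))
  class(out) <- "fge_null"
  out
}

#' Materialize the REML projection matrix P
#'
#' \eqn{P = \Sigma^{-1} - \Sigma^{-1}\tilde{X}
#'   (\tilde{X}^T\Sigma^{-1}\tilde{X})^{-1}\tilde{X}^T\Sigma^{-1}}
#' at the fitted variance components.
#'
#' @param fit A `fge_null`.
#' @return Dense n x n matrix.
#' @export
null_projection <- function(fit) {
  stopifnot(inherits(fit, "fge_null"))
  fit$Sigi - fit$SigiX %*% chol_solve(fit$chX, t(fit$SigiX))
}

#' @export
print.fge_null <- function(x, ...) {
  cat("Null GLMM fit (", x$family$family, "): n = ", x$n, ", q = ", x$q,
      " random SNP effects\n", sep = "")
  cat("  variance components:",
      paste(names(x$pi), "=", signif(x$pi, 4), collapse = ", "), "\n")
  if (!is.na(x$lambda)) {
    cat("  implied ridge penalty lambda = phi/sigma2_theta =",
        signif(x$lambda, 4), "\n")
  }
  cat("  converged:", x$converged, "in", x$iter, "iterations\n")
  invisible(x)
}
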