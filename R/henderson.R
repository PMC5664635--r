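#' Solve the mixed-model (Henderson) equations of the working LMM
#'
#' Solves the joint system for the fixed effects and the random-effect
#' coefficients of the working model
#' \eqn{\tilde{Y} = \tilde{X}\beta + G\theta + Kb + \varepsilon},
#' \eqn{\theta \sim N(0, \sigma_\theta^2 I_q)},
#' \eqn{b \sim N(0, \sigma^2 I_n)},
#' \eqn{\varepsilon \sim N(0, \phi W^{-1})}:
#' \deqn{\begin{pmatrix}
#'   \tilde{X}^T W \tilde{X} & \tilde{X}^T W G & \tilde{X}^T W K \\
#'   G^T W \tilde{X} & G^T W G + (\phi/\sigma_\theta^2) I_q & G^T W K \\
#'   K^T W \tilde{X} & K^T W G & K^T W K + (\phi/\sigma^2) I_n
#' \end{pmatrix}
#' \begin{pmatrix}\beta\\ \theta\\ b\end{pmatrix} =
#' \begin{pmatrix}\tilde{X}^T W \tilde{Y}\\ G^T W \tilde{Y}\\
#'   K^T W \tilde{Y}\end{pmatrix}}
#' This is the well-posed parameterisation of the identity-design system
#' (the \eqn{d_0}-form involves \eqn{(GG^T)^{-1}}, which is singular for
#' \eqn{q < n}); the BLUPs are \eqn{\hat{d}_1 = G\hat\theta},
#' \eqn{\hat{d}_2 = K\hat{b}}. The solution coincides with the GLS/BLUP
#' closed forms of [henderson_closed()], which is the identity the test
#' suite asserts.
#'
#' @param Xt Fixed-effect design matrix (n x p).
#' @param G Genotype matrix (n x q), or `NULL` to drop the term.
#' @param K Factor of the relationship matrix (`K %*% t(K) = 2 Phi`), or
#'   `NULL` to drop the kinship term.
#' @param w Working weight vector (diagonal of W).
#' @param yt Working response.
#' @param pi Named vector with `sigma2_theta`, `sigma2` and `phi` (only the
#'   components whose design matrices are supplied are used; all must be
#'   strictly positive).
#' @return List with `beta`, `theta`, `b`, `d1 = G theta`, `d2 = K b`.
#' @export
henderson_solve <- function(Xt, G, K, w, yt, pi) {
  n <- length(yt)
  stopifnot(nrow(Xt) == n, length(w) == n)
  phi <- pi[["phi"]]
  if (phi <= 0) stop("phi must be strictly positive")
  blocks <- list(Xt)
  ridge <- list(rep(0, ncol(Xt)))
  if (!is.null(G)) {
    if (pi[["sigma2_theta"]] <= 0) stop("sigma2_theta must be strictly positive")
    blocks <- c(blocks, list(G))
    ridge <- c(ridge, list(rep(phi / pi[["sigma2_theta"]], ncol(G))))
  }
  if (!is.null(K)) {
    if (pi[["sigma2"]] <= 0) stop("sigma2 must be strictly positive")
    blocks <- c(blocks, list(K))
    ridge <- c(ridge, list(rep(phi / pi[["sigma2"]], ncol(K))))
  }
  Z <- do.call(cbind, blocks)
  A <- crossprod(Z, w * Z) + diag(unlist(ridge), ncol(Z))
  rhs <- crossprod(Z, w * yt)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular Henderson system (collinear fixed-effect columns?): ",
         conditionMessage(e))
  })
  sol <- drop(sol)
  p <- ncol(Xt)
  beta <- sol[seq_len(p)]
  names(beta) <- colnames(Xt)
  at <- p
  theta <- d1 <- NULL
  if (!is.null(G)) {
    theta <- sol[at + seq_len(ncol(G))]
    d1 <- drop(G %*% theta)
    at <- at + ncol(G)
  }
  b <- d2 <- NULL
  if (!is.null(K)) {
    b <- sol[at + seq_len(ncol(K))]
    d2 <- drop(K %*% b)
  }
  list(beta = beta, theta = theta, b = b, d1 = d1, d2 = d2)
}

#' Closed-form BLUE/BLUP of the working LMM
#'
#' Evaluates \eqn{\hat\beta = (\tilde{X}^T\Sigma^{-1}\tilde{X})^{-1}
#' \tilde{X}^T\Sigma^{-1}\tilde{Y}} and the BLUPs
#' \eqn{\hat{d}_1 = \sigma_\theta^2 GG^T \Sigma^{-1}(\tilde{Y} -
#' \tilde{X}\hat\beta)}, \eqn{\hat{d}_2 = \sigma^2 KK^T \Sigma^{-1}
#' (\tilde{Y} - \tilde{X}\hat\beta)} with
#' \eqn{\Sigma = \sigma_\theta^2 GG^T + \sigma^2 KK^T + \phi W^{-1}}.
#'
#' @inheritParams henderson_solve
#' @return List with `beta`, `d1`, `d2`.
#' @export
henderson_closed <- function(Xt, G, K, w, yt, pi) {
  n <- length(yt)
  phi <- pi[["phi"]]
  Sig <- diag(phi / w, n)
  if (!is.null(G)) Sig <- Sig + pi[["sigma2_theta"]] * tcrossprod(G)
  if (!is.null(K)) Sig <- Sig + pi[["sigma2"]] * tcrossprod(K)
  Sigi <- chol2inv(chol(Sig))
  SigiX <- Sigi %*% Xt
  beta <- drop(solve(crossprod(Xt, SigiX), crossprod(SigiX, yt)))
  names(beta) <- colnames(Xt)
  r <- drop(Sigi %*% (yt - drop(Xt %*% beta)))
  d1 <- if (!is.null(G)) pi[["sigma2_theta"]] * drop(tcrossprod(G) %*% r) else NULL
  d2 <- if (!is.null(K)) pi[["sigma2"]] * drop(tcrossprod(K) %*% r) else NULL
  list(beta = beta, d1 = d1, d2 = d2)
}

#' Weighted ridge regression of the working response on genotypes
#'
#' Minimises \eqn{(\tilde{Y} - \tilde{X}\beta - G\theta)^T W
#' (\tilde{Y} - \tilde{X}\beta - G\theta) + \lambda\, \theta^T\theta}
#' jointly over \eqn{(\beta, \theta)}, with \eqn{\beta} unpenalised. With
#' \eqn{\lambda = \phi/\sigma_\theta^2} the fitted genetic values
#' \eqn{G\hat\theta} equal the BLUP \eqn{\hat{d}_1} of the mixed model
#' without the kinship term; with the kinship term present the equivalence
#' holds for the effective GLS weight matrix
#' \eqn{W = \phi\,(\sigma^2 KK^T + \phi W_0^{-1})^{-1}}.
#'
#' @param Xt Fixed-effect design (n x p; may have zero columns).
#' @param G Genotype matrix (n x q).
#' @param w Weight: a vector (diagonal W) or a full symmetric PSD matrix.
#' @param yt Working response.
#' @param lambda Ridge penalty, strictly positive.
#' @return List with `theta` (length q) and `beta` (length p).
#' @export
ridge_estimate <- function(Xt, G, w, yt, lambda) {
  if (lambda <= 0) stop("lambda must be strictly positive")
  n <- length(yt)
  if (is.null(Xt)) Xt <- matrix(0, n, 0)
  p <- ncol(Xt)
  q <- ncol(G)
  M <- cbind(Xt, G)
  WM <- if (is.matrix(w)) w %*% M else w * M
  A <- crossprod(M, WM) + diag(c(rep(0, p), rep(lambda, q)), p + q)
  rhs <- crossprod(WM, yt)
  sol <- drop(solve(A, rhs))
  list(beta = if (p) sol[seq_len(p)] else numeric(0),
       theta = sol[p + seq_len(q)])
}
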