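#' Distribution family specification for the GLMM
#'
#' Two canonical-link families are supported: binomial with logit link
#' (binary phenotypes) and gaussian with identity link (quantitative
#' phenotypes). The binomial dispersion is fixed at `phi = 1`; the gaussian
#' dispersion is estimated by REML alongside the variance components.
#'
#' @param family `"binomial"` or `"gaussian"`.
#' @param phi_known Logical; whether the dispersion is fixed. Defaults to
#'   `TRUE` for binomial (at 1) and `FALSE` for gaussian.
#' @return A `fge_family` list with the link, its inverse and derivative,
#'   the variance function and the dispersion policy.
#' @export
fge_family <- function(family = c("binomial", "gaussian"), phi_known = NULL) {
  family <- match.arg(family)
  if (family == "binomial") {
    if (is.null(phi_known)) phi_known <- TRUE
    out <- list(
      family = "binomial", link = "logit", phi_known = phi_known, phi = 1,
      linkinv = function(eta) stats::plogis(eta),
      variance = function(mu) mu * (1 - mu),
      # g'(mu) = 1/(mu(1-mu)) for the logit link
      mu_eta_inv = function(mu) 1 / (mu * (1 - mu)),
      clip = function(mu) pmin(pmax(mu, 1e-10), 1 - 1e-10))
  } else {
    if (is.null(phi_known)) phi_known <- FALSE
    out <- list(
      family = "gaussian", link = "identity", phi_known = phi_known, phi = 1,
      linkinv = identity,
      variance = function(mu) rep(1, length(mu)),
      mu_eta_inv = function(mu) rep(1, length(mu)),
      clip = identity)
  }
  class(out) <- "fge_family"
  out
}

#' PQL working response
#'
#' Linearised response \eqn{\tilde{Y} = \eta + (Y - \mu)\, g'(\mu)} used in
#' each quasi-likelihood iteration; for the gaussian identity family this
#' is `Y` itself.
#'
#' @param eta Linear predictor (including random effects).
#' @param Y Observed response.
#' @param fam A `fge_family`.
#' @return Working vector of length `n`.
#' @export
working_response <- function(eta, Y, fam = fge_family("binomial")) {
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  if (fam$family == "gaussian") return(as.numeric(Y))
  mu <- fam$clip(fam$linkinv(eta))
  as.numeric(eta + (Y - mu) * fam$mu_eta_inv(mu))
}

#' PQL working weights
#'
#' Diagonal of \eqn{W = \mathrm{diag}\{\omega / (\nu(\mu) g'(\mu)^2)\}};
#' for the logit link the entries are \eqn{\mu(1-\mu)}.
#'
#' @param mu Conditional mean vector.
#' @param fam A `fge_family`.
#' @param weights Prior observation weights (default 1).
#' @return Numeric vector of weight-matrix diagonal entries.
#' @export
working_weights <- function(mu, fam = fge_family("binomial"),
                            weights = rep(1, length(mu))) {
  mu <- fam$clip(mu)
  w <- weights / (fam$variance(mu) * fam$mu_eta_inv(mu)^2)
  if (any(w <= 0)) stop("non-positive working weights")
  as.numeric(w)
}
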