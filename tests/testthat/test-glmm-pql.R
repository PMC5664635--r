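test_that("working response and weights follow the PQL linearisation", {
  fam <- fge_family("binomial")
  # logit, eta = 0 (mu = 0.5), Y = 1: ytilde = 0 + 0.5 * 4 = 2
  expect_equal(working_response(0, 1, fam), 2)
  # zero residual returns eta itself
  mu <- plogis(0.7)
  expect_equal(working_response(0.7, mu, fam), 0.7)
  expect_error(working_response(Inf, 1, fam), "non-finite")
  expect_equal(working_weights(0.5, fam), 0.25)
  expect_equal(working_weights(0.1, fam), 0.09)

  gau <- fge_family("gaussian")
  y <- rnorm(5)
  expect_equal(working_response(rnorm(5), y, gau), y)
  expect_equal(working_weights(rnorm(5), gau), rep(1, 5))
})

test_that("Henderson system solution equals the closed-form BLUE/BLUP", {
  set.seed(10)
  n <- 20; q <- 3
  Xt <- cbind(1, rnorm(n))
  G <- matrix(rbinom(n * q, 2, 0.4), n, q)
  K <- t(chol(crossprod(matrix(rnorm(n * n), n)) / n + diag(n)))
  w <- runif(n, 0.5, 2)
  yt <- rnorm(n)
  pi <- c(sigma2_theta = 0.3, sigma2 = 0.8, phi = 1.2)
  hs <- henderson_solve(Xt, G, K, w, yt, pi)
  cf <- henderson_closed(Xt, G, K, w, yt, pi)
  expect_equal(hs$beta, cf$beta, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(hs$d1, cf$d1, tolerance = 1e-6)
  expect_equal(hs$d2, cf$d2, tolerance = 1e-6)
})

test_that("Henderson solve limits: vanishing penalty and dropped terms", {
  set.seed(11)
  n <- 15; q <- 2
  Xt <- cbind(rep(1, n))
  G <- matrix(rbinom(n * q, 2, 0.3), n, q)
  w <- rep(1, n)
  yt <- rnorm(n)
  # sigma2_theta -> 0 (infinite ridge): d1 -> 0
  hs <- henderson_solve(Xt, G, NULL, w, yt,
                        c(sigma2_theta = 1e-12, phi = 1))
  expect_lt(max(abs(hs$d1)), 1e-8)
  # no genotype term: beta is the GLS estimate under Sigma = s2 KK' + phi W^-1
  K <- diag(n)
  pi <- c(sigma2 = 0.5, phi = 1)
  hs2 <- henderson_solve(Xt, NULL, K, w, yt, pi)
  Sig <- 0.5 * diag(n) + diag(n)
  beta_gls <- solve(t(Xt) %*% solve(Sig) %*% Xt, t(Xt) %*% solve(Sig) %*% yt)
  expect_equal(unname(hs2$beta), drop(beta_gls), tolerance = 1e-8)
  expect_error(henderson_solve(cbind(Xt, Xt), G, NULL, w, yt,
                               c(sigma2_theta = 0.3, phi = 1)), "singular")
})

test_that("ridge estimator shrinks as expected in closed-form cases", {
  set.seed(12)
  n <- 12; q <- 3
  G <- qr.Q(qr(matrix(rnorm(n * q), n, q)))   # orthonormal columns
  yt <- rnorm(n)
  lam <- 2.5
  r <- ridge_estimate(NULL, G, rep(1, n), yt, lam)
  expect_equal(r$theta, drop(crossprod(G, yt)) / (1 + lam), tolerance = 1e-10)
  r_inf <- ridge_estimate(NULL, G, rep(1, n), yt, 1e12)
  expect_lt(max(abs(r_inf$theta)), 1e-8)
  expect_error(ridge_estimate(NULL, G, rep(1, n), yt, 0), "strictly positive")
})

test_that("ridge estimate equals BLUP d1 at lambda = phi/sigma2_theta", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(10:30, 1); q <- sample(2:5, 1)
    Xt <- cbind(1, rnorm(n))
    G <- matrix(rbinom(n * q, 2, 0.4), n, q)
    w <- runif(n, 0.5, 2)
    yt <- rnorm(n)
    s2t <- runif(1, 0.1, 1); phi <- runif(1, 0.5, 2)
    # no-kinship form: diagonal weights
    hs <- henderson_solve(Xt, G, NULL, w, yt,
                          c(sigma2_theta = s2t, phi = phi))
    rr <- ridge_estimate(Xt, G, w / phi, yt, 1 / s2t)
    expect_equal(drop(G %*% rr$theta), hs$d1, tolerance = 1e-8)
    # with kinship: effective GLS weight matrix phi * V^-1
    K <- t(chol(crossprod(matrix(rnorm(n * n), n)) / n + diag(n)))
    s2 <- runif(1, 0.2, 1)
    hs2 <- henderson_solve(Xt, G, K, w, yt,
                           c(sigma2_theta = s2t, sigma2 = s2, phi = phi))
    V <- s2 * K %*% t(K) + phi * diag(1 / w)
    rr2 <- ridge_estimate(Xt, G, phi * solve(V), yt, phi / s2t)
    expect_equal(drop(G %*% rr2$theta), hs2$d1, tolerance = 1e-8)
  }
})

test_that("ridge estimate minimises the penalized weighted least-squares objective", {
  set.seed(14)
  n <- 15; q <- 3
  Xt <- cbind(rep(1, n))
  G <- matrix(rbinom(n * q, 2, 0.3), n, q)
  w <- runif(n, 0.5, 2)
  yt <- rnorm(n)
  lam <- 1.7
  obj <- function(par) {
    b <- par[1]; th <- par[-1]
    r <- yt - Xt %*% b - G %*% th
    sum(w * r^2) + lam * sum(th^2)
  }
  rr <- ridge_estimate(Xt, G, w, yt, lam)
  num <- optim(rep(0, q + 1), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(c(rr$beta, rr$theta), num$par, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_lte(obj(c(rr$beta, rr$theta)), num$value + 1e-8)
})

test_that("gaussian REML fit reproduces the closed-form one-way ANOVA estimates", {
  set.seed(7)
  m <- 40; k <- 5; n <- m * k
  g <- rep(1:m, each = k)
  y <- 1 + rep(rnorm(m, 0, sqrt(2)), each = k) + rnorm(n, 0, sqrt(1.5))
  Z <- outer(g, 1:m, "==") * 1
  TwoPhi <- tcrossprod(Z)
  Xt <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- famGE:::fit_null_work(y, Xt, NULL, TwoPhi,
                               fge_family("gaussian"), fit_control())
  gm <- tapply(y, g, mean)
  MSB <- k * sum((gm - mean(y))^2) / (m - 1)
  MSW <- sum((y - gm[g])^2) / (n - m)
  expect_equal(unname(fit$pi[["sigma2"]]), (MSB - MSW) / k, tolerance = 1e-4)
  expect_equal(unname(fit$pi[["phi"]]), MSW, tolerance = 1e-4)
  expect_equal(unname(fit$beta[[1]]), mean(y), tolerance = 1e-6)
})

test_that("the blockwise iteration engine agrees with a single-block fit", {
  prob <- small_gaussian_problem(n_fam = 4, q = 2, seed = 21)
  TwoPhi <- kinship_matrix(prob$kin)
  Xt <- prob$design$Xtilde
  f_block <- fit_null(prob$design, prob$kin, fge_family("gaussian"))
  f_mono <- famGE:::fit_null_work(prob$design$Y, Xt, prob$design$G, TwoPhi,
                                  fge_family("gaussian"), fit_control(),
                                  blocks = NULL)
  expect_equal(f_block$pi, f_mono$pi, tolerance = 1e-6)
  expect_equal(f_block$beta, f_mono$beta, tolerance = 1e-6)
})

test_that("fitted null model satisfies the projection identities", {
  prob <- small_gaussian_problem(n_fam = 6, q = 3, seed = 31)
  fit <- fit_null(prob$design, prob$kin, fge_family("gaussian"))
  P <- null_projection(fit)
  Sig <- oracle_sigma(fit$pi, fit$state$GGt, fit$state$TwoPhi,
                      fit$state$winv, fit$state$phi_fixed)
  expect_lt(max(abs(P %*% fit$Xtilde)), 1e-6)
  expect_lt(max(abs(P - P %*% Sig %*% P)), 1e-6)
  expect_lt(max(abs(P - t(P))), 1e-10)
  expect_true(all(fit$pi >= 0))
})

test_that("degenerate binomial responses are refused", {
  prob <- small_gaussian_problem(n_fam = 3, q = 2, seed = 41)
  d <- prob$design
  d$Y <- rep(1, length(d$Y))
  expect_error(fit_null(d, prob$kin, fge_family("binomial")), "degenerate")
  d$Y <- rep(0.5, length(d$Y))
  expect_error(fit_null(d, prob$kin, fge_family("binomial")), "0/1")
})

test_that("binomial PQL recovers a plausible variance on exchangeable clusters", {
  # strong-signal smoke test of the logistic branch against the generative truth
  set.seed(51)
  m <- 120; k <- 8; n <- m * k
  g <- rep(1:m, each = k)
  b <- rep(rnorm(m, 0, 1), each = k)
  y <- rbinom(n, 1, plogis(0.2 + b))
  Z <- outer(g, 1:m, "==") * 1
  TwoPhi <- tcrossprod(Z)
  blocks <- split(seq_len(n), g)
  Xt <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- famGE:::fit_null_work(y, Xt, NULL, TwoPhi, fge_family("binomial"),
                               fit_control(), blocks = blocks)
  # PQL attenuates binary-data variance components somewhat; wide band
  expect_gt(fit$pi[["sigma2"]], 0.4)
  expect_lt(fit$pi[["sigma2"]], 1.6)
  expect_true(fit$converged)
})
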