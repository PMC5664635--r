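# bivariate-normal orthant oracle: P(Z1 < a, Z2 < b) with correlation rho,
# by 1-D quadrature — used to predict dosage correlations of the
# copula-based LD generator independently of its sampling code
bvn_lower <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a) * pnorm(b))
  f <- function(z) pnorm((b - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
  integrate(f, -Inf, a, rel.tol = 1e-10)$value
}

allele_cor_oracle <- function(rho, p1, p2) {
  a <- qnorm(p1); b <- qnorm(p2)
  p11 <- bvn_lower(a, b, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

test_that("the pedigree pool has the documented size and structure", {
  cfg <- sim_config(n_reps = 1, seed = 1)
  pool <- make_pedigree_pool(cfg)
  expect_equal(nrow(pool), 10000)
  expect_equal(length(unique(pool$fid)), 1000)
  expect_equal(sum(is_founder(pool)), 4000)   # 4 founders per family
})

test_that("simulated genotypes respect Hardy-Weinberg means on founders", {
  founders <- new_pedigree(rep(sprintf("s%05d", 1:20000), each = 1),
                           rep("1", 20000), rep("0", 20000), rep("0", 20000),
                           rep(1, 20000))
  G <- simulate_genotypes(founders, seed = 2, maf = 0.5,
                          ld_mode = "independent")
  expect_equal(mean(G), 1.0, tolerance = 0.01)
  G2 <- simulate_genotypes(founders, seed = 3, maf = 0.2,
                           ld_mode = "independent")
  expect_equal(mean(G2), 0.4, tolerance = 0.01)
  expect_error(simulate_genotypes(founders, maf = 0.5), "seed")
  expect_error(simulate_genotypes(founders, seed = 1, maf = 0.7), "MAF")
})

test_that("gene dropping is Mendelian-consistent", {
  cfg <- sim_config(n_families = 50, q = 5, n_reps = 1, seed = 4)
  ped <- make_pedigree_pool(200)
  G <- simulate_genotypes(ped, cfg, seed = 5)
  idx <- stats::setNames(seq_len(nrow(ped)), paste(ped$fid, ped$iid))
  ok <- TRUE
  for (i in which(!is_founder(ped))) {
    cf <- G[idx[[paste(ped$fid[i], ped$father[i])]], ]
    cm <- G[idx[[paste(ped$fid[i], ped$mother[i])]], ]
    ch <- G[i, ]
    # transmissible allele counts: parent dosage 0 -> transmits 0,
    # dosage 2 -> transmits 1, dosage 1 -> either
    lo <- (cf == 2) + (cm == 2)
    hi <- 2 - ((cf == 0) + (cm == 0))
    ok <- ok && all(ch >= lo & ch <= hi)
  }
  expect_true(ok)
})

test_that("founder allele frequencies are conserved through the pool", {
  cfg <- sim_config(q = 10, n_reps = 1, seed = 6)
  ped <- make_pedigree_pool(cfg)
  G <- simulate_genotypes(ped, cfg, seed = 7)
  maf <- attr(G, "maf")
  # empirical frequency within 3 binomial SEs of the target (founders only)
  fo <- is_founder(ped)
  n_al <- 2 * sum(fo)
  freq <- colMeans(G[fo, ]) / 2
  se <- sqrt(maf * (1 - maf) / n_al)
  expect_true(all(abs(freq - maf) <= 3 * se + 1e-12))
})

test_that("LD-mode dosage correlations match the copula quadrature oracle", {
  founders <- new_pedigree(sprintf("s%05d", 1:10000), rep("1", 10000),
                           rep("0", 10000), rep("0", 10000), rep(1, 10000))
  maf <- default_mafs(20, "ld")
  G <- simulate_genotypes(founders, seed = 9, maf = maf, ld_mode = "ld")
  R_lat <- ld_target_correlation(20)
  emp <- cor(G)
  for (pair in list(c(1, 2), c(1, 3), c(5, 6), c(11, 12), c(1, 11), c(3, 15))) {
    i <- pair[1]; j <- pair[2]
    expected <- allele_cor_oracle(R_lat[i, j], maf[i], maf[j])
    expect_lt(abs(emp[i, j] - expected), 0.03)
  }
  # sign texture: adjacent SNPs within a block anti-correlated (alternating
  # signs), distance-2 positively correlated, across blocks ~ 0
  expect_lt(emp[1, 2], -0.3)
  expect_gt(emp[1, 3], 0.3)
  expect_lt(abs(emp[1, 11]), 0.1)
})

test_that("environment model moments: variance 8, within-family covariance 4", {
  set.seed(10)
  nfam <- 4000
  fid <- rep(seq_len(nfam), each = 10)
  age <- runif(10 * nfam, 20, 80)
  sex <- rep(rep(c("male", "female"), 5), nfam)
  E <- simulate_environment(age, sex, fid)
  resid <- E - (2 + 0.01 * age + 0.1 * (sex == "female"))
  expect_equal(mean(resid), 0, tolerance = 0.1)
  expect_equal(var(resid), 8, tolerance = 0.3)
  rm <- matrix(resid, nrow = 10)
  within <- cov(rm[1, ], rm[2, ])
  expect_equal(within, 4, tolerance = 0.4)
  between <- cov(rm[1, seq_len(nfam - 1)], rm[2, 1 + seq_len(nfam - 1)])
  expect_equal(between, 0, tolerance = 0.3)
  # fixed part plugs in: age 40, female, residual removed
  expect_equal(2 + 0.01 * 40 + 0.1, 2.5)
})

test_that("phenotype generators hit their target marginal probabilities", {
  cfg <- sim_config(n_families = 1000, q = 5, n_reps = 1, seed = 11)
  pool <- make_sim_pool(cfg)
  ped <- pool$ped
  kin <- famGE:::replicate_kinship(pool$kin1, unique(ped$fid))
  set.seed(12)
  E <- simulate_environment(pool$age, pool$sex, ped$fid)
  eta <- 0.1 + 0.01 * pool$age + 0.1 * (pool$sex == "female") + 0.1 * E +
    0.3 * pool$G[, 1] + 0.3 * pool$G[, 5]
  # marginal generator: P(Y=1|covariates) = plogis(eta) by construction
  Ym <- simulate_phenotype(pool$G, E, pool$age, pool$sex, kin, cfg,
                           method = "marginal")
  expect_equal(mean(Ym), mean(plogis(eta)), tolerance = 0.01)
  # conditional generator: P(Y=1) = E_alpha[plogis(eta + alpha)],
  # alpha ~ N(0, 1) marginally; Gauss-Hermite quadrature oracle
  gh_n <- 40
  gh <- list(nodes = sqrt(2) * pracma::gaussHermite(gh_n)$x,
             w = pracma::gaussHermite(gh_n)$w / sqrt(pi))
  p_cond <- sapply(eta, function(e) sum(gh$w * plogis(e + gh$nodes)))
  Yc <- simulate_phenotype(pool$G, E, pool$age, pool$sex, kin, cfg,
                           method = "conditional")
  expect_equal(mean(Yc), mean(p_cond), tolerance = 0.01)
})

test_that("datasets are reproducible from config and seed", {
  cfg <- sim_config(n_families = 20, q = 5, n_reps = 1, seed = 13)
  pool <- make_sim_pool(cfg)
  d1 <- simulate_dataset(cfg, pool, seed = 99)
  d2 <- simulate_dataset(cfg, pool, seed = 99)
  expect_identical(d1$design$Y, d2$design$Y)
  expect_identical(d1$design$G, d2$design$G)
  expect_identical(d1$design$E, d2$design$E)
  pool2 <- make_sim_pool(cfg)
  expect_identical(pool$G, pool2$G)
  expect_identical(pool$age, pool2$age)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(n_families = 2000, pool_families = 1000, seed = 1),
               "exceed")
  expect_error(sim_config(q = 3, seed = 1), "at least 5")
  expect_error(sim_config(pedigree_size = 8, seed = 1), "10")
})

test_that("study drivers produce the documented tables", {
  cfg <- sim_config(n_families = 20, q = 5, n_reps = 3, seed = 14)
  st <- run_type1_study(cfg, tests = c("vct", "score"))
  expect_s3_class(st, "fge_study")
  expect_named(st$summary,
               c("q", "ld_mode", "gamma", "n_reps", "n_failed",
                 "mean_sigma2", "mean_sigma2_theta", "lambda",
                 "reject_vct", "reject_score", "reject_minp"))
  expect_equal(nrow(st$replicates), 3)
  expect_true(all(st$replicates$converged))
  bad <- sim_config(n_families = 20, gamma1 = 0.1, seed = 1)
  expect_error(run_type1_study(bad), "gamma1")

  ps <- run_power_study(cfg, gammas = c(0, 0.05), tests = "vct")
  expect_equal(nrow(ps$summary), 2)
  expect_named(ps$monotone)
  expect_true(all(ps$summary$gamma == c(0, 0.05)))
})

test_that("the two phenotype generators imply different fitted variance scales", {
  # marginal (copula, latent correlation 2*Phi) data fit near sigma2 ~ 1.2;
  # conditional draws with sigma2 = 1 fit far lower under PQL
  cfg <- sim_config(n_families = 30, q = 5, n_reps = 1, seed = 404)
  pool <- make_sim_pool(cfg)
  s2 <- matrix(NA_real_, 20, 2)
  set.seed(405)
  for (r in 1:20) {
    fids <- sort(sample(unique(pool$ped$fid), cfg$n_families))
    rows <- which(pool$ped$fid %in% fids)
    ped <- pool$ped[rows, ]
    kin <- famGE:::replicate_kinship(pool$kin1, fids)
    E <- simulate_environment(pool$age[rows], pool$sex[rows], ped$fid)
    for (m in 1:2) {
      Y <- simulate_phenotype(pool$G[rows, ], E, pool$age[rows],
                              pool$sex[rows], kin, cfg,
                              method = c("marginal", "conditional")[m])
      d <- ge_design(as.numeric(Y),
                     cbind(age = pool$age[rows],
                           female = as.numeric(pool$sex[rows] == "female")),
                     E, pool$G[rows, ],
                     ids = data.frame(fid = ped$fid, iid = ped$iid))
      fit <- tryCatch(suppressWarnings(fit_null(d, kin)),
                      error = function(e) NULL)
      if (!is.null(fit)) s2[r, m] <- fit$pi[["sigma2"]]
    }
  }
  expect_gt(mean(s2[, 1], na.rm = TRUE), 0.9)   # marginal generator
  expect_lt(mean(s2[, 2], na.rm = TRUE), 0.7)   # conditional generator
})
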