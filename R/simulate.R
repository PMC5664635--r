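#' Simulation study configuration
#'
#' Fixes the generative conditions of the family-based interaction study:
#' samples of `n_families` 10-member pedigrees drawn without replacement
#' from a pool of `pool_families` identical pedigrees; `q` SNPs per gene,
#' either mutually independent or in block LD; environment correlated
#' within families; correlated binary phenotype with a kinship-structured
#' random effect of variance `sigma2`. The two causal SNPs (positions 1
#' and 5) carry main effects of 0.3 and interactions `gamma1`, `gamma2`.
#'
#' @param n_families Families sampled per replicate dataset.
#' @param pool_families Families in the genotype pool.
#' @param pedigree_size Members per family (fixed canonical structure, 10).
#' @param q Number of SNPs in the gene (>= 5 so both causal positions exist).
#' @param ld_mode `"independent"` or `"ld"`.
#' @param gamma1,gamma2 Interaction effects of the two causal SNPs.
#' @param sigma2 Family (kinship) variance component on the logit scale.
#' @param n_reps Number of replicate datasets in a study.
#' @param alpha Nominal test level.
#' @param seed Mandatory integer seed.
#' @return A `fge_sim_config` list.
#' @export
sim_config <- function(n_families = 100, pool_families = 1000,
                       pedigree_size = 10, q = 5,
                       ld_mode = c("independent", "ld"),
                       gamma1 = 0, gamma2 = 0, sigma2 = 1,
                       n_reps = 1000, alpha = 0.05, seed = NULL) {
  ld_mode <- match.arg(ld_mode)
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  if (pedigree_size != 10) stop("the canonical pedigree has 10 members")
  if (n_families > pool_families) stop("n_families must not exceed pool_families")
  if (q < 5) stop("q must be at least 5 (causal SNPs sit at positions 1 and 5)")
  structure(list(n_families = n_families, pool_families = pool_families,
                 pedigree_size = pedigree_size, q = q, ld_mode = ld_mode,
                 gamma1 = gamma1, gamma2 = gamma2, sigma2 = sigma2,
                 n_reps = n_reps, alpha = alpha, seed = as.integer(seed),
                 causal = c(1L, 5L)),
            class = "fge_sim_config")
}

# deterministic sub-seed derivation (kept inside 32-bit integer range)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629)
}

#' Canonical 10-member, 3-generation pedigree pool
#'
#' Each family: two founding grandparents; two of their children, each
#' married to an unrelated founder spouse; four grandchildren (two per
#' couple). Sexes are fixed by the structure.
#'
#' @param cfg A `fge_sim_config` (or an integer number of families).
#' @return A `fge_pedigree` with `cfg$pool_families` families.
#' @export
make_pedigree_pool <- function(cfg) {
  nf <- if (inherits(cfg, "fge_sim_config")) cfg$pool_families else as.integer(cfg)
  one <- data.frame(
    iid    = as.character(1:10),
    father = c(NA, NA, "1", "1", NA, NA, "3", "3", "6", "6"),
    mother = c(NA, NA, "2", "2", NA, NA, "5", "5", "4", "4"),
    sex    = c("male", "female", "male", "female", "female", "male",
               "male", "female", "male", "female"),
    stringsAsFactors = FALSE)
  fids <- sprintf("fam%04d", seq_len(nf))
  ped <- one[rep(seq_len(10), nf), , drop = FALSE]
  ped$fid <- rep(fids, each = 10)
  new_pedigree(ped$fid, ped$iid, ped$father, ped$mother, ped$sex)
}

# pedigree generation index: 0 = grandparents, 1 = parents, 2 = children;
# founder spouses are pulled up to their co-parent's generation.
pedigree_generation <- function(ped) {
  n <- nrow(ped)
  gen <- rep(0L, n)
  key <- paste(ped$fid, ped$iid, sep = "\r")
  idx <- stats::setNames(seq_len(n), key)
  fa <- idx[paste(ped$fid, ped$father, sep = "\r")]
  mo <- idx[paste(ped$fid, ped$mother, sep = "\r")]
  for (pass in 1:25) {
    old <- gen
    dep <- ifelse(is.na(fa), 0L, gen[ifelse(is.na(fa), 1L, fa)] + 1L)
    dep2 <- ifelse(is.na(mo), 0L, gen[ifelse(is.na(mo), 1L, mo)] + 1L)
    gen <- pmax(gen, dep, dep2)
    # spouses: a parent sits one generation above each of its children
    for (p in list(fa, mo)) {
      ok <- !is.na(p)
      up <- tapply(gen[ok] - 1L, p[ok], max)
      gen[as.integer(names(up))] <- pmax(gen[as.integer(names(up))],
                                         as.integer(up))
    }
    if (identical(gen, old)) break
  }
  gen
}

# ages: Uniform(20, 50) plus 15 years per generation above the youngest
simulate_ages <- function(ped) {
  gen <- pedigree_generation(ped)
  stats::runif(nrow(ped), 20, 50) + (max(gen) - gen) * 15
}

#' Default minor allele frequencies for the simulated gene
#'
#' Causal positions 1 and 5 get MAF 0.3 and 0.1 (independent SNPs) or
#' 0.3 and 0.17 (LD SNPs); the remaining positions cycle through a fixed
#' grid of common frequencies.
#'
#' @param q Number of SNPs.
#' @param ld_mode `"independent"` or `"ld"`.
#' @return Numeric vector of length `q` with entries in (0, 0.5].
#' @export
default_mafs <- function(q, ld_mode = c("independent", "ld")) {
  ld_mode <- match.arg(ld_mode)
  maf <- rep_len(c(0.2, 0.3, 0.25, 0.4, 0.35, 0.15, 0.45, 0.3, 0.2, 0.25), q)
  maf[1] <- 0.3
  if (q >= 5) maf[5] <- if (ld_mode == "ld") 0.17 else 0.1
  maf
}

#' Target latent correlation of the LD haplotype model
#'
#' Block LD texture: blocks of 10 SNPs; within a block the latent
#' (Gaussian-copula) correlation is \eqn{s_i s_j\, 0.9^{|i-j|}} with
#' alternating signs \eqn{s_i = (-1)^{i-1}} (mixed high positive and
#' negative correlation); different blocks are independent.
#'
#' @param q Number of SNPs.
#' @return A q x q correlation matrix.
#' @export
ld_target_correlation <- function(q) {
  R <- diag(q)
  block <- (seq_len(q) - 1L) %/% 10L
  s <- (-1)^(seq_len(q) - 1L)
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (block[i] == block[j]) R[i, j] <- s[i] * s[j] * 0.9^abs(i - j)
    }
  }
  R
}

#' Gene-drop genotypes through a pedigree
#'
#' Founders draw two haplotypes — independently Bernoulli(MAF) per SNP in
#' independent mode, or from a Gaussian-copula haplotype model with the
#' block-LD latent correlation in LD mode — and every non-founder inherits
#' one haplotype of each parent uniformly at random (no recombination
#' within the gene), so genotypes are Mendelian-consistent by construction.
#'
#' @param ped A `fge_pedigree`.
#' @param cfg A `fge_sim_config` (supplies `q` and `ld_mode`), or `NULL`
#'   when `maf`/`ld_mode` are given directly.
#' @param seed Mandatory integer seed.
#' @param maf Optional MAF vector overriding [default_mafs()].
#' @param ld_mode Used when `cfg` is `NULL`.
#' @return Dosage matrix (individuals x SNPs, values 0/1/2) in pedigree row
#'   order, with attributes `maf` and `ld_mode`.
#' @export
simulate_genotypes <- function(ped, cfg = NULL, seed = NULL, maf = NULL,
                               ld_mode = c("independent", "ld")) {
  if (is.null(seed)) stop("a seed is required for genotype simulation")
  if (!is.null(cfg)) {
    ld_mode <- cfg$ld_mode
    if (is.null(maf)) maf <- default_mafs(cfg$q, ld_mode)
  } else {
    ld_mode <- match.arg(ld_mode)
    if (is.null(maf)) stop("supply cfg or maf")
  }
  if (any(maf <= 0 | maf > 0.5)) stop("MAFs must lie in (0, 0.5]")
  set.seed(seed)
  q <- length(maf)
  n <- nrow(ped)
  # founder haplotype bank (each missing-parent side consumes one entry)
  n_hap <- 2L * n
  if (ld_mode == "independent") {
    H <- matrix(stats::rbinom(n_hap * q, 1L, rep(maf, each = n_hap)),
                n_hap, q)
  } else {
    R <- ld_target_correlation(q)
    Z <- matrix(stats::rnorm(n_hap * q), n_hap, q) %*% chol(R)
    H <- matrix(0L, n_hap, q)
    H[sweep(Z, 2, stats::qnorm(maf), "<")] <- 1L
  }
  # haplotype bookkeeping: two rows per individual
  hap <- matrix(0L, 2L * n, q)
  key <- paste(ped$fid, ped$iid, sep = "\r")
  idx <- stats::setNames(seq_len(n), key)
  f_at <- 0L
  # process ancestors first within each family
  for (f in unique(ped$fid)) {
    rows <- which(ped$fid == f)
    fam <- ped[rows, , drop = FALSE]
    ord <- rows[topo_order_family(fam)]
    for (i in ord) {
      fa <- if (is.na(ped$father[i])) NA_integer_ else
        idx[[paste(ped$fid[i], ped$father[i], sep = "\r")]]
      mo <- if (is.na(ped$mother[i])) NA_integer_ else
        idx[[paste(ped$fid[i], ped$mother[i], sep = "\r")]]
      if (is.na(fa)) {
        f_at <- f_at + 1L
        hap[2L * i - 1L, ] <- H[f_at, ]
      } else {
        hap[2L * i - 1L, ] <- hap[2L * fa - 2L + sample.int(2L, 1L), ]
      }
      if (is.na(mo)) {
        f_at <- f_at + 1L
        hap[2L * i, ] <- H[f_at, ]
      } else {
        hap[2L * i, ] <- hap[2L * mo - 2L + sample.int(2L, 1L), ]
      }
    }
  }
  G <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  storage.mode(G) <- "double"
  colnames(G) <- paste0("snp", seq_len(q))
  rownames(G) <- paste(ped$fid, ped$iid, sep = ":")
  attr(G, "maf") <- maf
  attr(G, "ld_mode") <- ld_mode
  G
}

#' Simulate the family-correlated environmental exposure
#'
#' \eqn{E_{ij} = 2 + 0.01\,\mathrm{Age}_{ij} + 0.1\, I(\mathrm{Female}_{ij})
#' + \gamma_i + \varepsilon_{ij}} with family effect
#' \eqn{\gamma_i \sim N(0, 4)} and noise \eqn{\varepsilon_{ij} \sim N(0,4)},
#' giving residual variance 8 and within-family exchangeable correlation 0.5.
#'
#' @param age Numeric age vector.
#' @param sex Sex vector (`"male"`/`"female"` or 1/2 codes).
#' @param fid Family identifier vector.
#' @param seed Optional seed (draws from the ambient RNG stream if `NULL`).
#' @return Numeric exposure vector.
#' @export
simulate_environment <- function(age, sex, fid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sex <- normalize_sex(sex)
  fids <- unique(fid)
  gam <- stats::setNames(stats::rnorm(length(fids), 0, 2), fids)
  2 + 0.01 * age + 0.1 * (sex == "female") + gam[fid] +
    stats::rnorm(length(age), 0, 2)
}

#' Simulate the correlated binary phenotype
#'
#' The linear predictor is
#' \deqn{\eta_{ij} = 0.1 + 0.01\,\mathrm{Age} + 0.1\,I(\mathrm{Female}) +
#' 0.1 E + 0.3 G_1 + 0.3 G_2 + \gamma_1 (G_1 \times E) +
#' \gamma_2 (G_2 \times E)}
#' and the family dependence is kinship-structured with scale parameter
#' `sigma2`. Two generators are available:
#'
#' * `"marginal"` (default): the coefficients are marginal log-odds and the
#'   within-family dependence is injected through a Gaussian copula on the
#'   logistic error — \eqn{Y_{ij} = I(e_{ij} \le \eta_{ij})} with
#'   \eqn{e_{ij} = F_L^{-1}(\Phi_N(Z_{ij}))}, \eqn{Z_i \sim N(0,
#'   2\sigma^2\Phi_i)} (for non-inbred pedigrees and `sigma2 = 1` the
#'   latent correlation matrix is exactly \eqn{2\Phi_i}). This is the
#'   marginally-specified correlated-binary construction used for the
#'   reference simulation study.
#' * `"conditional"`: the GLMM's own data-generating process —
#'   \eqn{\alpha_i \sim N(0, 2\sigma^2\Phi_i)} enters the logit and
#'   \eqn{Y_{ij} \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\eta_{ij} +
#'   \alpha_{ij}))} conditionally independently.
#'
#' @param G Dosage matrix.
#' @param E Exposure vector.
#' @param age,sex Covariates.
#' @param kin `fge_kinship` aligned with the rows.
#' @param cfg `fge_sim_config` (supplies `gamma1`, `gamma2`, `sigma2`,
#'   causal positions).
#' @param method `"marginal"` or `"conditional"` (see Details).
#' @param seed Optional seed.
#' @return 0/1 response vector with attribute `truth` recording all
#'   generative coefficients.
#' @export
simulate_phenotype <- function(G, E, age, sex, kin, cfg,
                               method = c("marginal", "conditional"),
                               seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  sex <- normalize_sex(sex)
  c1 <- cfg$causal[1]; c2 <- cfg$causal[2]
  # kinship-structured gaussian draw, Var = 2*sigma2*Phi, via family factors
  alpha <- numeric(nrow(G))
  at <- 1L
  for (b in kin$blocks) {
    k <- length(b$ids)
    alpha[at:(at + k - 1L)] <- sqrt(cfg$sigma2) * drop(b$K %*% stats::rnorm(k))
    at <- at + k
  }
  eta <- 0.1 + 0.01 * age + 0.1 * (sex == "female") + 0.1 * E +
    0.3 * G[, c1] + 0.3 * G[, c2] +
    cfg$gamma1 * G[, c1] * E + cfg$gamma2 * G[, c2] * E
  if (method == "conditional") {
    Y <- stats::rbinom(length(eta), 1L, stats::plogis(eta + alpha))
  } else {
    # copula-correlated logistic errors; the latent correlation is 2*Phi
    # (scale-free in sigma2, which only fixes the correlation-matrix scale)
    e <- if (cfg$sigma2 > 0) {
      stats::qlogis(stats::pnorm(alpha / sqrt(cfg$sigma2)))
    } else {
      stats::rlogis(length(eta))
    }
    Y <- as.integer(e <= eta)
  }
  attr(Y, "truth") <- list(intercept = 0.1, age = 0.01, female = 0.1,
                           env = 0.1, main = c(0.3, 0.3),
                           gamma = c(cfg$gamma1, cfg$gamma2),
                           sigma2 = cfg$sigma2, causal = cfg$causal,
                           method = method, alpha = alpha, eta = eta)
  Y
}

#' Build the genotype pool for a simulation study
#'
#' Generates the pedigree pool, gene-drops the genotypes once (they stay
#' fixed across replicates, as in a genotyped cohort), simulates ages, and
#' computes the canonical per-family kinship block.
#'
#' @param cfg A `fge_sim_config`.
#' @return A `fge_sim_pool` list with `ped`, `G`, `age`, `sex`, and the
#'   canonical one-family kinship `kin1`.
#' @export
make_sim_pool <- function(cfg) {
  ped <- make_pedigree_pool(cfg)
  G <- simulate_genotypes(ped, cfg, seed = derive_seed(cfg$seed, 1))
  set.seed(derive_seed(cfg$seed, 2))
  age <- simulate_ages(ped)
  kin1 <- compute_kinship(ped[ped$fid == ped$fid[1], , drop = FALSE])
  structure(list(ped = ped, G = G, age = age, sex = ped$sex, kin1 = kin1,
                 cfg = cfg),
            class = "fge_sim_pool")
}

# kinship structure for a sampled set of identical-structure families
replicate_kinship <- function(kin1, fids) {
  b1 <- kin1$blocks[[1]]
  blocks <- lapply(fids, function(f) {
    b <- b1; b$fid <- f; b
  })
  names(blocks) <- fids
  structure(list(blocks = blocks,
                 ids = data.frame(fid = rep(fids, each = length(b1$ids)),
                                  iid = rep(b1$ids, length(fids)),
                                  stringsAsFactors = FALSE)),
            class = "fge_kinship")
}

#' Draw one replicate dataset from a pool
#'
#' Samples `cfg$n_families` families without replacement, simulates the
#' exposure and phenotype, and assembles the analysis design (covariates:
#' age and sex indicator; exposure E; the gene's dosages).
#'
#' @param cfg A `fge_sim_config`.
#' @param pool A `fge_sim_pool` (built if `NULL`).
#' @param seed Optional seed for this replicate.
#' @return A `fge_sim_dataset`: list with `design` (`fge_design`), `kin`
#'   (`fge_kinship`), `ped`, `truth`.
#' @export
simulate_dataset <- function(cfg, pool = NULL, seed = NULL) {
  if (is.null(pool)) pool <- make_sim_pool(cfg)
  if (!is.null(seed)) set.seed(seed)
  fids_all <- unique(pool$ped$fid)
  fids <- sort(sample(fids_all, cfg$n_families))
  rows <- which(pool$ped$fid %in% fids)
  ped <- pool$ped[rows, , drop = FALSE]
  class(ped) <- c("fge_pedigree", "data.frame")
  age <- pool$age[rows]
  sex <- pool$sex[rows]
  G <- pool$G[rows, , drop = FALSE]
  kin <- replicate_kinship(pool$kin1, fids)
  E <- simulate_environment(age, sex, ped$fid)
  Y <- simulate_phenotype(G, E, age, sex, kin, cfg)
  design <- ge_design(Y = as.numeric(Y),
                      X = cbind(age = age, female = as.numeric(sex == "female")),
                      E = E, G = G,
                      ids = data.frame(fid = ped$fid, iid = ped$iid,
                                       stringsAsFactors = FALSE))
  structure(list(design = design, kin = kin, ped = ped,
                 truth = attr(Y, "truth"), cfg = cfg),
            class = "fge_sim_dataset")
}

# ---- study drivers ----------------------------------------------------------

# one (q, ld_mode, gamma) scenario; returns replicate-level data frame
run_scenario <- function(cfg, tests, scenario_seed) {
  set.seed(scenario_seed)
  pool <- make_sim_pool(cfg)
  set.seed(derive_seed(scenario_seed, 3))
  out <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    ds <- simulate_dataset(cfg, pool)
    row <- data.frame(rep = r, q = cfg$q, ld_mode = cfg$ld_mode,
                      gamma = cfg$gamma1, converged = FALSE,
                      sigma2 = NA_real_, sigma2_theta = NA_real_,
                      lambda = NA_real_, p_vct = NA_real_,
                      p_score = NA_real_, p_minp = NA_real_)
    out[[r]] <- tryCatch(suppressWarnings({
      fit <- fit_null(ds$design, ds$kin, fge_family("binomial"),
                      fit_control())
      row$converged <- TRUE
      row$sigma2 <- fit$pi[["sigma2"]]
      row$sigma2_theta <- fit$pi[["sigma2_theta"]]
      row$lambda <- fit$lambda
      if ("vct" %in% tests) {
        row$p_vct <- vct(ds$design, ds$kin, fit = fit)$p_value
      }
      if ("score" %in% tests) {
        row$p_score <- fixed_score_test(fit, ds$design$S)$p_value
      }
      if ("minp" %in% tests) {
        row$p_minp <- minp_test(ds$design, ds$kin)$p_value
      }
      row
    }), error = function(e) row)
  }
  do.call(rbind, out)
}

summarize_study <- function(reps, alpha) {
  by <- split(reps, list(reps$q, reps$ld_mode, reps$gamma), drop = TRUE)
  do.call(rbind, lapply(by, function(d) {
    ok <- d$converged
    data.frame(
      q = d$q[1], ld_mode = d$ld_mode[1], gamma = d$gamma[1],
      n_reps = nrow(d), n_failed = sum(!ok),
      mean_sigma2 = mean(d$sigma2[ok]),
      mean_sigma2_theta = mean(d$sigma2_theta[ok]),
      lambda = 1 / mean(d$sigma2_theta[ok]),
      reject_vct = mean(d$p_vct[ok] < alpha),
      reject_score = mean(d$p_score[ok] < alpha),
      reject_minp = mean(d$p_minp[ok] < alpha),
      row.names = NULL)
  }))
}

#' Type-I-error study under the null (no interaction)
#'
#' Runs the null simulation (`gamma1 = gamma2 = 0`) for every combination
#' of `q` and `ld_mode`, recording per replicate the fitted variance
#' components, the implied ridge penalty, and the p-values of the selected
#' tests. The summary's `lambda` column is the dispersion over the mean of
#' the fitted `sigma2_theta` across replicates.
#'
#' @param cfg A `fge_sim_config` with `gamma1 = gamma2 = 0`; its `q` and
#'   `ld_mode` entries may be vectors, which are crossed into scenarios.
#' @param tests Character subset of `c("vct", "score", "minp")`.
#' @return A `fge_study`: list with `summary` (one row per scenario) and
#'   `replicates` (one row per replicate).
#' @export
run_type1_study <- function(cfg, tests = c("vct", "score")) {
  if (cfg$gamma1 != 0 || cfg$gamma2 != 0) {
    stop("type-I-error study requires gamma1 = gamma2 = 0")
  }
  grid <- expand.grid(q = unique(cfg$q), ld_mode = unique(cfg$ld_mode),
                      stringsAsFactors = FALSE)
  reps <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$q <- grid$q[i]
    cfg_i$ld_mode <- grid$ld_mode[i]
    run_scenario(cfg_i, tests, derive_seed(cfg$seed, 100 + i))
  }))
  structure(list(summary = summarize_study(reps, cfg$alpha),
                 replicates = reps, alpha = cfg$alpha),
            class = "fge_study")
}

#' Empirical power study over a grid of interaction effects
#'
#' For each value `g` of the grid, sets `gamma1 = gamma2 = g` and runs the
#' simulation, reporting the empirical rejection rate per method together
#' with a monotone-trend diagnostic (is power non-decreasing in gamma).
#'
#' @param cfg A `fge_sim_config`; its `q`/`ld_mode` must be scalar.
#' @param gammas Numeric grid of interaction effect sizes.
#' @param tests Character subset of `c("vct", "score", "minp")`.
#' @return A `fge_study` with a `summary` row per gamma value and the
#'   attribute `monotone` (logical per test).
#' @export
run_power_study <- function(cfg, gammas = seq(0, 0.1, by = 0.01),
                            tests = c("vct", "minp")) {
  reps <- do.call(rbind, lapply(seq_along(gammas), function(i) {
    cfg_i <- cfg
    cfg_i$gamma1 <- cfg_i$gamma2 <- gammas[i]
    run_scenario(cfg_i, tests, derive_seed(cfg$seed, 500 + i))
  }))
  summ <- summarize_study(reps, cfg$alpha)
  summ <- summ[order(summ$gamma), , drop = FALSE]
  monotone <- vapply(c(vct = "reject_vct", score = "reject_score",
                       minp = "reject_minp"),
                     function(col) {
                       v <- summ[[col]]
                       !anyNA(v) && all(diff(v) >= -.Machine$double.eps)
                     }, logical(1))
  structure(list(summary = summ, replicates = reps, alpha = cfg$alpha,
                 monotone = monotone),
            class = "fge_study")
}

#' @export
print.fge_study <- function(x, ...) {
  cat("Simulation study (", max(x$summary$n_reps), " replicates per scenario, alpha = ",
      x$alpha, ")\n", sep = "")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
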