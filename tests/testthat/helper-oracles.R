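# Independent oracles used across the test files. These deliberately avoid
# the package's own algorithms: kinship is computed by exhaustive
# enumeration of inheritance vectors, and the GLMM quantities by explicit
# matrix inverses.

# --- exhaustive-gene-drop kinship oracle -------------------------------------
# phi(a, b) = P(a random allele of a is IBD to a random allele of b),
# computed exactly by enumerating every inheritance vector (2 bits per
# non-founder). Practical for pedigrees of <= ~10 members.
oracle_kinship <- function(fam) {
  n <- nrow(fam)
  idx <- stats::setNames(seq_len(n), fam$iid)
  fa <- idx[fam$father]
  mo <- idx[fam$mother]
  ord <- famGE:::topo_order_family(fam)
  # one inheritance bit per known-parent side
  nbits <- sum(!is.na(fa)) + sum(!is.na(mo))
  phi <- matrix(0, n, n, dimnames = list(fam$iid, fam$iid))
  nvec <- 2L^nbits
  for (v in 0:(nvec - 1L)) {
    bits <- as.integer(intToBits(v))[seq_len(max(nbits, 1L))]
    al <- matrix(NA_integer_, n, 2)
    lab <- 0L
    bit_at <- 0L
    for (i in ord) {
      for (side in 1:2) {
        p <- if (side == 1) fa[[i]] else mo[[i]]
        if (is.na(p)) {
          lab <- lab + 1L                      # fresh founder allele
          al[i, side] <- lab
        } else {
          bit_at <- bit_at + 1L
          al[i, side] <- al[p, 1L + bits[bit_at]]
        }
      }
    }
    phi <- phi + (outer(al[, 1], al[, 1], "==") + outer(al[, 1], al[, 2], "==") +
                    outer(al[, 2], al[, 1], "==") + outer(al[, 2], al[, 2], "==")) /
      (4 * nvec)
  }
  phi
}

# --- dense GLMM oracle -------------------------------------------------------
# Everything via solve() on explicitly built matrices.
oracle_sigma <- function(pi, GGt, TwoPhi, winv, phi_fixed = NULL) {
  phi <- if (is.null(phi_fixed)) pi[["phi"]] else phi_fixed
  Sig <- pi[["sigma2"]] * TwoPhi + diag(phi * winv)
  if (!is.null(GGt)) Sig <- Sig + pi[["sigma2_theta"]] * GGt
  Sig
}

oracle_projection <- function(Sig, Xt) {
  Sigi <- solve(Sig)
  Sigi - Sigi %*% Xt %*% solve(t(Xt) %*% Sigi %*% Xt) %*% t(Xt) %*% Sigi
}

# brute-force score moments: U, e, I_tau, J, M with explicit inverses
oracle_vct_moments <- function(fit, S) {
  st <- fit$state
  Sig <- oracle_sigma(fit$pi, st$GGt, st$TwoPhi, st$winv, st$phi_fixed)
  P <- oracle_projection(Sig, fit$Xtilde)
  r <- fit$ytilde - drop(fit$Xtilde %*% fit$beta)
  U <- 0.5 * drop(t(r) %*% solve(Sig) %*% S %*% t(S) %*% solve(Sig) %*% r)
  N <- S %*% t(S)
  comps <- list()
  if (!is.null(st$GGt)) comps$sigma2_theta <- st$GGt
  comps$sigma2 <- st$TwoPhi
  if (is.null(st$phi_fixed)) comps$phi <- diag(st$winv)
  k <- length(comps)
  J <- numeric(k); M <- matrix(0, k, k)
  for (a in seq_len(k)) {
    J[a] <- 0.5 * sum(diag(P %*% N %*% P %*% comps[[a]]))
    for (b in seq_len(k)) {
      M[a, b] <- 0.5 * sum(diag(P %*% comps[[a]] %*% P %*% comps[[b]]))
    }
  }
  Itt <- 0.5 * sum(diag(P %*% N %*% P %*% N))
  list(U = U, e = 0.5 * sum(diag(P %*% N)), I_tau = Itt - drop(t(J) %*% solve(M) %*% J),
       J = J, M = M, P = P, Sig = Sig)
}

# --- small builders ----------------------------------------------------------
make_fam <- function(iid, father, mother, sex, fid = "f1") {
  data.frame(fid = fid, iid = as.character(iid),
             father = ifelse(is.na(father), NA_character_, as.character(father)),
             mother = ifelse(is.na(mother), NA_character_, as.character(mother)),
             sex = sex, stringsAsFactors = FALSE)
}

canonical_family <- function(fid = "f1") {
  make_fam(1:10,
           c(NA, NA, 1, 1, NA, NA, 3, 3, 6, 6),
           c(NA, NA, 2, 2, NA, NA, 5, 5, 4, 4),
           c("male", "female", "male", "female", "female", "male",
             "male", "female", "male", "female"),
           fid = fid)
}

# random gaussian test problem with family structure; returns design + kin
small_gaussian_problem <- function(n_fam = 5, q = 3, seed = 1) {
  set.seed(seed)
  ped <- make_pedigree_pool(n_fam)
  kin <- compute_kinship(ped)
  n <- nrow(ped)
  G <- matrix(rbinom(n * q, 2, 0.3), n, q)
  while (any(apply(G, 2, var) == 0)) G <- matrix(rbinom(n * q, 2, 0.3), n, q)
  E <- rnorm(n, 2, 1)
  X <- cbind(age = runif(n, 20, 80))
  # genuine random-effect signal so variance components sit in the interior
  alpha <- drop(kinship_matrix(kin, "K") %*% rnorm(n)) * 0.8
  theta <- rnorm(q, 0, 0.5)
  Y <- rnorm(n, 1 + 0.01 * X[, 1] + 0.1 * E + drop(G %*% theta) + alpha, 1)
  design <- ge_design(Y, X, E, G, ids = data.frame(fid = ped$fid, iid = ped$iid))
  list(design = design, kin = kin, ped = ped)
}

# write a pedigree data frame to a temp PED file
write_ped_file <- function(df, sep = " ") {
  path <- tempfile(fileext = ".ped")
  sexcode <- ifelse(df$sex %in% c("male", "1"), 1, 2)
  lines <- paste(df$fid, df$iid,
                 ifelse(is.na(df$father), "0", df$father),
                 ifelse(is.na(df$mother), "0", df$mother),
                 sexcode, sep = sep)
  writeLines(lines, path)
  path
}
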