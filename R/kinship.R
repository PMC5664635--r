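#' Compute pedigree kinship matrices
#'
#' Runs the standard recursive kinship algorithm on each family of a
#' pedigree: founders are unrelated and non-inbred, and, processing
#' individuals ancestors-first,
#' \deqn{\phi(a,a) = \tfrac12\,(1 + \phi(f_a, m_a)), \qquad
#'       \phi(a,b) = \tfrac12\,(\phi(f_a, b) + \phi(m_a, b))}
#' where a missing parent contributes kinship 0 (an individual with exactly
#' one known parent is treated as having a unique unrelated founder for the
#' other). The additive relationship matrix \eqn{2\Phi_i} of each family is
#' factored as \eqn{K_i K_i^T} so the family random effect
#' \eqn{\alpha_i \sim N(0, 2\sigma^2 \Phi_i)} can be written
#' \eqn{K_i b_i} with i.i.d. \eqn{b_i}.
#'
#' @param ped A `fge_pedigree`.
#' @return A `fge_kinship` object holding, per family, the kinship matrix
#'   `phi`, its scaled version `twophi` and the factor `K`, plus the global
#'   individual ordering (identical to the pedigree row order).
#' @export
compute_kinship <- function(ped) {
  stopifnot(inherits(ped, "fge_pedigree"))
  fids <- unique(ped$fid)
  blocks <- vector("list", length(fids))
  names(blocks) <- fids
  for (f in fids) {
    fam <- ped[ped$fid == f, , drop = FALSE]
    phi <- kinship_recursion(fam)
    twophi <- 2 * phi
    K <- cholesky_factor(twophi)
    blocks[[f]] <- list(fid = f, ids = fam$iid, phi = phi,
                        twophi = twophi, K = K)
  }
  structure(
    list(blocks = blocks,
         ids = data.frame(fid = ped$fid, iid = ped$iid,
                          stringsAsFactors = FALSE)),
    class = "fge_kinship")
}

# Recursive kinship for one family; returns the n_i x n_i matrix phi with
# dimnames = individual ids, in the family's row order.
kinship_recursion <- function(fam) {
  n <- nrow(fam)
  ord <- topo_order_family(fam)
  idx <- stats::setNames(seq_len(n), fam$iid)
  fa <- idx[fam$father]  # NA when missing
  mo <- idx[fam$mother]
  phi <- matrix(0, n, n, dimnames = list(fam$iid, fam$iid))
  get_phi <- function(a, b) {           # 0 for a missing parent
    if (is.na(a) || is.na(b)) 0 else phi[a, b]
  }
  for (k in seq_along(ord)) {
    a <- ord[[k]]
    phi[a, a] <- 0.5 * (1 + get_phi(fa[[a]], mo[[a]]))
    if (k > 1L) {
      for (b in ord[seq_len(k - 1L)]) {
        v <- 0.5 * (get_phi(fa[[a]], b) + get_phi(mo[[a]], b))
        phi[a, b] <- phi[b, a] <- v
      }
    }
  }
  phi
}

#' Lower-triangular factor of a symmetric PSD matrix
#'
#' Returns `K` with `K %*% t(K)` reconstructing `m`. Uses `chol()` with a
#' small jitter fallback (`1e-10 * mean(diag)`, up to 3 attempts); for
#' rank-deficient input falls back to a symmetric eigendecomposition,
#' clamping eigenvalues in `[-tol, 0]` to zero. Eigenvalues below `-tol`
#' (relative to the largest) are an error.
#'
#' @param m Symmetric positive semi-definite matrix.
#' @param tol Relative tolerance for negative eigenvalues.
#' @return A matrix `K` (lower-triangular on the main path) with
#'   `K %*% t(K)` equal to `m` to numerical tolerance.
#' @export
cholesky_factor <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("matrix is not symmetric")
  }
  jitter <- 1e-10 * mean(diag(m))
  mm <- m
  for (attempt in 0:3) {
    ch <- tryCatch(chol(mm), error = function(e) NULL)
    if (!is.null(ch)) return(t(ch))
    mm <- mm + diag(jitter, nrow(m))
  }
  # eigen fallback for rank-deficient (PSD) input
  es <- eigen(m, symmetric = TRUE)
  lam <- es$values
  if (min(lam) < -tol * max(abs(lam), 1)) {
    stop("matrix is not positive semi-definite (smallest eigenvalue ",
         format(min(lam)), ")")
  }
  lam[lam < 0] <- 0
  K <- es$vectors %*% diag(sqrt(lam), length(lam))
  dimnames(K) <- dimnames(m)
  K
}

#' Assemble the block-diagonal relationship matrix 2*Phi
#'
#' @param kin A `fge_kinship`.
#' @param what `"twophi"`, `"phi"` or `"K"`.
#' @return Dense block-diagonal matrix over all individuals, in pedigree
#'   order, with `fid:iid` dimnames.
#' @export
kinship_matrix <- function(kin, what = c("twophi", "phi", "K")) {
  stopifnot(inherits(kin, "fge_kinship"))
  what <- match.arg(what)
  n <- nrow(kin$ids)
  if (n > 6000) {
    stop("refusing to assemble a dense ", n, "x", n,
         " matrix; work per family via kin$blocks")
  }
  out <- matrix(0, n, n)
  labs <- paste(kin$ids$fid, kin$ids$iid, sep = ":")
  dimnames(out) <- list(labs, labs)
  at <- 1L
  for (b in kin$blocks) {
    k <- length(b$ids)
    out[at:(at + k - 1L), at:(at + k - 1L)] <- b[[what]]
    at <- at + k
  }
  out
}

#' Restrict a kinship structure to a subset of individuals
#'
#' Drops rows/columns of each family's Phi while keeping the original
#' full-pedigree kinship coefficients (relatedness through dropped
#' ancestors is preserved), then refactors 2*Phi.
#'
#' @param kin A `fge_kinship`.
#' @param keep Data frame with columns `fid`, `iid` of individuals to keep,
#'   in the desired output order (must be grouped by family consistently
#'   with the pedigree family order).
#' @return A `fge_kinship` over the retained individuals.
#' @export
subset_kinship <- function(kin, keep) {
  stopifnot(inherits(kin, "fge_kinship"))
  have <- paste(kin$ids$fid, kin$ids$iid, sep = "\r")
  want <- paste(keep$fid, keep$iid, sep = "\r")
  if (!all(want %in% have)) {
    stop("individuals not present in kinship structure: ",
         paste(utils::head(keep$iid[!(want %in% have)], 5), collapse = ", "))
  }
  blocks <- list()
  for (f in unique(keep$fid)) {
    b <- kin$blocks[[f]]
    ids <- keep$iid[keep$fid == f]
    phi <- b$phi[ids, ids, drop = FALSE]
    twophi <- 2 * phi
    blocks[[f]] <- list(fid = f, ids = ids, phi = phi, twophi = twophi,
                        K = cholesky_factor(twophi))
  }
  structure(
    list(blocks = blocks,
         ids = data.frame(fid = keep$fid, iid = keep$iid,
                          stringsAsFactors = FALSE)),
    class = "fge_kinship")
}

#' Export a kinship matrix as dense CSV
#'
#' Writes 2*Phi with an individual-id header row and column.
#'
#' @param kin A `fge_kinship`.
#' @param path Output CSV path.
#' @export
write_kinship <- function(kin, path) {
  m <- kinship_matrix(kin, "twophi")
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.fge_kinship <- function(x, ...) {
  cat("Kinship structure: ", nrow(x$ids), " individuals, ",
      length(x$blocks), " families\n", sep = "")
  invisible(x)
}
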