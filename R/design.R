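#' Assemble a gene-environment analysis design
#'
#' Bundles the response, covariates, exposure and genotype dosages for one
#' gene/SNP set, row-aligned with a pedigree ordering. The interaction
#' matrix `S` is always recomputed as `E * G` column-wise (never supplied),
#' and the fixed-effect design is `Xtilde = [1 | X | E]`.
#'
#' @param Y Length-n response (binary 0/1 or continuous).
#' @param X n x p matrix/data frame of non-genetic covariates (no
#'   intercept; may have zero columns).
#' @param E Length-n environmental exposure.
#' @param G n x q genotype dosage matrix, values in `{0, 1, 2}` (q >= 1).
#' @param ids Data frame with columns `fid`, `iid` aligned to the rows.
#' @return A `fge_design` with elements `Y`, `X`, `E`, `G`, `S`, `Xtilde`,
#'   `ids`.
#' @export
ge_design <- function(Y, X, E, G, ids) {
  Y <- as.numeric(Y)
  n <- length(Y)
  if (is.null(X)) X <- matrix(0, n, 0)
  X <- as.matrix(X)
  if (!is.numeric(X)) storage.mode(X) <- "double"
  E <- as.numeric(E)
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  stopifnot(nrow(X) == n, length(E) == n, nrow(G) == n, nrow(ids) == n)
  if (ncol(G) < 1L) stop("at least one SNP is required (q >= 1)")
  if (anyNA(Y) || anyNA(X) || anyNA(E) || anyNA(G)) {
    stop("missing values in the design; filter them upstream (load_design)")
  }
  bad <- !(G %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype dosages must be 0, 1 or 2; offending value ",
         G[which(bad)[1]])
  }
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  if (ncol(X) && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  S <- G * E
  colnames(S) <- paste0(colnames(G), ":E")
  Xtilde <- cbind(`(Intercept)` = 1, X, E = E)
  structure(list(Y = Y, X = X, E = E, G = G, S = S, Xtilde = Xtilde,
                 ids = ids),
            class = "fge_design")
}

#' @export
print.fge_design <- function(x, ...) {
  cat("GE design: n = ", length(x$Y), ", q = ", ncol(x$G),
      " SNPs, ", ncol(x$Xtilde), " fixed-effect columns\n", sep = "")
  invisible(x)
}
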