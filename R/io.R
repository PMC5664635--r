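#' Read a genotype dosage CSV
#'
#' Expected layout: columns `FID`, `IID` (any capitalisation), then one
#' column per SNP with dosages in `{0, 1, 2}`; missing genotypes coded
#' `NA` or `-9`.
#'
#' @param path CSV path.
#' @return Data frame with `fid`, `iid` and numeric SNP columns (missing as
#'   `NA`).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1:2] <- c("fid", "iid")
  df$fid <- as.character(df$fid)
  df$iid <- as.character(df$iid)
  for (j in seq(3, ncol(df))) {
    col <- df[[j]]
    if (is.character(col)) col[trimws(col) %in% c("NA", "")] <- NA
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop("non-numeric genotype token '", col[bad[1]], "' in column '",
           names(df)[j], "', row ", bad[1])
    }
    num[num == -9] <- NA
    ok <- is.na(num) | num %in% c(0, 1, 2)
    if (!all(ok)) {
      stop("genotype value ", num[which(!ok)[1]], " in column '",
           names(df)[j], "', row ", which(!ok)[1],
           " is not in {0, 1, 2, NA, -9}")
    }
    df[[j]] <- num
  }
  df
}

#' Read a phenotype/covariate CSV
#'
#' Expected layout: `FID`, `IID`, then phenotype, exposure and covariate
#' columns.
#'
#' @param path CSV path.
#' @return Data frame with `fid`, `iid` and the remaining columns as read.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1:2] <- c("fid", "iid")
  df$fid <- as.character(df$fid)
  df$iid <- as.character(df$iid)
  df
}

#' Load and align pedigree, genotypes and phenotypes into a design
#'
#' Joins the three inputs on the composite key (family id, individual id),
#' applies complete-case filtering on the phenotype, exposure, covariates
#' and every SNP of the gene, and restricts the kinship structure to the
#' retained individuals while keeping the full-pedigree kinship
#' coefficients (relatedness through dropped relatives is preserved). Rows
#' are returned in pedigree order regardless of input file order.
#'
#' @param pedigree A `fge_pedigree` or path to a PED-style file.
#' @param genotypes Data frame from [read_genotypes()] or a path.
#' @param phenotypes Data frame from [read_phenotype()] or a path.
#' @param phenotype Column name of the response.
#' @param exposure Column name of the environmental exposure.
#' @param covariates Character vector of covariate column names (possibly
#'   empty).
#' @return List with `design` (`fge_design`), `kin` (`fge_kinship`), and
#'   `dropped` (data frame of dropped individuals and reasons).
#' @export
load_design <- function(pedigree, genotypes, phenotypes,
                        phenotype = "Y", exposure = "E",
                        covariates = character()) {
  ped <- if (inherits(pedigree, "fge_pedigree")) pedigree else read_pedigree(pedigree)
  gen <- if (is.data.frame(genotypes)) genotypes else read_genotypes(genotypes)
  phe <- if (is.data.frame(phenotypes)) phenotypes else read_phenotype(phenotypes)
  for (col in c(phenotype, exposure, covariates)) {
    if (!col %in% names(phe)) stop("column '", col, "' not found in phenotype table")
  }
  keyp <- paste(ped$fid, ped$iid, sep = "\r")
  keyg <- paste(gen$fid, gen$iid, sep = "\r")
  keyy <- paste(phe$fid, phe$iid, sep = "\r")
  if (anyDuplicated(keyg)) stop("duplicate (FID, IID) rows in genotype file")
  if (anyDuplicated(keyy)) stop("duplicate (FID, IID) rows in phenotype file")
  orphan <- setdiff(keyy, keyp)
  if (length(orphan)) {
    stop("individual(s) present in phenotype table but not in pedigree: ",
         paste(utils::head(sub("\r", ":", orphan), 5), collapse = ", "))
  }

  snp_cols <- setdiff(names(gen), c("fid", "iid"))
  gi <- match(keyp, keyg)
  yi <- match(keyp, keyy)
  reason <- rep(NA_character_, nrow(ped))
  reason[is.na(gi)] <- "no genotype record"
  reason[is.na(yi)] <- "no phenotype record"
  gmat <- as.matrix(gen[gi, snp_cols, drop = FALSE])
  rownames(gmat) <- NULL
  miss_g <- rowSums(is.na(gmat)) > 0
  reason[is.na(reason) & miss_g] <- "missing genotype"
  pvals <- phe[yi, c(phenotype, exposure, covariates), drop = FALSE]
  miss_p <- rowSums(is.na(pvals)) > 0
  reason[is.na(reason) & miss_p] <- "missing phenotype/covariate"
  keep <- is.na(reason)
  if (!any(keep)) stop("all individuals dropped during complete-case filtering")

  dropped <- data.frame(fid = ped$fid[!keep], iid = ped$iid[!keep],
                        reason = reason[!keep], row.names = NULL)
  if (nrow(dropped)) {
    message(nrow(dropped), " individual(s) dropped: ",
            paste(sprintf("%s (%d)", names(table(dropped$reason)),
                          as.integer(table(dropped$reason))), collapse = ", "))
  }

  kin <- compute_kinship(ped)
  ids <- data.frame(fid = ped$fid[keep], iid = ped$iid[keep],
                    stringsAsFactors = FALSE)
  kin <- subset_kinship(kin, ids)
  X <- if (length(covariates)) {
    m <- as.matrix(pvals[keep, covariates, drop = FALSE])
    storage.mode(m) <- "double"
    m
  } else NULL
  design <- ge_design(Y = as.numeric(pvals[keep, phenotype]),
                      X = X,
                      E = as.numeric(pvals[keep, exposure]),
                      G = gmat[keep, , drop = FALSE],
                      ids = ids)
  list(design = design, kin = kin, dropped = dropped)
}

#' Write test results to JSON (and per-SNP CSV)
#'
#' Serialises one or more test results (`fge_vct`, `fge_competitor`) into a
#' single JSON file; a MinP result's per-SNP p-value table is written
#' alongside as CSV (same path with suffix `_per_snp.csv`).
#'
#' @param results A single result object or a named list of them.
#' @param path Output JSON path.
#' @return Invisibly, the list serialised.
#' @export
write_results <- function(results, path) {
  if (inherits(results, c("fge_vct", "fge_competitor"))) {
    results <- stats::setNames(list(results),
                               if (inherits(results, "fge_vct")) "vct"
                               else results$test_name)
  }
  out <- lapply(results, function(r) {
    if (inherits(r, "fge_vct")) {
      list(test = "vct", U_tau = r$U_tau, e = r$e, I_tau = r$I_tau,
           kappa = r$kappa, xi = r$xi, p_value = r$p_value,
           lambda_hat = r$lambda_hat, pi = as.list(r$pi), n = r$n, q = r$q)
    } else if (identical(r$test_name, "score_qdf")) {
      list(test = "score_qdf", statistic = r$statistic, df = r$df,
           p_value = r$p_value)
    } else {
      list(test = "minp", raw_min_p = r$raw_min_p, M_eff = r$M_eff,
           p_value = r$p_value)
    }
  })
  out$famGE_version <- as.character(utils::packageVersion("famGE"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (nm in names(results)) {
    r <- results[[nm]]
    if (inherits(r, "fge_competitor") && identical(r$test_name, "minp")) {
      utils::write.csv(r$per_snp,
                       sub("\\.json$", "_per_snp.csv", path),
                       row.names = FALSE)
    }
  }
  invisible(out)
}

#' Serialise a fitted null model
#'
#' Writes the scalar summary (fixed effects, variance components, implied
#' penalty, convergence) as JSON and the working vectors (ytilde, weights,
#' eta, mu, residuals) as CSV next to it, so a fit can be archived or
#' reused without refitting.
#'
#' @param fit A `fge_null`.
#' @param path JSON output path (the CSV lands at the same path with
#'   suffix `_vectors.csv`).
#' @return Invisibly, the JSON path.
#' @export
write_null_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fge_null"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(beta = as.list(fit$beta), pi = as.list(fit$pi), phi = fit$phi,
         lambda = fit$lambda, n = fit$n, q = fit$q,
         family = fit$family$family, converged = fit$converged,
         iter = fit$iter,
         famGE_version = as.character(utils::packageVersion("famGE"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  vec <- data.frame(ytilde = fit$ytilde, w = fit$w, eta = fit$eta,
                    mu = fit$mu, residuals = fit$residuals, Py = fit$Py)
  utils::write.csv(vec, sub("\\.json$", "_vectors.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Read back a serialised null-model summary
#'
#' @param path JSON path written by [write_null_fit()].
#' @return List with the scalar summary plus a `vectors` data frame.
#' @export
read_null_fit <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  vpath <- sub("\\.json$", "_vectors.csv", path)
  if (file.exists(vpath)) out$vectors <- utils::read.csv(vpath)
  out
}
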