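#' Read a PED-style pedigree file
#'
#' Parses the first five columns of a PLINK-style pedigree file
#' (`FID IID PAT MAT SEX`), whitespace- or comma-delimited. The missing
#' parent code is `"0"`; sex is coded `1` = male, `2` = female on input and
#' normalised to `"male"`/`"female"` internally. A header line is skipped
#' automatically when the first row is recognisably non-numeric in the sex
#' column.
#'
#' @param path Path to the pedigree file.
#' @return A `fge_pedigree` object: a data frame with columns `fid`, `iid`,
#'   `father`, `mother` (both `NA` when missing) and `sex`, rows grouped by
#'   family in file order, validated for parent resolution and acyclicity.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("pedigree file is empty: ", path)
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  split_row <- function(x) {
    if (sep == ",") trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    else strsplit(trimws(x), "[ \t]+")[[1]]
  }
  rows <- lapply(lines, split_row)
  ncols <- vapply(rows, length, integer(1))
  bad <- which(ncols < 5L)
  if (length(bad)) {
    stop("pedigree row ", bad[[1]], " has ", ncols[[bad[[1]]]],
         " fields; at least 5 (FID IID PAT MAT SEX) are required")
  }
  # header detection: sex column must be 1/2 on data rows
  first_sex <- rows[[1]][[5]]
  if (is.na(suppressWarnings(as.numeric(first_sex)))) {
    rows <- rows[-1]
    if (!length(rows)) stop("pedigree file has a header but no data rows")
  }
  fid    <- vapply(rows, `[[`, character(1), 1L)
  iid    <- vapply(rows, `[[`, character(1), 2L)
  father <- vapply(rows, `[[`, character(1), 3L)
  mother <- vapply(rows, `[[`, character(1), 4L)
  sex    <- vapply(rows, `[[`, character(1), 5L)
  new_pedigree(fid, iid, father, mother, sex)
}

#' Construct a pedigree object from vectors
#'
#' @param fid,iid Family and individual identifiers (coerced to character).
#' @param father,mother Parent identifiers; `"0"`, `""` or `NA` mean missing.
#' @param sex Sex codes: `1`/`"male"`/`"M"` or `2`/`"female"`/`"F"`.
#' @return A validated `fge_pedigree` data frame.
#' @export
new_pedigree <- function(fid, iid, father, mother, sex) {
  fid <- as.character(fid); iid <- as.character(iid)
  father <- as.character(father); mother <- as.character(mother)
  missing_code <- function(x) is.na(x) | x %in% c("0", "", "NA", "-9")
  father[missing_code(father)] <- NA_character_
  mother[missing_code(mother)] <- NA_character_
  sex <- normalize_sex(sex)
  ped <- data.frame(fid = fid, iid = iid, father = father, mother = mother,
                    sex = sex, stringsAsFactors = FALSE)
  # group rows by family, keeping within-family file order
  ped <- ped[order(match(ped$fid, unique(ped$fid))), , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("fge_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  if (anyNA(out)) {
    stop("unrecognised sex code(s): ",
         paste(unique(s[is.na(out)]), collapse = ", "),
         " (expected 1=male, 2=female)")
  }
  out
}

validate_pedigree <- function(ped) {
  key <- paste(ped$fid, ped$iid, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (family, individual) id pairs in pedigree: ",
         paste(utils::head(ped$iid[dup], 5), collapse = ", "))
  }
  for (f in unique(ped$fid)) {
    fam <- ped[ped$fid == f, , drop = FALSE]
    ids <- fam$iid
    for (col in c("father", "mother")) {
      par <- fam[[col]]
      bad <- !is.na(par) & !(par %in% ids)
      if (any(bad)) {
        i <- which(bad)[[1]]
        stop("family ", f, ", individual ", fam$iid[[i]], ": ", col, " id '",
             par[[i]], "' does not resolve to an individual in the family")
      }
    }
    topo_order_family(fam)  # errors on parentage cycles
  }
  invisible(ped)
}

# Kahn topological sort of one family's parentage digraph (ancestors first).
# Returns row indices into `fam`; errors if a cycle exists.
topo_order_family <- function(fam) {
  n <- nrow(fam)
  idx <- stats::setNames(seq_len(n), fam$iid)
  parents <- cbind(idx[fam$father], idx[fam$mother])  # NA when missing
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != n) {
    stop("cyclic parentage in family ", fam$fid[[1]], " involving: ",
         paste(fam$iid[indeg > 0], collapse = ", "))
  }
  out
}

#' @export
print.fge_pedigree <- function(x, ...) {
  cat("Pedigree: ", nrow(x), " individuals in ", length(unique(x$fid)),
      " famil", if (length(unique(x$fid)) == 1L) "y" else "ies", "\n", sep = "")
  founders <- is.na(x$father) & is.na(x$mother)
  cat("  founders: ", sum(founders), ", non-founders: ", sum(!founders),
      "\n", sep = "")
  invisible(x)
}

is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)
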