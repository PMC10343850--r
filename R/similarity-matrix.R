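#' Symmetric similarity matrix with optional missing entries
#'
#' Houses every similarity used by the pipeline: miRNA functional similarity
#' (possibly with missing entries), disease semantic similarity, GIP kernel
#' similarity, and the integrated matrices. Missing entries are stored as
#' `NA` in `values`.
#'
#' @param values square numeric matrix; `NA` marks a missing entry.
#' @param ids character identifiers for rows/columns.
#' @param check_diag if TRUE (default), require diagonal == 1 and non-missing.
#' @return An object of class `similarity_matrix` with elements `values`,
#'   `ids`, `missing` (logical mask).
#' @export
similarity_matrix <- function(values, ids, check_diag = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != ncol(values)) stopf("similarity matrix must be square")
  if (length(ids) != nrow(values)) stopf("ids length must match matrix dimension")
  if (anyDuplicated(ids)) stopf("duplicate ids")
  asym <- max(0, abs(values - t(values)), na.rm = TRUE)
  if (asym > 1e-8) stopf("similarity matrix not symmetric (max deviation %g)", asym)
  miss_asym <- is.na(values) != t(is.na(values))
  if (any(miss_asym)) stopf("missing-entry mask not symmetric")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stopf("similarity values outside [0,1]: range [%g, %g]", rng[1], rng[2])
  if (check_diag && (anyNA(diag(values)) || any(abs(diag(values) - 1) > 1e-9)))
    stopf("diagonal must be 1 and non-missing")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = as.character(ids),
                 missing = is.na(values)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, %d missing off-diagonal entries\n",
              length(x$ids), length(x$ids), sum(x$missing)))
  invisible(x)
}

#' Read a square similarity matrix from TSV
#'
#' The file has a header row of ids and a leading id column; empty cells or
#' `NA` mark missing entries. Asymmetric cell pairs deviating by more than
#' `1e-8` are symmetrized by averaging, with a warning. Values outside
#' `[0,1]` by more than `1e-6` trigger a warning and are clipped.
#'
#' @param path path to the TSV file.
#' @param expected_ids optional id universe; a mismatch is an error listing
#'   the offending ids.
#' @param check_diag passed to [similarity_matrix()].
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path, expected_ids = NULL, check_diag = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                   comment.char = "#", check.names = FALSE,
                   na.strings = c("", "NA"), colClasses = "character")
  ids <- rownames(df)
  if (!identical(sort(ids), sort(colnames(df))) || nrow(df) != ncol(df))
    stopf("similarity file is not square (rows %d, cols %d)", nrow(df), ncol(df))
  vals <- apply(as.matrix(df[, ids, drop = FALSE]), c(1, 2), as.numeric)
  if (!is.null(expected_ids)) {
    offenders <- c(setdiff(ids, expected_ids), setdiff(expected_ids, ids))
    if (length(offenders))
      stopf("similarity ids do not match the association universe: %s",
            paste(head(offenders, 10), collapse = ", "))
    vals <- vals[expected_ids, expected_ids]
    ids <- expected_ids
  }
  asym <- abs(vals - t(vals))
  if (max(0, asym, na.rm = TRUE) > 1e-8)
    warnf("asymmetric entries (max deviation %g) symmetrized by averaging",
          max(asym, na.rm = TRUE))
  vals <- (vals + t(vals)) / 2
  out_of_range <- pmax(vals - 1, -vals)
  if (max(0, out_of_range, na.rm = TRUE) > 1e-6)
    warnf("values outside [0,1] by up to %g clipped", max(out_of_range, na.rm = TRUE))
  vals <- pmin(pmax(vals, 0), 1)
  similarity_matrix(vals, ids, check_diag = check_diag)
}

#' Write a similarity matrix to TSV
#'
#' Full-precision (`%.17g`) export so that a write/read round trip is
#' bit-exact; missing entries are written as empty cells.
#'
#' @param sim a [similarity_matrix()].
#' @param path output path.
#' @export
write_similarity_matrix <- function(sim, path) {
  v <- sim$values
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  header <- paste(c("id", sim$ids), collapse = "\t")
  body <- vapply(seq_along(sim$ids), function(i)
    paste(c(sim$ids[i], fmt(v[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}
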