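#' Binary miRNA-disease association matrix
#'
#' Container for the bipartite adjacency matrix `A` (`nm` miRNAs by `nd`
#' diseases) with `A[i, j] = 1` iff miRNA `i` has a verified association with
#' disease `j`. Row `i` of `A` is the interaction profile of miRNA `i`;
#' column `j` is the interaction profile of disease `j`.
#'
#' @param A numeric matrix of 0/1 entries.
#' @param mirna_ids character vector of row identifiers (no duplicates).
#' @param disease_ids character vector of column identifiers (no duplicates).
#' @return An object of class `association_matrix`: a list with elements
#'   `A`, `mirna_ids`, `disease_ids`, `nm`, `nd`.
#' @export
association_matrix <- function(A, mirna_ids, disease_ids) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  if (anyDuplicated(mirna_ids)) stopf("duplicate miRNA ids")
  if (anyDuplicated(disease_ids)) stopf("duplicate disease ids")
  if (nrow(A) != length(mirna_ids) || ncol(A) != length(disease_ids))
    stopf("matrix dims (%d x %d) do not match id lists (%d, %d)",
          nrow(A), ncol(A), length(mirna_ids), length(disease_ids))
  if (!all(A %in% c(0, 1))) stopf("association matrix entries must be 0 or 1")
  dimnames(A) <- list(mirna_ids, disease_ids)
  structure(
    list(A = A, mirna_ids = as.character(mirna_ids),
         disease_ids = as.character(disease_ids),
         nm = nrow(A), nd = ncol(A)),
    class = "association_matrix"
  )
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> %d miRNAs x %d diseases, %d known associations\n",
              x$nm, x$nd, sum(x$A)))
  invisible(x)
}

#' Read a miRNA-disease pair list
#'
#' Reads a two-column TSV (`mirna_id<TAB>disease_id`, `#` comment lines
#' allowed) of verified associations and builds the adjacency matrix.
#' Identifier order is first appearance in the file, unless explicit id
#' universes are supplied, in which case ids are ordered lexicographically
#' over the universe (so that every matrix derived from one universe shares
#' one ordering).
#'
#' @param path path to the TSV pair file.
#' @param mirna_universe,disease_universe optional character vectors giving
#'   the full id universes (rows/columns present even with no association).
#' @return An [association_matrix()].
#' @export
read_association_pairs <- function(path, mirna_universe = NULL,
                                   disease_universe = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad))
    stopf("malformed row at line %d: expected 2 tab-separated columns", lineno[bad[1]])
  mir <- vapply(fields, `[[`, "", 1L)
  dis <- vapply(fields, `[[`, "", 2L)

  dup <- duplicated(paste(mir, dis, sep = "\r"))
  if (any(dup)) {
    warnf("%d duplicate pair(s) removed", sum(dup))
    mir <- mir[!dup]; dis <- dis[!dup]
  }

  if (is.null(mirna_universe)) mirna_universe <- unique(mir)
  else {
    mirna_universe <- sort(unique(as.character(mirna_universe)))
    if (!all(mir %in% mirna_universe))
      stopf("miRNA id(s) outside universe: %s",
            paste(head(setdiff(mir, mirna_universe), 5), collapse = ", "))
  }
  if (is.null(disease_universe)) disease_universe <- unique(dis)
  else {
    disease_universe <- sort(unique(as.character(disease_universe)))
    if (!all(dis %in% disease_universe))
      stopf("disease id(s) outside universe: %s",
            paste(head(setdiff(dis, disease_universe), 5), collapse = ", "))
  }

  A <- matrix(0, length(mirna_universe), length(disease_universe))
  if (length(mir))
    A[cbind(match(mir, mirna_universe), match(dis, disease_universe))] <- 1
  association_matrix(A, mirna_universe, disease_universe)
}

#' Write a pair list for an association matrix
#'
#' Inverse of [read_association_pairs()]: writes one `mirna<TAB>disease` row
#' per 1-entry, in row-major order.
#'
#' @param assoc an [association_matrix()].
#' @param path output path.
#' @export
write_association_pairs <- function(assoc, path) {
  ones <- which(t(assoc$A) == 1)  # row-major over A
  j <- (ones - 1) %% assoc$nd + 1
  i <- (ones - 1) %/% assoc$nd + 1
  writeLines(paste(assoc$mirna_ids[i], assoc$disease_ids[j], sep = "\t"), path)
  invisible(path)
}
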