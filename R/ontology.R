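#' Disease ontology (child-to-parent DAG)
#'
#' A global acyclic child-to-parent term graph, plus a mapping from disease
#' identifiers to ontology terms (identity by default). The per-disease
#' ancestor closure of this graph is the disease's DAG used by the semantic
#' similarity schemes.
#'
#' @param terms character vector of term identifiers.
#' @param parent_edges two-column matrix or data.frame of (child, parent)
#'   pairs; both endpoints must be registered terms.
#' @param disease_to_term optional named character vector mapping disease ids
#'   to terms; defaults to identity for every term.
#' @return An object of class `disease_ontology` with elements `terms`,
#'   `parent_edges` (2-col character matrix), `disease_to_term`, and `graph`
#'   (an igraph DAG with edges child -> parent).
#' @export
disease_ontology <- function(terms, parent_edges, disease_to_term = NULL) {
  terms <- unique(as.character(terms))
  pe <- as.matrix(parent_edges)
  if (length(pe) == 0) pe <- matrix(character(), 0, 2)
  if (ncol(pe) != 2) stopf("parent_edges must have two columns (child, parent)")
  mode(pe) <- "character"
  missing_terms <- setdiff(c(pe), terms)
  if (length(missing_terms))
    stopf("edge endpoint(s) not registered as terms: %s",
          paste(head(missing_terms, 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pe[, 1], to = pe[, 2], stringsAsFactors = FALSE),
    directed = TRUE, vertices = data.frame(name = terms)
  )
  if (!igraph::is_dag(g)) {
    member <- find_cycle_member(pe)
    stopf("ontology contains a cycle (involves term '%s')", member %||% "?")
  }
  if (is.null(disease_to_term)) {
    disease_to_term <- stats::setNames(terms, terms)
  }
  structure(
    list(terms = terms, parent_edges = pe,
         disease_to_term = disease_to_term, graph = g),
    class = "disease_ontology"
  )
}

# name one vertex on a directed cycle (used only for the error message)
find_cycle_member <- function(pe) {
  nodes <- unique(c(pe))
  # peel sinks (Kahn); leftovers lie on cycles
  remaining <- nodes
  edges <- pe
  repeat {
    children <- unique(edges[, 1])
    sinks <- setdiff(remaining, children)
    if (!length(sinks)) break
    remaining <- setdiff(remaining, sinks)
    edges <- edges[!(edges[, 2] %in% sinks), , drop = FALSE]
    if (!nrow(edges)) return(NULL)
  }
  remaining[1]
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat(sprintf("<disease_ontology> %d terms, %d parent edges\n",
              length(x$terms), nrow(x$parent_edges)))
  invisible(x)
}

#' Read ontology edges from a TSV file
#'
#' Each non-comment row is `child<TAB>parent`. Terms are the union of all
#' endpoints; isolated root terms may additionally be declared with a row
#' containing a single column.
#'
#' @param path path to the edge file.
#' @return A [disease_ontology()].
#' @export
read_ontology_edges <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf > 2)) stopf("ontology rows must have 1 or 2 columns")
  singles <- vapply(fields[nf == 1], `[[`, "", 1L)
  pe <- do.call(rbind, fields[nf == 2])
  if (is.null(pe)) pe <- matrix(character(), 0, 2)
  disease_ontology(unique(c(c(pe), singles)), pe)
}

#' Write ontology edges to TSV
#'
#' @param onto a [disease_ontology()].
#' @param path output path.
#' @export
write_ontology_edges <- function(onto, path) {
  roots <- setdiff(onto$terms, c(onto$parent_edges))
  lines <- c(paste(onto$parent_edges[, 1], onto$parent_edges[, 2], sep = "\t"),
             roots)
  writeLines(lines, path)
  invisible(path)
}
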