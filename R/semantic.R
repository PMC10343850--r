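#' Semantic similarity parameters
#'
#' @param mu semantic contribution decay factor, in (0, 1); each step from a
#'   disease to a parent multiplies the contribution by `mu`. Default 0.5,
#'   the standard choice for MeSH-style disease DAGs.
#' @param log_base base of the logarithm in the information-content scheme.
#'   Default `exp(1)` (natural log).
#' @return A list of class `semantic_params`.
#' @export
semantic_params <- function(mu = 0.5, log_base = exp(1)) {
  stopifnot(mu > 0, mu < 1, log_base > 1)
  structure(list(mu = mu, log_base = log_base), class = "semantic_params")
}

#' Ancestor closure of a disease in the ontology
#'
#' Returns the disease's DAG: the node set `G(d)` = the disease's term plus
#' every term reachable through child-to-parent edges, and the induced edge
#' set `E(d)`.
#'
#' @param onto a [disease_ontology()].
#' @param d disease identifier.
#' @return A list with `disease`, `nodes` (character, `d`'s term first),
#'   `edges` (2-col character matrix), or `NULL` if the disease has no
#'   ontology coverage (semantic similarity unavailable -- not an error).
#' @export
ancestor_closure <- function(onto, d) {
  term <- if (d %in% names(onto$disease_to_term)) onto$disease_to_term[[d]] else d
  if (!term %in% onto$terms) return(NULL)
  reach <- igraph::subcomponent(onto$graph, term, mode = "out")
  nodes <- igraph::V(onto$graph)$name[reach]
  nodes <- c(term, setdiff(nodes, term))
  keep <- onto$parent_edges[, 1] %in% nodes & onto$parent_edges[, 2] %in% nodes
  list(disease = d, nodes = nodes,
       edges = onto$parent_edges[keep, , drop = FALSE])
}

#' Wang-style semantic contributions within one disease DAG
#'
#' The disease's own term contributes 1; every ancestor `k` contributes
#' `mu * max(contribution of children of k within the DAG)`, computed by a
#' traversal in order of increasing distance from the disease. Equivalently,
#' `C1(k) = mu ^ (shortest child-to-parent path length from d to k)`.
#'
#' @param dag an ancestor closure from [ancestor_closure()].
#' @param params a [semantic_params()].
#' @return Named numeric vector of contributions over the DAG's nodes.
#' @export
semantic_contribution_wang <- function(dag, params = semantic_params()) {
  if (is.null(dag) || !length(dag$nodes)) stopf("empty DAG")
  mu <- params$mu
  c1 <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  c1[dag$nodes[1]] <- 1
  frontier <- dag$nodes[1]
  while (length(frontier)) {
    parents <- unique(dag$edges[dag$edges[, 1] %in% frontier, 2])
    parents <- parents[is.na(c1[parents])]
    for (p in parents) {
      kids <- dag$edges[dag$edges[, 2] == p, 1]
      c1[p] <- mu * max(c1[kids], na.rm = TRUE)
    }
    frontier <- parents
  }
  # nodes unreachable by the peeling above cannot occur in a closure
  stopifnot(!anyNA(c1))
  c1
}

#' Disease semantic value
#'
#' The sum of a disease's per-term contributions over its DAG; used as the
#' normalizer of both semantic similarity schemes.
#'
#' @param contributions named contribution vector (Wang or information-content).
#' @return A scalar.
#' @export
semantic_value <- function(contributions) {
  if (!length(contributions)) stopf("empty contribution map")
  sum(contributions)
}

#' Information-content contributions (shared across diseases)
#'
#' `NG(k)` counts how many disease DAGs contain term `k`; the contribution of
#' `k` is `-log(NG(k) / nd)`, so terms shared by every disease contribute 0
#' and rare terms contribute most. Unlike the Wang scheme the contribution is
#' a property of the term, not of the (disease, term) pair.
#'
#' @param onto a [disease_ontology()].
#' @param diseases character vector of disease ids (`nd = length(diseases)`).
#' @param params a [semantic_params()].
#' @return A list with `C2` (named numeric over all terms appearing in some
#'   DAG) and `closures` (per-disease ancestor closures, `NULL` where
#'   uncovered).
#' @export
semantic_contribution_xuan <- function(onto, diseases,
                                       params = semantic_params()) {
  stopifnot(length(diseases) >= 1)
  closures <- lapply(diseases, function(d) ancestor_closure(onto, d))
  names(closures) <- diseases
  all_nodes <- unlist(lapply(closures, `[[`, "nodes"), use.names = FALSE)
  if (!length(all_nodes))
    return(list(C2 = stats::setNames(numeric(0), character(0)),
                closures = closures))
  ng <- table(all_nodes)
  stopifnot(all(ng >= 1))
  c2 <- -log(as.numeric(ng) / length(diseases), base = params$log_base)
  list(C2 = stats::setNames(c2, names(ng)), closures = closures)
}

#' Disease semantic similarity matrix
#'
#' For each disease pair, the similarity is the summed contribution of
#' shared DAG terms from both sides, normalized by the two disease semantic
#' values. Scheme `"wang"` uses the decay contributions; scheme `"xuan"`
#' uses the information-content contributions. Pairs where either disease
#' lacks ontology coverage are missing (the integrated similarity falls back
#' to the GIP kernel there); the diagonal is always 1.
#'
#' @param onto a [disease_ontology()].
#' @param diseases character vector of disease ids.
#' @param params a [semantic_params()].
#' @param scheme `"wang"` or `"xuan"`.
#' @return A [similarity_matrix()] over `diseases`.
#' @export
semantic_similarity <- function(onto, diseases, params = semantic_params(),
                                scheme = c("wang", "xuan")) {
  scheme <- match.arg(scheme)
  nd <- length(diseases)
  xu <- semantic_contribution_xuan(onto, diseases, params)
  closures <- xu$closures
  contribs <- vector("list", nd)
  for (i in seq_len(nd)) {
    if (is.null(closures[[i]])) next
    contribs[[i]] <- if (scheme == "wang") {
      semantic_contribution_wang(closures[[i]], params)
    } else {
      xu$C2[closures[[i]]$nodes]
    }
  }
  dsv <- vapply(contribs, function(cc) if (is.null(cc)) NA_real_
                else semantic_value(cc), 0)
  S <- matrix(NA_real_, nd, nd)
  for (i in seq_len(nd)) {
    if (is.null(contribs[[i]])) next
    for (j in seq_len(nd)) {
      if (j < i || is.null(contribs[[j]])) next
      shared <- intersect(names(contribs[[i]]), names(contribs[[j]]))
      denom <- dsv[i] + dsv[j]
      val <- if (denom == 0) 0
             else sum(contribs[[i]][shared] + contribs[[j]][shared]) / denom
      S[i, j] <- S[j, i] <- val
    }
  }
  diag(S) <- 1
  similarity_matrix(S, diseases)
}

#' Combine the two semantic similarity schemes
#'
#' Elementwise mean of the decay-based and information-content matrices; an
#' entry is missing if it is missing in either input.
#'
#' @param dss1,dss2 [similarity_matrix()] objects over the same ids, in the
#'   same order.
#' @return A [similarity_matrix()].
#' @export
combined_semantic_similarity <- function(dss1, dss2) {
  if (!identical(dss1$ids, dss2$ids)) stopf("id mismatch between schemes")
  similarity_matrix((dss1$values + dss2$values) / 2, dss1$ids)
}
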