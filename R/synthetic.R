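#' Synthetic data generators
#'
#' These generators emulate the three pipeline inputs -- a disease ontology,
#' a binary association matrix, and a miRNA functional-similarity matrix with
#' missing entries -- so that every downstream stage can be exercised and
#' benchmarked without any database download. All generators are pure
#' functions of their parameters and seed.
#'
#' @name synthetic
NULL

#' Generate a random ontology forest
#'
#' Terms are created in index order `t1..tn`; each non-root term receives
#' between 1 and `max_parents` parents chosen uniformly among earlier-indexed
#' terms, so the result is acyclic by construction. Term `t1` is always a
#' root.
#'
#' @param n_terms number of terms (>= 1).
#' @param max_parents maximum parents per non-root term (>= 1).
#' @param seed integer seed.
#' @param root_prob probability that a later term is an additional root.
#' @param prefix term-name prefix (default `"t"`; use `"d"` to make terms
#'   coincide with generated disease ids).
#' @return A [disease_ontology()].
#' @export
generate_ontology <- function(n_terms, max_parents = 2, seed = 1,
                              root_prob = 0.1, prefix = "t") {
  stopifnot(n_terms >= 1, max_parents >= 1)
  terms <- sprintf("%s%d", prefix, seq_len(n_terms))
  edges <- withr::with_seed(seed, {
    out <- list()
    for (k in seq_len(n_terms)[-1]) {
      if (runif(1) < root_prob) next
      np <- sample.int(min(max_parents, k - 1L), 1L)
      parents <- sample.int(k - 1L, np)
      out[[length(out) + 1L]] <- cbind(terms[k], terms[parents])
    }
    do.call(rbind, out)
  })
  if (is.null(edges)) edges <- matrix(character(), 0, 2)
  disease_ontology(terms, edges)
}

#' Generate a planted low-rank association matrix
#'
#' Latent factors `U` (`nm x rank`) and `V` (`nd x rank`) are drawn standard
#' normal and each association is Bernoulli with success probability
#' `sigmoid(signal * <U_i, V_j> / sqrt(rank) + bias)`. The bias is calibrated
#' by bisection so that the expected density matches `density`; with
#' `signal = 0` the entries are i.i.d. Bernoulli(density).
#'
#' @param nm,nd numbers of miRNAs and diseases (>= 2).
#' @param rank latent dimension (>= 1).
#' @param density target fraction of 1-entries, in (0, 1).
#' @param signal non-negative signal strength; 0 gives pure noise.
#' @param seed integer seed.
#' @return A list with `assoc` (an [association_matrix()]) and `model` (the
#'   planted model: `U`, `V`, `bias`, `scale`, `density_target`), for use in
#'   recovery benchmarks.
#' @export
generate_associations <- function(nm, nd, rank = 5, density = 0.1,
                                  signal = 6, seed = 1) {
  stopifnot(nm >= 2, nd >= 2, rank >= 1, density > 0, density < 1, signal >= 0)
  withr::with_seed(seed, {
    U <- matrix(rnorm(nm * rank), nm, rank)
    V <- matrix(rnorm(nd * rank), nd, rank)
    logits0 <- signal * tcrossprod(U, V) / sqrt(rank)
    # bisection on the bias so mean(sigmoid(logits0 + bias)) == density
    lo <- -50; hi <- 50
    f <- function(b) mean(sigmoid(logits0 + b)) - density
    for (it in seq_len(100)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-12) break
    }
    bias <- (lo + hi) / 2
    if (abs(f(bias)) > 0.2 * density)
      stopf("density calibration failed (target %.3f, achieved %.3f)",
            density, f(bias) + density)
    P <- sigmoid(logits0 + bias)
    A <- matrix(as.numeric(runif(nm * nd) < P), nm, nd)
    assoc <- association_matrix(A, sprintf("m%d", seq_len(nm)),
                                sprintf("d%d", seq_len(nd)))
    model <- list(U = U, V = V, bias = bias, scale = signal / sqrt(rank),
                  density_target = density)
    list(assoc = assoc, model = model)
  })
}

#' Generate a functional-similarity matrix from planted latent factors
#'
#' `MFS(i, j) = (1 + cosine(U_i, U_j)) / 2`, rescaling cosine similarity of
#' the planted miRNA factors to `[0, 1]`; the diagonal is 1. A random
#' symmetric subset of off-diagonal pairs (fraction `missing_frac`) is
#' masked missing, emulating miRNAs absent from a functional-similarity
#' resource.
#'
#' @param model a planted model as returned by [generate_associations()].
#' @param missing_frac fraction of off-diagonal pairs to mask, in `[0, 1)`.
#' @param seed integer seed.
#' @param ids optional ids (defaults to `m1..mnm`).
#' @return A [similarity_matrix()].
#' @export
generate_functional_similarity <- function(model, missing_frac = 0, seed = 1,
                                           ids = NULL) {
  stopifnot(missing_frac >= 0, missing_frac < 1)
  U <- model$U
  norms <- sqrt(rowSums(U^2))
  if (any(norms == 0)) stopf("zero-norm latent row: cosine undefined")
  Un <- U / norms
  S <- (1 + tcrossprod(Un)) / 2
  S <- pmin(pmax((S + t(S)) / 2, 0), 1)
  diag(S) <- 1
  nm <- nrow(S)
  if (missing_frac > 0 && nm > 1) {
    pairs <- which(upper.tri(S), arr.ind = TRUE)
    n_mask <- round(missing_frac * nrow(pairs))
    masked <- withr::with_seed(seed, sample.int(nrow(pairs), n_mask))
    S[pairs[masked, , drop = FALSE]] <- NA
    S[pairs[masked, c(2, 1), drop = FALSE]] <- NA
  }
  similarity_matrix(S, ids %||% sprintf("m%d", seq_len(nm)))
}

#' Hand-checkable worked example
#'
#' A fixed 4 miRNA x 3 disease fixture used throughout the unit tests:
#' diseases `d1` and `d2` share a parent term `p`, while `d3` has no
#' ontology coverage at all, so its semantic similarities are missing and
#' the integrated disease similarity falls back to the GIP kernel there;
#' the association matrix has 6 known pairs; the
#' functional-similarity matrix is fully specified except `MFS(m1, m2)`,
#' which is missing so the integrated-similarity fallback path is exercised.
#'
#' @return A list with `assoc`, `onto`, `mfs`.
#' @export
make_worked_example <- function() {
  A <- rbind(c(1, 0, 0),
             c(1, 1, 0),
             c(0, 1, 1),
             c(0, 0, 1))
  assoc <- association_matrix(A, c("m1", "m2", "m3", "m4"),
                              c("d1", "d2", "d3"))
  onto <- disease_ontology(
    terms = c("d1", "d2", "p"),   # d3 deliberately uncovered
    parent_edges = rbind(c("d1", "p"), c("d2", "p"))
  )
  mfs_vals <- rbind(
    c(1.0,  NA, 0.2, 0.1),
    c(NA,  1.0, 0.5, 0.3),
    c(0.2, 0.5, 1.0, 0.6),
    c(0.1, 0.3, 0.6, 1.0))
  mfs <- similarity_matrix(mfs_vals, c("m1", "m2", "m3", "m4"))
  list(assoc = assoc, onto = onto, mfs = mfs)
}
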