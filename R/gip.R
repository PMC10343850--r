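#' GIP kernel bandwidth
#'
#' The Gaussian interaction-profile bandwidth is the numerator `alpha_prime`
#' divided by the mean squared norm of the binary interaction profiles, so
#' the kernel adapts to the overall density of the association network.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param alpha_prime bandwidth numerator (> 0); default 1.
#' @return The bandwidth `alpha` (scalar).
#' @export
gip_bandwidth <- function(profiles, alpha_prime = 1) {
  stopifnot(alpha_prime > 0)
  profiles <- as.matrix(profiles)
  msn <- mean(rowSums(profiles^2))
  if (msn == 0) stopf("degenerate interaction profiles (all zero)")
  alpha_prime / msn
}

#' GIP kernel similarity matrix
#'
#' `KS(i, j) = exp(-alpha * ||IP_i - IP_j||^2)` over interaction profiles.
#' The diagonal is exactly 1 and there are no missing entries.
#'
#' @param profiles numeric matrix, one profile per row.
#' @param alpha bandwidth (> 0); typically from [gip_bandwidth()].
#' @param ids optional row identifiers.
#' @return A [similarity_matrix()].
#' @export
gip_kernel <- function(profiles, alpha, ids = NULL) {
  stopifnot(alpha > 0)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2 <- pmax(d2, 0)
  K <- exp(-alpha * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  similarity_matrix(K, ids %||% rownames(profiles) %||% sprintf("p%d", seq_len(n)))
}

#' GIP kernels for both sides of an association matrix
#'
#' Convenience wrapper computing the miRNA kernel (over rows of `A`) and the
#' disease kernel (over columns of `A`), each with its own bandwidth.
#'
#' @param assoc an [association_matrix()].
#' @param alpha_prime_m,alpha_prime_d bandwidth numerators; default 1.
#' @return A list with `KSM` and `KSD` ([similarity_matrix()] objects).
#' @export
gip_similarities <- function(assoc, alpha_prime_m = 1, alpha_prime_d = 1) {
  list(
    KSM = gip_kernel(assoc$A, gip_bandwidth(assoc$A, alpha_prime_m),
                     ids = assoc$mirna_ids),
    KSD = gip_kernel(t(assoc$A), gip_bandwidth(t(assoc$A), alpha_prime_d),
                     ids = assoc$disease_ids)
  )
}

#' Integrate a primary similarity with its GIP kernel
#'
#' Where the primary similarity (functional or semantic) exists, the result
#' is the mean of primary and GIP values; where it is missing, the GIP value
#' is used alone. Applied identically on the miRNA side (functional + miRNA
#' GIP) and the disease side (semantic + disease GIP).
#'
#' @param primary a [similarity_matrix()], possibly with missing entries.
#' @param gip a [similarity_matrix()] with no missing entries.
#' @return A [similarity_matrix()] with no missing entries.
#' @export
integrate_similarity <- function(primary, gip) {
  if (!identical(primary$ids, gip$ids)) stopf("id mismatch")
  if (any(gip$missing)) stopf("GIP matrix must have no missing entries")
  v <- ifelse(primary$missing, gip$values, (primary$values + gip$values) / 2)
  similarity_matrix(v, primary$ids)
}
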