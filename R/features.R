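#' Pairwise feature representation for miRNA-disease pairs
#'
#' Each pair (miRNA `i`, disease `j`) is represented by the concatenation of
#' four blocks: the integrated miRNA-similarity row `MS[i, ]` (`nm` values),
#' the disease interaction profile `A[, j]` (`nm` values), the integrated
#' disease-similarity row `DS[j, ]` (`nd` values), and the miRNA interaction
#' profile `A[i, ]` (`nd` values) -- `2 * (nm + nd)` columns in total. With
#' `mask_target = TRUE` the two positions inside the profile blocks that
#' hold the pair's own association status `A[i, j]` are zeroed, removing the
#' label from its own feature vector (required for honest recovery and
#' case-study evaluation; the default `FALSE` keeps the literal
#' construction).
#'
#' @param MS integrated miRNA [similarity_matrix()] (`nm x nm`).
#' @param DS integrated disease [similarity_matrix()] (`nd x nd`).
#' @param assoc an [association_matrix()].
#' @param pairs two-column integer matrix of (miRNA index, disease index).
#' @param y optional labels; defaults to `A[i, j]` for each pair.
#' @param mask_target zero the pair's own entries in the profile blocks.
#' @return An object of class `pair_feature_set`: list with `pairs`, `X`
#'   (one row per pair), `y`, `layout` (named block widths), `mask_target`.
#' @export
build_pair_features <- function(MS, DS, assoc, pairs, y = NULL,
                                mask_target = FALSE) {
  nm <- assoc$nm; nd <- assoc$nd
  if (length(MS$ids) != nm || length(DS$ids) != nd)
    stopf("similarity dims do not match association matrix (%d x %d)", nm, nd)
  if (any(MS$missing) || any(DS$missing))
    stopf("integrated similarities must have no missing entries")
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stopf("pairs must have two columns")
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) &&
      (min(pairs) < 1 || max(pairs[, 1]) > nm || max(pairs[, 2]) > nd))
    stopf("pair indices out of range")
  i <- pairs[, 1]; j <- pairs[, 2]
  A <- assoc$A
  X <- cbind(MS$values[i, , drop = FALSE],        # MS_i  (nm)
             t(A)[j, , drop = FALSE],             # A_.j  (nm)
             DS$values[j, , drop = FALSE],        # DS_j  (nd)
             A[i, , drop = FALSE])                # A_i.  (nd)
  if (is.null(y)) y <- A[pairs]
  y <- as.numeric(y)
  if (mask_target && nrow(pairs)) {
    rows <- seq_len(nrow(pairs))
    X[cbind(rows, nm + i)] <- 0           # position i inside A_.j block
    X[cbind(rows, 2 * nm + nd + j)] <- 0  # position j inside A_i. block
  }
  dimnames(X) <- NULL
  structure(
    list(pairs = pairs, X = X, y = y,
         layout = c(MS_row = nm, A_col = nm, DS_row = nd, A_row = nd),
         mask_target = mask_target),
    class = "pair_feature_set"
  )
}

#' @export
print.pair_feature_set <- function(x, ...) {
  cat(sprintf("<pair_feature_set> %d pairs x %d features (%d positive), mask_target=%s\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), x$mask_target))
  invisible(x)
}

#' Sample negative pairs uniformly from the unknown associations
#'
#' Draws `n` distinct pairs with `A[i, j] == 0`, uniformly without
#' replacement; used to balance the positive set before training.
#'
#' @param assoc an [association_matrix()].
#' @param n number of negatives; must not exceed the number of 0-entries.
#' @param seed integer seed.
#' @return Two-column integer matrix of (miRNA index, disease index).
#' @export
sample_negatives <- function(assoc, n, seed = 1) {
  zeros <- which(assoc$A == 0)
  if (n > length(zeros))
    stopf("requested %d negatives but only %d unknown pairs exist",
          n, length(zeros))
  chosen <- withr::with_seed(seed, sample(zeros, n))
  cbind((chosen - 1L) %% assoc$nm + 1L, (chosen - 1L) %/% assoc$nm + 1L)
}

#' All pairs of an association matrix, with labels
#'
#' @param assoc an [association_matrix()].
#' @param label 1, 0, or NULL for both.
#' @return Two-column integer matrix of pair indices.
#' @export
association_pairs <- function(assoc, label = NULL) {
  idx <- if (is.null(label)) seq_along(assoc$A) else which(assoc$A == label)
  cbind((idx - 1L) %% assoc$nm + 1L, (idx - 1L) %/% assoc$nm + 1L)
}

#' Balanced labeled pair sample
#'
#' All positive pairs plus an equal number of sampled negatives.
#'
#' @param assoc an [association_matrix()].
#' @param seed seed for negative sampling.
#' @return Two-column pair matrix with attribute `y`.
#' @export
balanced_pairs <- function(assoc, seed = 1) {
  pos <- association_pairs(assoc, label = 1)
  neg <- sample_negatives(assoc, nrow(pos), seed = seed)
  structure(rbind(pos, neg), y = rep(c(1, 0), c(nrow(pos), nrow(neg))))
}

#' Stratified train/test split
#'
#' @param fs a `pair_feature_set`.
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed.
#' @return List with `train` and `test` `pair_feature_set`s.
#' @export
split_train_test <- function(fs, ratio = 0.8, seed = 1) {
  y <- fs$y
  if (length(y) < 5) stopf("need at least 5 samples to split")
  if (any(table(y) < 2)) stopf("each class needs at least 2 members")
  hold <- stratified_holdout(y, 1 - ratio, seed)
  list(train = subset_feature_set(fs, !hold),
       test = subset_feature_set(fs, hold))
}

subset_feature_set <- function(fs, idx) {
  structure(list(pairs = fs$pairs[idx, , drop = FALSE],
                 X = fs$X[idx, , drop = FALSE],
                 y = fs$y[idx], layout = fs$layout,
                 mask_target = fs$mask_target),
            class = "pair_feature_set")
}

#' Stratified k-fold partition
#'
#' Assigns each sample to one of `k` folds so that fold sizes differ by at
#' most one and class proportions are preserved per fold.
#'
#' @param y binary label vector (or a `pair_feature_set`).
#' @param k number of folds (default 4).
#' @param seed integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
kfold_partition <- function(y, k = 4, seed = 1) {
  if (inherits(y, "pair_feature_set")) y <- y$y
  stopifnot(k >= 2)
  folds <- integer(length(y))
  withr::with_seed(seed, {
    offset <- 0L
    for (cl in unique(y)) {
      members <- sample(which(y == cl))
      # rotate the fold cycle between classes so overall sizes differ by <= 1
      folds[members] <- (seq_along(members) - 1L + offset) %% k + 1L
      offset <- offset + length(members)
    }
  })
  folds
}
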