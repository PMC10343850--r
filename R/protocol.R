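#' Integrated similarity matrices for a dataset
#'
#' Computes disease semantic similarity (both schemes, combined), the two
#' GIP kernels, and the integrated miRNA/disease similarities.
#'
#' @param assoc an [association_matrix()].
#' @param onto a [disease_ontology()] (or NULL: semantic similarity entirely
#'   missing, disease similarity falls back to the GIP kernel).
#' @param mfs optional miRNA functional [similarity_matrix()] (may contain
#'   missing entries); NULL means all missing.
#' @param params a [semantic_params()].
#' @param alpha_prime_m,alpha_prime_d GIP bandwidth numerators.
#' @return List with `MS`, `DS` (integrated) and intermediates `DSS1`,
#'   `DSS2`, `DSS`, `KSM`, `KSD`.
#' @export
compute_similarities <- function(assoc, onto = NULL, mfs = NULL,
                                 params = semantic_params(),
                                 alpha_prime_m = 1, alpha_prime_d = 1) {
  gip <- gip_similarities(assoc, alpha_prime_m, alpha_prime_d)
  all_missing <- function(ids) {
    v <- matrix(NA_real_, length(ids), length(ids)); diag(v) <- 1
    similarity_matrix(v, ids)
  }
  if (is.null(onto)) {
    dss1 <- dss2 <- dss <- all_missing(assoc$disease_ids)
  } else {
    dss1 <- semantic_similarity(onto, assoc$disease_ids, params, "wang")
    dss2 <- semantic_similarity(onto, assoc$disease_ids, params, "xuan")
    dss <- combined_semantic_similarity(dss1, dss2)
  }
  if (is.null(mfs)) mfs <- all_missing(assoc$mirna_ids)
  if (!identical(mfs$ids, assoc$mirna_ids))
    stopf("functional-similarity ids do not match the association universe")
  list(MS = integrate_similarity(mfs, gip$KSM),
       DS = integrate_similarity(dss, gip$KSD),
       DSS1 = dss1, DSS2 = dss2, DSS = dss, KSM = gip$KSM, KSD = gip$KSD)
}

#' Pipeline configuration
#'
#' Bundles the stacked-autoencoder and cascade settings used by
#' [fit_pipeline()], [run_protocol()] and [case_study()].
#'
#' @param sae_dims code dimensions (NULL = scaled default, see [sae_dims()]).
#' @param sae_epochs,sae_batch,sae_lr autoencoder training settings.
#' @param cascade a [cascade_config()].
#' @param seed master seed; SAE and cascade seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sae_dims = NULL, sae_epochs = 50, sae_batch = 128,
                            sae_lr = 1e-3, cascade = cascade_config(),
                            seed = 1) {
  cascade$seed <- derive_seed(seed, 2)
  structure(list(sae_dims = sae_dims, sae_epochs = sae_epochs,
                 sae_batch = sae_batch, sae_lr = sae_lr,
                 cascade = cascade, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Fit the SAE + cascade pipeline on labeled pair features
#'
#' @param X raw pair-feature matrix.
#' @param y binary labels.
#' @param config a [pipeline_config()].
#' @return List of class `mda_pipeline` with `stack` and `cascade`.
#' @export
fit_pipeline <- function(X, y, config = pipeline_config()) {
  stack <- fit_sae(X, dims = config$sae_dims, epochs = config$sae_epochs,
                   batch = config$sae_batch, lr = config$sae_lr,
                   seed = derive_seed(config$seed, 1))
  Z <- encode(stack, X)
  model <- fit_cascade(Z, y, config$cascade)
  structure(list(stack = stack, cascade = model), class = "mda_pipeline")
}

#' Score new pairs with a fitted pipeline
#'
#' @param pipeline an `mda_pipeline`.
#' @param X raw pair-feature matrix.
#' @return Scores in `[0, 1]`.
#' @export
predict_pipeline <- function(pipeline, X) {
  predict_proba(pipeline$cascade, encode(pipeline$stack, X))
}

#' Split / cross-validation evaluation protocol
#'
#' Splits the balanced sample 8:2 (stratified) into training and test sets,
#' runs stratified 4-fold cross validation on the training set (the SAE and
#' cascade are refitted on each 3/4, the held-out quarter is only
#' transformed and scored), then refits on the full training set and scores
#' the test set once.
#'
#' By default the GIP kernels (and hence the features in `fs`) are computed
#' once globally. With `gip_per_fold = TRUE` (requires `data`), the strict
#' variant is run instead: for every fold -- and for the final test
#' evaluation -- the labels of the pairs under evaluation are zeroed in the
#' association matrix before the similarities and features are recomputed,
#' so no evaluated pair's own label can reach any feature column.
#'
#' @param fs a `pair_feature_set` (balanced sample).
#' @param config a [pipeline_config()].
#' @param ratio train fraction (default 0.8).
#' @param k CV folds (default 4).
#' @param gip_per_fold recompute GIP similarities per evaluation unit,
#'   excluding evaluated-pair labels (default FALSE: once globally).
#' @param data required when `gip_per_fold = TRUE`: list with `assoc`, and
#'   optionally `onto` and `mfs`, from which features are recomputed.
#' @return List with `cv_reports` (one `metrics_report` per fold), `cv_mean`
#'   (fieldwise mean of the fold reports), `test_report`, `split_sizes`.
#' @export
run_protocol <- function(fs, config = pipeline_config(), ratio = 0.8, k = 4,
                         gip_per_fold = FALSE, data = NULL) {
  if (gip_per_fold && is.null(data$assoc))
    stopf("gip_per_fold = TRUE requires data = list(assoc, onto, mfs)")
  sp <- split_train_test(fs, ratio = ratio, seed = derive_seed(config$seed, 31))
  folds <- kfold_partition(sp$train$y, k = k, seed = derive_seed(config$seed, 32))
  fold_sets <- function(eval_pairs, train_fs, eval_fs) {
    if (!gip_per_fold) return(list(train = train_fs, eval = eval_fs))
    A2 <- data$assoc$A
    A2[eval_pairs] <- 0
    assoc2 <- association_matrix(A2, data$assoc$mirna_ids,
                                 data$assoc$disease_ids)
    sims <- compute_similarities(assoc2, data$onto, data$mfs)
    list(train = build_pair_features(sims$MS, sims$DS, assoc2,
                                     train_fs$pairs, y = train_fs$y,
                                     mask_target = fs$mask_target),
         eval = build_pair_features(sims$MS, sims$DS, assoc2,
                                    eval_fs$pairs, y = eval_fs$y,
                                    mask_target = fs$mask_target))
  }
  cv_reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    cfg_f <- config
    cfg_f$seed <- derive_seed(config$seed, 100 + f)
    cfg_f$cascade$seed <- derive_seed(cfg_f$seed, 2)
    parts <- fold_sets(sp$train$pairs[!tr, , drop = FALSE],
                       subset_feature_set(sp$train, tr),
                       subset_feature_set(sp$train, !tr))
    pipe <- fit_pipeline(parts$train$X, parts$train$y, cfg_f)
    scores <- predict_pipeline(pipe, parts$eval$X)
    cv_reports[[f]] <- confusion_metrics(parts$eval$y, scores)
  }
  cv_mean <- mean_report(cv_reports)
  parts <- fold_sets(sp$test$pairs, sp$train, sp$test)
  pipe <- fit_pipeline(parts$train$X, parts$train$y, config)
  test_scores <- predict_pipeline(pipe, parts$eval$X)
  list(cv_reports = cv_reports, cv_mean = cv_mean,
       test_report = confusion_metrics(parts$eval$y, test_scores),
       test_scores = test_scores, test_y = parts$eval$y,
       split_sizes = c(train = length(sp$train$y), test = length(sp$test$y)))
}

mean_report <- function(reports) {
  fields <- c("TP", "TN", "FP", "FN", "acc", "pre", "sen", "spe",
              "mcc", "f1", "auc", "aupr", "threshold")
  out <- lapply(fields, function(f)
    mean(vapply(reports, `[[`, 0, f)))
  structure(stats::setNames(out, fields), class = "metrics_report")
}

#' Leave-one-disease-out case study
#'
#' Removes every trace of the target disease (its column of the association
#' matrix is zeroed and all its pairs leave the labeled pool), recomputes
#' the GIP kernels and integrated similarities from the masked matrix,
#' trains the pipeline on a balanced sample of the remaining pairs (target
#' masking on, so no feature encodes its own label), scores every
#' (miRNA, target disease) pair, and returns the top `top_k` candidates by
#' descending score (ties broken by miRNA id).
#'
#' @param disease_id the held-out disease.
#' @param assoc an [association_matrix()] (unmasked; used only to report the
#'   held-out known associations for verification).
#' @param onto a [disease_ontology()] or NULL.
#' @param mfs optional functional [similarity_matrix()].
#' @param config a [pipeline_config()].
#' @param top_k number of candidates to return (default 50).
#' @param params a [semantic_params()].
#' @param reuse_global_similarity if FALSE (default), every similarity and
#'   feature is recomputed from the masked matrix -- the strict, leak-free
#'   protocol under which the scores provably contain no information from
#'   the held-out column. If TRUE, similarities and interaction-profile
#'   feature blocks are taken from the unmasked matrix (only the scored
#'   pair's own entry is still masked); this lax variant mirrors protocols
#'   that compute similarities once globally, and lets verified neighbours
#'   in the held-out column inform the ranking.
#' @return A list of class `ranked_predictions` with `disease_id`, `ranking`
#'   (data.frame rank / mirna_id / score) and `masked_known` (ids of the
#'   held-out true associations).
#' @export
case_study <- function(disease_id, assoc, onto = NULL, mfs = NULL,
                       config = pipeline_config(), top_k = 50,
                       params = semantic_params(),
                       reuse_global_similarity = FALSE) {
  j <- match(disease_id, assoc$disease_ids)
  if (is.na(j)) stopf("unknown disease '%s'", disease_id)
  masked_known <- assoc$mirna_ids[assoc$A[, j] == 1]
  A_masked <- assoc$A
  A_masked[, j] <- 0
  assoc_m <- association_matrix(A_masked, assoc$mirna_ids, assoc$disease_ids)
  if (sum(assoc_m$A) == 0) stopf("no known associations left for training")

  assoc_feat <- if (reuse_global_similarity) assoc else assoc_m
  sims <- compute_similarities(assoc_feat, onto, mfs, params)
  pos <- association_pairs(assoc_m, label = 1)
  # negatives drawn outside the held-out column: its pairs are scoring
  # targets, not training material
  neg_pool <- which(assoc_m$A == 0)
  neg_pool <- neg_pool[((neg_pool - 1L) %/% assoc_m$nm + 1L) != j]
  if (nrow(pos) > length(neg_pool)) stopf("not enough negatives outside the held-out disease")
  chosen <- withr::with_seed(derive_seed(config$seed, 55),
                             sample(neg_pool, nrow(pos)))
  neg <- cbind((chosen - 1L) %% assoc_m$nm + 1L, (chosen - 1L) %/% assoc_m$nm + 1L)
  pairs <- rbind(pos, neg)
  y <- rep(c(1, 0), c(nrow(pos), nrow(neg)))
  fs <- build_pair_features(sims$MS, sims$DS, assoc_feat, pairs, y = y,
                            mask_target = TRUE)
  pipe <- fit_pipeline(fs$X, fs$y, config)

  cand <- cbind(seq_len(assoc_m$nm), rep(j, assoc_m$nm))
  fs_cand <- build_pair_features(sims$MS, sims$DS, assoc_feat, cand,
                                 y = rep(0, assoc_m$nm), mask_target = TRUE)
  scores <- predict_pipeline(pipe, fs_cand$X)
  ord <- order(-scores, assoc$mirna_ids)
  keep <- head(ord, top_k)
  structure(list(disease_id = disease_id,
                 ranking = data.frame(rank = seq_along(keep),
                                      mirna_id = assoc$mirna_ids[keep],
                                      score = scores[keep],
                                      stringsAsFactors = FALSE),
                 masked_known = masked_known),
            class = "ranked_predictions")
}

#' @export
print.ranked_predictions <- function(x, ...) {
  cat(sprintf("<ranked_predictions> disease %s, top %d candidates (%d known held out)\n",
              x$disease_id, nrow(x$ranking), length(x$masked_known)))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Write a ranked-prediction table to TSV
#'
#' @param rp a `ranked_predictions` object.
#' @param path output path.
#' @export
write_ranked_predictions <- function(rp, path) {
  df <- rp$ranking
  lines <- c("rank\tmirna_id\tscore",
             sprintf("%d\t%s\t%.17g", df$rank, df$mirna_id, df$score))
  writeLines(lines, path)
  invisible(path)
}

#' Export a metrics report (or list of reports) as JSON
#'
#' @param x a `metrics_report` or named list of them.
#' @param path output path.
#' @export
write_metrics_json <- function(x, path) {
  unclass_deep <- function(z) if (inherits(z, "metrics_report")) unclass(z)
                              else lapply(z, unclass_deep)
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
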