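#' Cascade forest configuration
#'
#' @param mode `"svm"` -- the full model: four diverse estimators per level
#'   and a polynomial-kernel SVM predictor; `"average"` -- same diverse
#'   estimator bank but the prediction is the mean of the four class
#'   vectors (ablation: estimator modification only); `"classic"` -- the
#'   traditional cascade-forest bank (2 bagged + 2 completely random tree
#'   forests) with the averaging predictor (ablation: no modification).
#'   `"model1"` and `"model2"` are accepted as aliases for `"classic"` and
#'   `"average"`.
#' @param trees_per_estimator trees in each of the four ensembles (default
#'   100, i.e. 400 trees per level).
#' @param inner_folds folds of the per-estimator cross validation that
#'   produces out-of-fold class vectors (default 5).
#' @param max_levels maximum cascade depth (default 10).
#' @param patience consecutive non-improving levels tolerated before growth
#'   stops (default 1).
#' @param tol minimal validation-AUC improvement that counts (default 1e-3).
#' @param val_fraction fraction of the training data held out (stratified)
#'   to drive cascade growth (default 0.2).
#' @param svm_input `"concat"` (default): the SVM sees the original features
#'   plus the 8 augmented columns; `"augmented_only"`: the 8 columns alone.
#' @param svm_degree,svm_cost,svm_coef0 polynomial-kernel SVM
#'   hyperparameters; `coef0 = 1` (inhomogeneous polynomial) with internal
#'   feature standardization keeps the kernel well conditioned on
#'   tanh-scaled codes.
#' @param seed integer seed; all folds, estimator seeds and the SVM fit
#'   derive from it.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(mode = c("svm", "average", "classic",
                                    "model1", "model2"),
                           trees_per_estimator = 100, inner_folds = 5,
                           max_levels = 10, patience = 1, tol = 1e-3,
                           val_fraction = 0.2, svm_input = c("concat", "augmented_only"),
                           svm_degree = 3, svm_cost = 1, svm_coef0 = 1,
                           seed = 1) {
  mode <- match.arg(mode)
  mode <- switch(mode, model1 = "classic", model2 = "average", mode)
  structure(list(mode = mode, trees_per_estimator = trees_per_estimator,
                 inner_folds = inner_folds, max_levels = max_levels,
                 patience = patience, tol = tol, val_fraction = val_fraction,
                 svm_input = match.arg(svm_input), svm_degree = svm_degree,
                 svm_cost = svm_cost, svm_coef0 = svm_coef0,
                 seed = as.integer(seed)),
            class = "cascade_config")
}

estimator_bank <- function(mode) {
  if (mode == "classic") c("rf", "rf", "crt", "crt")
  else c("rf", "crt", "xgb", "lgbm")
}

# ranger requires named covariates; use positional names consistently
named_cols <- function(X) {
  colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  X
}

fit_estimator <- function(name, X, y, trees, seed) {
  X <- named_cols(X)
  yf <- factor(y, levels = c(0, 1))
  switch(name,
    rf = ranger::ranger(x = X, y = yf, probability = TRUE, num.trees = trees,
                        seed = seed, num.threads = 1),
    crt = ranger::ranger(x = X, y = yf, probability = TRUE, num.trees = trees,
                         splitrule = "extratrees", num.random.splits = 1,
                         mtry = 1, seed = seed, num.threads = 1),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = trees),
    lgbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", tree_method = "hist",
                    grow_policy = "lossguide", max_leaves = 31, max_depth = 0,
                    eta = 0.1, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = trees),
    stopf("unknown estimator '%s'", name))
}

predict_estimator <- function(name, fit, X) {
  X <- named_cols(X)
  if (name %in% c("rf", "crt")) {
    p <- predict(fit, data = X, num.threads = 1)$predictions
    cbind(p[, "0"], p[, "1"])
  } else {
    p1 <- predict(fit, xgboost::xgb.DMatrix(X))
    cbind(1 - p1, p1)
  }
}

#' Fit one cascade level
#'
#' Trains the level's four estimators, each under stratified
#' `inner_folds`-fold cross validation, and returns the out-of-fold class
#' vectors: for each sample, the class-probability pair predicted by the
#' fold model that did not train on it, concatenated across estimators in
#' bank order with class order (P0, P1) -- 8 columns for the standard bank.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (both classes present).
#' @param config a [cascade_config()].
#' @param seed level seed.
#' @return List with `level` (fitted level: per-estimator fold models) and
#'   `oof` (N x 8 out-of-fold class vectors).
#' @export
fit_level <- function(X, y, config = cascade_config(), seed = config$seed) {
  if (length(unique(y)) < 2) stopf("both classes must be present")
  k <- config$inner_folds
  if (nrow(X) < k) stopf("fewer samples than inner folds")
  bank <- estimator_bank(config$mode)
  folds <- kfold_partition(y, k = k, seed = derive_seed(seed, 101))
  if (any(vapply(seq_len(k), function(f)
    length(unique(y[folds != f])) < 2 || sum(folds == f) == 0, TRUE)))
    stopf("stratification failed: a fold is missing a class")
  oof <- matrix(NA_real_, nrow(X), 2 * length(bank))
  models <- vector("list", length(bank))
  for (e in seq_along(bank)) {
    models[[e]] <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_estimator(bank[e], X[tr, , drop = FALSE], y[tr],
                           config$trees_per_estimator,
                           derive_seed(seed, 1000 * e + f))
      models[[e]][[f]] <- fit
      oof[!tr, (2 * e - 1):(2 * e)] <-
        predict_estimator(bank[e], fit, X[!tr, , drop = FALSE])
    }
  }
  level <- structure(list(bank = bank, models = models, in_dim = ncol(X),
                          inner_folds = k),
                     class = "cascade_level")
  list(level = level, oof = oof, folds = folds)
}

#' Class-vector block for new data
#'
#' Each estimator's prediction on new data is the mean of its fold models'
#' class-probability outputs; blocks are concatenated in bank order.
#'
#' @param level a fitted `cascade_level`.
#' @param X_new matrix with the level's input width.
#' @return Matrix of augmented class vectors (`nrow(X_new)` x 8).
#' @export
transform_level <- function(level, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != level$in_dim)
    stopf("input has %d columns; level expects %d", ncol(X_new), level$in_dim)
  blocks <- lapply(seq_along(level$bank), function(e) {
    preds <- lapply(level$models[[e]], function(fit)
      predict_estimator(level$bank[e], fit, X_new))
    Reduce(`+`, preds) / length(preds)
  })
  do.call(cbind, blocks)
}

positive_cols <- function(aug) aug[, seq(2, ncol(aug), by = 2), drop = FALSE]

#' Fit the full cascade forest
#'
#' Carves a stratified validation split from the training data; grows
#' levels, feeding each level the original features plus the previous
#' level's out-of-fold class vectors; stops when the validation AUC fails to
#' improve by more than `tol` for `patience` consecutive levels (or at
#' `max_levels`) and rolls back to the best level count. In `"svm"` mode a
#' polynomial-kernel SVM with probability calibration is then fitted on the
#' best level's concatenated representation; in the averaging modes the
#' predictor is the mean of the final level's positive-class entries.
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param config a [cascade_config()].
#' @return An object of class `cascade_model` with `levels`, `n_levels`,
#'   `growth_log` (validation AUC per trained level, including rolled-back
#'   ones), `best_level`, `predictor` (SVM fit or NULL), `config`.
#' @export
fit_cascade <- function(X, y, config = cascade_config()) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stopf("both classes must be present")
  seed <- config$seed
  hold <- stratified_holdout(y, config$val_fraction, derive_seed(seed, 7))
  X_tr <- X[!hold, , drop = FALSE]; y_tr <- y[!hold]
  X_val <- X[hold, , drop = FALSE]; y_val <- y[hold]

  levels_ <- list(); oofs <- list(); growth <- numeric(0)
  aug_tr <- NULL; aug_val <- NULL
  bad_streak <- 0
  for (t in seq_len(config$max_levels)) {
    Xin_tr <- if (is.null(aug_tr)) X_tr else cbind(X_tr, aug_tr)
    Xin_val <- if (is.null(aug_val)) X_val else cbind(X_val, aug_val)
    lf <- fit_level(Xin_tr, y_tr, config, seed = derive_seed(seed, 10 + t))
    aug_val_new <- transform_level(lf$level, Xin_val)
    score <- roc_auc(y_val, rowMeans(positive_cols(aug_val_new)))
    if (!is.finite(score)) stopf("non-finite validation metric at level %d", t)
    levels_[[t]] <- lf$level
    oofs[[t]] <- lf$oof
    growth[t] <- score
    best_prev <- if (t == 1) -Inf else max(growth[seq_len(t - 1)])
    if (score > best_prev + config$tol) bad_streak <- 0
    else bad_streak <- bad_streak + 1
    if (bad_streak >= config$patience) break
    aug_tr <- lf$oof
    aug_val <- aug_val_new
  }
  best_level <- which.max(growth)

  predictor <- NULL
  if (config$mode == "svm") {
    rep_tr <- switch(config$svm_input,
                     concat = cbind(X_tr, oofs[[best_level]]),
                     augmented_only = oofs[[best_level]])
    predictor <- withr::with_seed(derive_seed(seed, 999), {
      e1071::svm(x = rep_tr, y = factor(y_tr, levels = c(0, 1)),
                 kernel = "polynomial", degree = config$svm_degree,
                 cost = config$svm_cost, coef0 = config$svm_coef0,
                 probability = TRUE, scale = TRUE)
    })
  }
  structure(list(levels = levels_[seq_len(best_level)],
                 n_levels = best_level, growth_log = growth,
                 best_level = best_level, predictor = predictor,
                 config = config),
            class = "cascade_model")
}

#' Predict association probabilities with a fitted cascade
#'
#' Passes the data through every retained level (recomputing the augmented
#' class vectors with [transform_level()]) and returns the SVM class-1
#' probability (`"svm"` mode) or the mean positive-class vote (averaging
#' modes).
#'
#' @param model a `cascade_model`.
#' @param X_new feature matrix with the model's original input width.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_proba <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  aug <- NULL
  for (lvl in model$levels) {
    Xin <- if (is.null(aug)) X_new else cbind(X_new, aug)
    aug <- transform_level(lvl, Xin)
  }
  if (model$config$mode == "svm") {
    rep_new <- switch(model$config$svm_input,
                      concat = cbind(X_new, aug),
                      augmented_only = aug)
    pr <- predict(model$predictor, rep_new, probability = TRUE)
    unname(attr(pr, "probabilities")[, "1"])
  } else {
    rowMeans(positive_cols(aug))
  }
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> mode=%s, %d level(s) retained (of %d trained), val AUC %.4f\n",
              x$config$mode, x$n_levels, length(x$growth_log),
              max(x$growth_log)))
  invisible(x)
}
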