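# Gradient-boosted regression of editing efficiency with grouped nested
# cross-validation. The outer loop partitions *target mutations* (group =
# genomic position + target allele), never rows, so designs of one
# mutation can never straddle a train/test boundary; the inner loop tunes
# hyperparameters on the outer-training groups only.

#' Default hyperparameter grid
#'
#' The tuned XGBoost parameters and their candidate values:
#' max_depth 2/5/9/14, learning_rate 0.01/0.1, min_child_weight 1/5/10,
#' colsample_bylevel, colsample_bytree and subsample 0.2/0.6/1,
#' reg_alpha 0/0.1/1, reg_lambda 0/1/2 (3888 combinations).
#'
#' @return named list of candidate-value vectors.
#' @export
default_grid <- function() {
  list(max_depth = c(2L, 5L, 9L, 14L),
       learning_rate = c(0.01, 0.1),
       min_child_weight = c(1, 5, 10),
       colsample_bylevel = c(0.2, 0.6, 1),
       colsample_bytree = c(0.2, 0.6, 1),
       subsample = c(0.2, 0.6, 1),
       reg_alpha = c(0, 0.1, 1),
       reg_lambda = c(0, 1, 2))
}

#' Validate a training table
#'
#' A training table has a `group_id` column (target-mutation key:
#' genomic position + target allele), the feature columns of one schema,
#' and `efficiency` in percent.
#'
#' @param table data.frame.
#' @param schema feature names expected (default: full 23).
#' @return the table, invisibly, or an error.
#' @export
validate_training_table <- function(table, schema = feature_schema("full")) {
  stopifnot(is.data.frame(table))
  need <- c("group_id", schema, "efficiency")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("training table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!nzchar(table$group_id))) stop("training table: empty group_id")
  X <- as.matrix(table[, schema])
  if (any(!is.finite(X))) stop("training table: non-finite feature values")
  if (any(table$efficiency < 0 | table$efficiency > 100))
    stop("training table: efficiency outside [0, 100]")
  invisible(table)
}

# Assign groups to k folds, balanced by group count, seeded.
group_folds <- function(groups, k, seed) {
  ug <- unique(groups)
  if (length(ug) < k)
    stop("fewer groups (", length(ug), ") than folds (", k,
         "); reduce the fold count or supply more target mutations")
  set.seed(seed)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(ug))[
    sample.int(length(ug))], ug)
  unname(fold_of[groups])
}

assert_no_leakage <- function(groups, train_idx, test_idx) {
  shared <- intersect(unique(groups[train_idx]), unique(groups[test_idx]))
  if (length(shared) > 0)
    stop("group leakage detected: ", paste(head(shared, 3), collapse = ", "))
  invisible(TRUE)
}

fit_booster <- function(X, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgb_params <- list(objective = "reg:squarederror",
                     max_depth = params$max_depth, eta = params$learning_rate,
                     min_child_weight = params$min_child_weight,
                     colsample_bylevel = params$colsample_bylevel,
                     colsample_bytree = params$colsample_bytree,
                     subsample = params$subsample, alpha = params$reg_alpha,
                     lambda = params$reg_lambda, nthread = 1,
                     seed = as.integer(seed))
  xgboost::xgb.train(params = xgb_params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

sample_grid <- function(grid, n_candidates, seed) {
  full <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(full) > n_candidates) {
    set.seed(seed)
    full <- full[sort(sample.int(nrow(full), n_candidates)), , drop = FALSE]
  }
  rownames(full) <- NULL
  full
}

inner_select <- function(X, y, groups, candidates, inner_k, nrounds, seed) {
  folds <- group_folds(groups, inner_k, derive_seed(seed, 11L))
  scores <- numeric(nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    rho <- numeric(inner_k)
    for (f in seq_len(inner_k)) {
      tr <- which(folds != f); te <- which(folds == f)
      assert_no_leakage(groups, tr, te)
      bst <- fit_booster(X[tr, , drop = FALSE], y[tr],
                         as.list(candidates[ci, ]), nrounds,
                         derive_seed(seed, 100L + ci))
      pred <- predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
      rho[f] <- if (sd(pred) == 0 || sd(y[te]) == 0) 0 else
        cor(pred, y[te], method = "spearman")
    }
    scores[ci] <- mean(rho)
  }
  which.max(scores)
}

#' Train an efficiency model under grouped nested cross-validation
#'
#' Outer loop: `outer_k`-fold cross-validation splitting *groups* (target
#' mutations), with held-out Spearman and Pearson correlations reported
#' per fold. Inner loop: `inner_k`-fold grouped CV over a randomized
#' sample of the hyperparameter grid (capped at `n_candidates`; raise it
#' to the full grid size for an exhaustive search). The final model is
#' refit on all rows with the parameter set selected most often across
#' outer folds. Fully seeded: fold assignment, grid sampling and tree
#' fitting all derive from `seed`.
#'
#' @param table training table (see [validate_training_table()]).
#' @param model_type `"pe3"` (all 23 features) or `"pe2"` (drops
#'   `ngrna_pos` and `is_PE3b`).
#' @param grid hyperparameter grid, default [default_grid()].
#' @param outer_k,inner_k fold counts.
#' @param n_candidates randomized-search cap on grid points.
#' @param nrounds boosting rounds.
#' @param seed integer seed.
#' @return an `efficiency_model`: the fitted ensemble, feature schema,
#'   training config and `cv_report` (per-fold held-out correlations and
#'   chosen parameters).
#' @export
nested_cv_train <- function(table, model_type = c("pe3", "pe2"),
                            grid = default_grid(), outer_k = 5L, inner_k = 3L,
                            n_candidates = 60L, nrounds = 500L, seed = 1L) {
  model_type <- match.arg(model_type)
  schema <- feature_schema(model_type)
  validate_training_table(table, schema)
  X <- as.matrix(table[, schema]); y <- table$efficiency
  groups <- as.character(table$group_id)
  candidates <- sample_grid(grid, n_candidates, derive_seed(seed, 5L))
  folds <- group_folds(groups, outer_k, derive_seed(seed, 7L))
  report <- list(); chosen <- integer(outer_k)
  for (f in seq_len(outer_k)) {
    tr <- which(folds != f); te <- which(folds == f)
    assert_no_leakage(groups, tr, te)
    ci <- inner_select(X[tr, , drop = FALSE], y[tr], groups[tr], candidates,
                       inner_k, nrounds, derive_seed(seed, 1000L + f))
    chosen[f] <- ci
    bst <- fit_booster(X[tr, , drop = FALSE], y[tr],
                       as.list(candidates[ci, ]), nrounds,
                       derive_seed(seed, 2000L + f))
    pred <- predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
    report[[f]] <- data.frame(
      fold = f, n_test = length(te), n_test_groups = length(unique(groups[te])),
      spearman = cor(pred, y[te], method = "spearman"),
      pearson = cor(pred, y[te]),
      params = paste(names(candidates), candidates[ci, ], sep = "=",
                     collapse = ";"))
  }
  cv_report <- do.call(rbind, report)
  best_ci <- as.integer(names(which.max(table(chosen))))
  final_params <- as.list(candidates[best_ci, ])
  final <- fit_booster(X, y, final_params, nrounds, derive_seed(seed, 3000L))
  new_efficiency_model(final, schema, model_type, final_params,
                       list(outer_k = outer_k, inner_k = inner_k,
                            n_candidates = n_candidates, nrounds = nrounds,
                            seed = seed),
                       cv_report)
}

new_efficiency_model <- function(booster, schema, model_type, params, config,
                                 cv_report) {
  structure(list(booster = booster, schema = schema,
                 schema_id = schema_id(schema), model_type = model_type,
                 params = params, config = config, cv_report = cv_report),
            class = "efficiency_model")
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat(sprintf("<efficiency_model> %s, %d features, %d rounds\n",
              toupper(x$model_type), length(x$schema), x$config$nrounds))
  if (!is.null(x$cv_report))
    cat(sprintf("  held-out Spearman: %s (mean %.3f)\n",
                paste(sprintf("%.3f", x$cv_report$spearman), collapse = " "),
                mean(x$cv_report$spearman)))
  invisible(x)
}

#' Train with an externally supplied train/test split
#'
#' Honors precomputed split labels (e.g. the splits shipped with a public
#' training set): hyperparameters are tuned by grouped inner CV on the
#' training rows only, the final model is fit on them, and test-set
#' Spearman/Pearson are reported.
#'
#' @param table training table.
#' @param split_labels character vector (`"train"`/`"test"`), one per row.
#' @inheritParams nested_cv_train
#' @return an `efficiency_model` with a one-row `cv_report` for the test
#'   set.
#' @export
train_test_split_train <- function(table, split_labels,
                                   model_type = c("pe3", "pe2"),
                                   grid = default_grid(), inner_k = 3L,
                                   n_candidates = 60L, nrounds = 500L,
                                   seed = 1L) {
  model_type <- match.arg(model_type)
  schema <- feature_schema(model_type)
  validate_training_table(table, schema)
  if (length(split_labels) != nrow(table) ||
      any(!split_labels %in% c("train", "test")))
    stop("train_test_split_train: every row needs a 'train' or 'test' label")
  tr <- which(split_labels == "train"); te <- which(split_labels == "test")
  if (length(te) == 0L) stop("train_test_split_train: empty test set")
  if (length(tr) == 0L) stop("train_test_split_train: empty training set")
  X <- as.matrix(table[, schema]); y <- table$efficiency
  groups <- as.character(table$group_id)
  candidates <- sample_grid(grid, n_candidates, derive_seed(seed, 5L))
  ci <- inner_select(X[tr, , drop = FALSE], y[tr], groups[tr], candidates,
                     inner_k, nrounds, derive_seed(seed, 1500L))
  bst <- fit_booster(X[tr, , drop = FALSE], y[tr], as.list(candidates[ci, ]),
                     nrounds, derive_seed(seed, 2500L))
  pred <- predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
  cv_report <- data.frame(
    fold = NA_integer_, n_test = length(te),
    n_test_groups = length(unique(groups[te])),
    spearman = cor(pred, y[te], method = "spearman"), pearson = cor(pred, y[te]),
    params = paste(names(candidates), candidates[ci, ], sep = "=",
                   collapse = ";"))
  new_efficiency_model(bst, schema, model_type, as.list(candidates[ci, ]),
                       list(inner_k = inner_k, n_candidates = n_candidates,
                            nrounds = nrounds, seed = seed, split = "external"),
                       cv_report)
}

#' Predict editing efficiency (%)
#'
#' @param object an `efficiency_model`.
#' @param newdata data.frame or matrix carrying the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of efficiencies, clipped to \[0, 100\].
#' @export
predict.efficiency_model <- function(object, newdata, ...) {
  miss <- setdiff(object$schema, colnames(newdata))
  if (length(miss) > 0)
    stop("predict: feature schema mismatch; missing: ",
         paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, object$schema, drop = FALSE])
  if (any(!is.finite(X))) stop("predict: non-finite feature values")
  pmin(100, pmax(0, predict(object$booster, xgboost::xgb.DMatrix(X))))
}

#' Persist an efficiency model to a single file
#'
#' The booster is serialized through xgboost's raw format together with
#' the feature schema, training config and CV report, so a reloaded model
#' predicts bit-identically and still refuses mismatched schemas.
#'
#' @param model an `efficiency_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_efficiency_model <- function(model, path) {
  stopifnot(inherits(model, "efficiency_model"))
  obj <- model
  obj$booster <- xgboost::xgb.save.raw(model$booster)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a persisted efficiency model
#' @param path file written by [save_efficiency_model()].
#' @return an `efficiency_model`.
#' @export
load_efficiency_model <- function(path) {
  obj <- readRDS(path)
  if (!is.raw(obj$booster)) stop("load_efficiency_model: not a model file")
  obj$booster <- xgboost::xgb.load.raw(obj$booster)
  class(obj) <- "efficiency_model"
  obj
}

#' SHAP feature attribution for a model
#'
#' Per-feature mean absolute SHAP value (TreeSHAP contributions) over the
#' supplied rows, ranked descending, plus the combined RNA-folding
#' aggregate (sum of the ten `fold_d*` means) used for simplified
#' reporting.
#'
#' @param model an `efficiency_model`.
#' @param table data.frame carrying the model's feature columns.
#' @return an `attribution_report`: list with `per_feature` (data.frame
#'   `feature`, `mean_abs_shap`, sorted descending) and `fold_aggregate`.
#' @export
explain <- function(model, table) {
  stopifnot(inherits(model, "efficiency_model"))
  X <- as.matrix(as.data.frame(table)[, model$schema, drop = FALSE])
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(X),
                     predcontrib = TRUE)
  contrib <- contrib[, seq_along(model$schema), drop = FALSE]  # drop BIAS
  m <- colMeans(abs(contrib))
  names(m) <- model$schema
  per <- data.frame(feature = names(m), mean_abs_shap = unname(m),
                    stringsAsFactors = FALSE)
  per <- per[order(-per$mean_abs_shap), ]
  rownames(per) <- NULL
  fold <- grepl("^fold_d", names(m))
  structure(list(per_feature = per, fold_aggregate = sum(m[fold])),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report> top features by mean |SHAP|:\n")
  print(head(x$per_feature, 8), row.names = FALSE)
  cat(sprintf("  combined RNA-folding aggregate: %.4f\n", x$fold_aggregate))
  invisible(x)
}
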