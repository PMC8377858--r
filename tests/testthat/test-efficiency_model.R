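# small fabricated training table: features drawn directly, efficiency a
# simple monotone function; enough for protocol/robustness tests that do
# not need the full generator
quick_table <- function(n = 300L, groups = 30L, seed = 71L, noise = 3) {
  set.seed(seed)
  g <- sprintf("g%02d", sample.int(groups, n, TRUE))
  X <- matrix(runif(n * 23), n, 23,
              dimnames = list(NULL, feature_schema("full")))
  X[, "pbs_len"] <- sample(8:17, n, TRUE)
  X[, "rtt_len"] <- sample(10:30, n, TRUE)
  X[, "is_dPAM"] <- rbinom(n, 1, 0.3)
  X[, "is_PE3b"] <- rbinom(n, 1, 0.1)
  X[, "target_pos"] <- sample(1:25, n, TRUE)
  X[, "ngrna_pos"] <- sample(-100:100, n, TRUE)
  eff <- pmin(100, pmax(0, 40 + 30 * X[, "cas9_score"] -
                          25 * X[, "fold_d1"] + rnorm(n, 0, noise)))
  out <- data.frame(group_id = g, X)
  out$efficiency <- eff
  out
}

test_that("training tables are validated", {
  tab <- quick_table()
  expect_silent(validate_training_table(tab))
  bad <- tab; bad$efficiency[1] <- 120
  expect_error(validate_training_table(bad), "efficiency")
  bad <- tab; bad$cas9_score[2] <- NA
  expect_error(validate_training_table(bad), "non-finite")
  bad <- tab[, -1]
  expect_error(validate_training_table(bad), "group_id")
})

test_that("outer folds partition groups with no leakage", {
  tab <- quick_table(n = 120L, groups = 10L)
  m <- nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                       outer_k = 5L, nrounds = 30L, seed = 1L)
  # every group appears in exactly one outer test fold
  expect_equal(sum(m$cv_report$n_test), nrow(tab))
  expect_equal(sum(m$cv_report$n_test_groups), length(unique(tab$group_id)))
  # fewer groups than folds is refused with guidance
  tiny <- quick_table(n = 40L, groups = 3L)
  expect_error(nested_cv_train(tiny, outer_k = 5L, n_candidates = 2L,
                               nrounds = 10L), "fewer groups")
})

test_that("training is reproducible for a fixed seed", {
  tab <- quick_table(n = 150L, groups = 15L)
  m1 <- nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                        outer_k = 3L, nrounds = 30L, seed = 5L)
  m2 <- nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                        outer_k = 3L, nrounds = 30L, seed = 5L)
  expect_identical(m1$cv_report, m2$cv_report)
  expect_identical(predict(m1, tab), predict(m2, tab))
  m3 <- nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                        outer_k = 3L, nrounds = 30L, seed = 6L)
  expect_false(identical(m1$cv_report$spearman, m3$cv_report$spearman))
})

test_that("prediction enforces the schema and the percent range", {
  tab <- quick_table(n = 150L, groups = 15L)
  m <- nested_cv_train(tab, model_type = "pe2", n_candidates = 2L,
                       outer_k = 3L, nrounds = 30L, seed = 2L)
  p <- predict(m, tab)
  expect_true(all(p >= 0 & p <= 100))
  expect_true(all(is.finite(p)))
  expect_error(predict(m, tab[, 1:5]), "schema")
  # PE2 model must not require the ngRNA-specific columns
  expect_silent(predict(m, tab[, c(feature_schema("pe2"))]))
})

test_that("persisted models reload to bit-identical predictions", {
  tab <- quick_table(n = 1000L, groups = 40L, seed = 73L)
  m <- nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                       outer_k = 3L, nrounds = 40L, seed = 3L)
  path <- tempfile(fileext = ".rds")
  save_efficiency_model(m, path)
  m2 <- load_efficiency_model(path)
  expect_identical(predict(m, tab), predict(m2, tab))
  expect_identical(m2$schema_id, m$schema_id)
  expect_identical(m2$cv_report, m$cv_report)
  expect_error(suppressWarnings(load_efficiency_model(tempfile())),
               "cannot open|No such")
})

test_that("external train/test splits are honored", {
  tab <- quick_table(n = 200L, groups = 20L)
  groups <- unique(tab$group_id)
  test_groups <- groups[1:4]
  labels <- ifelse(tab$group_id %in% test_groups, "test", "train")
  m <- train_test_split_train(tab, labels, model_type = "pe3",
                              n_candidates = 2L, nrounds = 30L, seed = 4L)
  expect_equal(m$cv_report$n_test, sum(labels == "test"))
  expect_equal(m$cv_report$n_test_groups, length(test_groups))
  m2 <- train_test_split_train(tab, labels, model_type = "pe3",
                               n_candidates = 2L, nrounds = 30L, seed = 4L)
  expect_identical(m$cv_report$spearman, m2$cv_report$spearman)
  expect_error(train_test_split_train(tab, rep("train", nrow(tab))),
               "empty test")
  expect_error(train_test_split_train(tab, labels[-1]), "label")
})

test_that("attribution reflects signal and respects report arithmetic", {
  # only cas9_score and fold_d1 carry signal in the quick table
  tab <- quick_table(n = 400L, groups = 30L, seed = 75L, noise = 2)
  m <- nested_cv_train(tab, model_type = "pe3", n_candidates = 2L,
                       outer_k = 3L, nrounds = 80L, seed = 8L)
  rep <- explain(m, tab)
  expect_s3_class(rep, "attribution_report")
  expect_true(all(diff(rep$per_feature$mean_abs_shap) <= 0))
  expect_true(all(rep$per_feature$feature[1:2] %in%
                    c("cas9_score", "fold_d1")))
  # aggregate equals the sum of its folding parts
  fold_rows <- grepl("^fold_d", rep$per_feature$feature)
  expect_equal(rep$fold_aggregate,
               sum(rep$per_feature$mean_abs_shap[fold_rows]))
  # a constant feature receives (near) zero attribution
  tab2 <- tab; tab2$n_ins <- 0
  m2 <- nested_cv_train(tab2, model_type = "pe3", n_candidates = 2L,
                        outer_k = 3L, nrounds = 40L, seed = 8L)
  rep2 <- explain(m2, tab2)
  expect_equal(rep2$per_feature$mean_abs_shap[
    rep2$per_feature$feature == "n_ins"], 0, tolerance = 1e-8)
})

test_that("higher-signal designs outrank lower-signal designs in prediction", {
  m <- fx_models()$pe3
  tab <- fx_models()$table
  set.seed(76)
  wins <- 0L
  for (i in 1:200) {
    base <- tab[sample.int(nrow(tab), 1), feature_schema("full")]
    hi <- base; lo <- base
    hi$cas9_score <- 0.9; lo$cas9_score <- 0.1
    hi$fold_d1 <- 0.02;  lo$fold_d1 <- 0.6
    hi$pbs_gc <- 0.65;   lo$pbs_gc <- 0.2
    hi$is_dPAM <- 1;     lo$is_dPAM <- 0
    hi$target_pos <- 2;  lo$target_pos <- 14
    wins <- wins + (predict(m, hi) > predict(m, lo))
  }
  expect_gte(wins, 190L)
})
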