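# Training, prediction contracts, cross-validation bookkeeping, recursive
# feature elimination, and persistence. Small planted-signal matrices keep
# these fast; the full-scale recovery runs live in test-acceptance.R.

small_sim <- function(n = 300, p = 40, k = 5, noise = 1, seed = 101) {
  simulate_feature_matrix(n = n, p = p, k_signal = k, noise_sd = noise,
                          seed = seed)
}

test_that("training recovers a strong planted signal on the training set", {
  sim <- small_sim(noise = 0)
  fit <- train_tm_model(sim$X, sim$y, seed = 3)
  p <- predict(fit, sim$X)
  expect_gt(pcc(p, sim$y), 0.99)
})

test_that("a constant target is predicted as that constant", {
  sim <- small_sim()
  y <- rep(50, nrow(sim$X))
  fit <- train_tm_model(sim$X, y, seed = 3)
  expect_equal(predict(fit, sim$X), rep(50, nrow(sim$X)), tolerance = 1e-6)
})

test_that("training and prediction are deterministic for a fixed seed", {
  sim <- small_sim()
  f1 <- train_tm_model(sim$X, sim$y, seed = 7)
  f2 <- train_tm_model(sim$X, sim$y, seed = 7)
  expect_identical(predict(f1, sim$X), predict(f2, sim$X))
})

test_that("training validates its inputs", {
  sim <- small_sim(n = 20)
  expect_error(train_tm_model(sim$X[1:5, ], sim$y[1:5]), "at least 10")
  y_bad <- sim$y; y_bad[3] <- NA
  expect_error(train_tm_model(sim$X, y_bad), "finite")
  X_un <- sim$X; colnames(X_un) <- NULL
  expect_error(train_tm_model(X_un, sim$y), "column names")
})

test_that("prediction aligns columns by name and rejects missing features", {
  sim <- small_sim()
  fit <- train_tm_model(sim$X, sim$y, seed = 5)
  perm <- sim$X[, rev(colnames(sim$X))]
  expect_identical(predict(fit, perm), predict(fit, sim$X))
  extra <- cbind(sim$X, junk = 1)
  expect_identical(predict(fit, extra), predict(fit, sim$X))
  expect_error(predict(fit, sim$X[, -3]), "missing required feature")
})

test_that("k-fold CV covers each record exactly once with balanced folds", {
  sim <- small_sim(n = 103)
  rep5 <- kfold_cv(sim$X, sim$y, k = 5, seed = 2)
  folds <- attr(rep5, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  sizes <- table(folds)
  expect_lte(diff(range(sizes)), 1)
  expect_true(all(is.finite(attr(rep5, "oof"))))
  expect_equal(rep5$n, 103L)
  expect_error(kfold_cv(sim$X, sim$y, k = 200), "exceed")
})

test_that("CV detects the planted signal on clean data", {
  sim <- small_sim(n = 400, p = 20, k = 5, noise = 1)
  rep3 <- kfold_cv(sim$X, sim$y, k = 3, seed = 2)
  expect_gt(rep3$pcc, 0.9)
})

test_that("RFE bookkeeping: strict shrinkage, no resurrection, exact sizes", {
  sim <- small_sim(n = 200, p = 60, k = 5, noise = 1)
  res <- rfe_select(sim$X, sim$y, target_sizes = c(10, 25, 60), cv = 3,
                    seed = 4)
  expect_s3_class(res, "rfe_result")
  expect_equal(sort(res$target_sizes), c(10, 25, 60))
  expect_equal(vapply(res$feature_sets, length, integer(1)),
               c(`60` = 60L, `25` = 25L, `10` = 10L))
  # nesting: each smaller set is contained in every larger one
  expect_true(all(res$feature_sets[["10"]] %in% res$feature_sets[["25"]]))
  expect_true(all(res$feature_sets[["25"]] %in% res$feature_sets[["60"]]))
  expect_false(anyDuplicated(res$ranked_features) > 0)
  expect_setequal(res$ranked_features, colnames(sim$X))
  # the ranking prefix reproduces each retained set
  expect_setequal(res$ranked_features[1:10], res$feature_sets[["10"]])
  expect_error(rfe_select(sim$X, sim$y, target_sizes = integer(0)),
               "non-empty")
})

test_that("requesting all features is the identity selection", {
  sim <- small_sim(n = 120, p = 15, k = 3)
  res <- rfe_select(sim$X, sim$y, target_sizes = 15, cv = 3, seed = 4)
  expect_setequal(res$selected_features, colnames(sim$X))
})

test_that("RFE retains planted features and ranks them highly", {
  sim <- small_sim(n = 400, p = 80, k = 5, noise = 1)
  sel <- select_features(sim$X, sim$y, size = 10, seed = 6)
  expect_length(sel, 10L)
  expect_gte(sum(sim$signal_features %in% sel), 4L)
})

test_that("size choice uses CV PCC with ties toward the smaller size", {
  sim <- small_sim(n = 250, p = 30, k = 5, noise = 1)
  res <- rfecv_select(sim$X, sim$y, cv = 3, target_sizes = c(10, 20, 30),
                      seed = 8)
  pccs <- vapply(res$per_size_scores, function(r) r$pcc, numeric(1))
  sizes <- as.integer(names(pccs))
  best <- max(pccs)
  expect_equal(res$chosen_size, min(sizes[pccs == best]))
  tab <- selection_table(res)
  expect_equal(tab$n_features, sort(sizes))
  expect_named(tab, c("n_features", "pcc", "rmse", "r2", "mse", "mae"))
})

test_that("default candidate grid covers 50..3000 plus all features", {
  # grid construction only; sizes above p collapse onto p
  sim <- small_sim(n = 60, p = 12, k = 2)
  res <- rfe_select(sim$X, sim$y, cv = 2, seed = 1, compute_scores = FALSE)
  expect_equal(res$target_sizes, 12L)
  X_big <- matrix(rnorm(40 * 60), 40, 60,
                  dimnames = list(NULL, paste0("f", 1:60)))
  res2 <- rfe_select(X_big, rnorm(40), target_sizes = NULL, cv = 2,
                     seed = 1, compute_scores = FALSE)
  expect_equal(res2$target_sizes, c(50L, 60L))
})

test_that("model bundles round-trip bit-identically and reject corruption", {
  sim <- small_sim()
  fit <- train_tm_model(sim$X, sim$y, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_tm_model(fit, path)
  back <- load_tm_model(path)
  expect_identical(predict(back, sim$X), predict(fit, sim$X))
  expect_identical(back$selected_features, fit$selected_features)
  expect_identical(back$params, fit$params)
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(oops = 1), junk)
  expect_error(load_tm_model(junk), "bundle")
  txt <- withr::local_tempfile(fileext = ".rds")
  writeLines("not an rds", txt)
  expect_error(load_tm_model(txt))
})

test_that("prediction warns on a descriptor fingerprint mismatch", {
  sim <- small_sim()
  X <- sim$X
  attr(X, "config_fingerprint") <- "cfgA"
  fit <- train_tm_model(X, sim$y, seed = 1)
  X2 <- sim$X
  attr(X2, "config_fingerprint") <- "cfgB"
  expect_warning(predict(fit, X2), "fingerprint")
})

test_that("baseline algorithms share folds and report all five measures", {
  skip_if_not_installed("rpart")
  skip_if_not_installed("e1071")
  sim <- small_sim(n = 150, p = 10, k = 3, noise = 1)
  reps <- baseline_regressors(sim$X, sim$y,
                              algorithms = c("decision_tree", "linear_svr",
                                             "gbrt", "lightgbm"),
                              k = 3, seed = 12)
  expect_named(reps, c("decision_tree", "linear_svr", "gbrt", "lightgbm"))
  folds <- lapply(reps, attr, "folds")
  expect_identical(folds[[1]], folds[[2]])
  expect_identical(folds[[1]], folds[[4]])
  for (r in reps) {
    expect_true(all(is.finite(c(r$pcc, r$rmse, r$mse, r$mae, r$r2))))
  }
  # boosted ensembles should beat a single tree on a linear signal
  expect_gte(reps$lightgbm$pcc, reps$decision_tree$pcc)
  expect_error(baseline_regressors(sim$X, sim$y, algorithms = "magic"),
               "unknown algorithm")
})
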