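# Gradient-boosted regression tree modelling of melting temperatures:
# training, prediction, k-fold cross-validation, recursive feature
# elimination (with and without an inner CV loop), and model persistence.

MODEL_MAGIC <- "thermostab_model_v1"

#' Default gradient-boosting hyperparameters
#'
#' The package's defaults: 150 boosting rounds, learning rate 0.1, tree
#' depth 4, no row or column subsampling, a single thread (for bit-level
#' determinism). Sequence-stability regression has many weakly informative
#' descriptors and a largely additive structure, so moderately shallow
#' trees with a standard learning rate balance bias and variance better
#' than deep ones; see the methods vignette for the capacity profile
#' behind this choice.
#'
#' @return Named list of parameters; `nrounds` is consumed separately from
#'   the booster parameters.
#' @export
default_gbdt_params <- function() {
  list(nrounds = 150L, eta = 0.1, max_depth = 4L, min_child_weight = 1,
       subsample = 1, colsample_bytree = 1, nthread = 1L,
       objective = "reg:squarederror")
}

#' Default retained-feature count of the final model
#'
#' Recursive feature elimination stops at 200 features for the final
#' predictor: performance across the candidate grid plateaus from a few
#' hundred features on, and the smaller of two near-identical sizes covers
#' the space of feature combinations better.
#'
#' @return Integer, 200.
#' @export
final_model_size <- function() 200L

check_xy <- function(X, y) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("X must have unique column names")
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (anyNA(X) || any(!is.finite(X))) stop("X contains non-finite values")
  if (anyNA(y) || any(!is.finite(y))) stop("y contains non-finite values")
  invisible(NULL)
}

fit_booster <- function(X, y, params, seed) {
  p <- utils::modifyList(default_gbdt_params(), params)
  nrounds <- p$nrounds
  p$nrounds <- NULL
  withr::with_seed(as.integer(seed), {
    xgboost::xgb.train(params = p,
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = nrounds, verbose = 0)
  })
}

#' Train a melting temperature regressor
#'
#' Fits a gradient-boosted regression tree ensemble on a feature matrix and
#' Tm targets. Deterministic for a fixed seed (single-threaded boosting).
#'
#' @param X Numeric feature matrix with unique column names (rows aligned
#'   with `y`), e.g. from [featurize()].
#' @param y Melting temperatures (degrees C), finite.
#' @param params Named list overriding [default_gbdt_params()].
#' @param seed Integer seed.
#' @return An object of class `tm_model`: the fitted ensemble plus the
#'   ordered feature-name contract, hyperparameters, seed and the
#'   descriptor-configuration fingerprint of `X` (when present).
#' @export
train_tm_model <- function(X, y, params = list(), seed = 1L) {
  check_xy(X, y)
  if (nrow(X) < 10L) stop("need at least 10 training rows")
  booster <- fit_booster(X, y, params, seed)
  structure(list(booster = booster,
                 selected_features = colnames(X),
                 params = utils::modifyList(default_gbdt_params(), params),
                 seed = as.integer(seed),
                 descriptor_fingerprint =
                   attr(X, "config_fingerprint", exact = TRUE),
                 version = as.character(utils::packageVersion("thermostab"))),
            class = "tm_model")
}

#' Predict melting temperatures
#'
#' Columns are aligned to the model's feature contract by name; extra
#' columns are ignored, missing ones are an error (never silent positional
#' reindexing).
#'
#' @param object A `tm_model`.
#' @param X Numeric matrix containing at least the model's
#'   `selected_features` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted Tm (degrees C), one per row of `X`.
#' @export
predict.tm_model <- function(object, X, ...) {
  if (!is.matrix(X)) stop("X must be a numeric matrix")
  missing_feats <- setdiff(object$selected_features, colnames(X))
  if (length(missing_feats) > 0L) {
    stop("X is missing required feature column(s): ",
         paste(utils::head(missing_feats, 10), collapse = ", "),
         if (length(missing_feats) > 10L) ", ...")
  }
  fp <- attr(X, "config_fingerprint", exact = TRUE)
  if (!is.null(fp) && !is.null(object$descriptor_fingerprint) &&
      !identical(fp, object$descriptor_fingerprint)) {
    warning("descriptor configuration fingerprint of X differs from the ",
            "one the model was trained with")
  }
  Xo <- X[, object$selected_features, drop = FALSE]
  stats::predict(object$booster, Xo)
}

#' @export
print.tm_model <- function(x, ...) {
  cat("Gradient-boosted Tm regressor (", length(x$selected_features),
      " features, ", x$params$nrounds, " rounds, eta ", x$params$eta,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# shuffled fold labels, sizes differing by at most one
fold_assignment <- function(n, k, seed) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k must not exceed the number of records")
  withr::with_seed(as.integer(seed), sample(rep_len(seq_len(k), n)))
}

#' k-fold cross-validation
#'
#' Each record is predicted exactly once by a model trained on the other
#' folds; the five regression measures are computed on the pooled
#' out-of-fold predictions.
#'
#' @inheritParams train_tm_model
#' @param k Number of folds (default 10).
#' @param folds Optional precomputed fold labels (overrides `k`/`seed`),
#'   enabling shared-fold comparisons across algorithms.
#' @param engine Fitting function `(X, y) -> model` with a matching
#'   `predict(model, X)`; defaults to the package's gradient-boosted engine.
#' @return An `evaluation_report` with attributes `folds` (fold labels) and
#'   `oof` (the pooled out-of-fold predictions).
#' @export
kfold_cv <- function(X, y, k = 10L, seed = 1L, params = list(),
                     folds = NULL, engine = NULL) {
  check_xy(X, y)
  n <- nrow(X)
  if (is.null(folds)) folds <- fold_assignment(n, k, seed)
  stopifnot(length(folds) == n)
  oof <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    Xtr <- X[-test_idx, , drop = FALSE]
    ytr <- y[-test_idx]
    if (is.null(engine)) {
      fit <- fit_booster(Xtr, ytr, params, seed)
      oof[test_idx] <- stats::predict(fit, X[test_idx, , drop = FALSE])
    } else {
      fit <- engine(Xtr, ytr)
      oof[test_idx] <- stats::predict(fit, X[test_idx, , drop = FALSE])
    }
  }
  report <- evaluate_predictions(oof, y)
  attr(report, "folds") <- folds
  attr(report, "oof") <- oof
  report
}

# per-feature importance (gain), zero for features the ensemble never used
booster_importance <- function(booster, feature_names) {
  imp <- xgboost::xgb.importance(model = booster)
  gain <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0L) {
    gain[imp$Feature] <- imp$Gain
  }
  gain
}

#' Recursive feature elimination
#'
#' Repeatedly fits the gradient-boosted ensemble, ranks features by gain
#' importance, and prunes the least important 10% (at least one feature,
#' clamped so the path lands exactly on every requested size). Per-size
#' cross-validated scores are recorded; the chosen size is the one with the
#' best cross-validated PCC, ties broken toward the smaller size.
#'
#' @inheritParams train_tm_model
#' @param target_sizes Integer vector of candidate retained-feature counts;
#'   defaults to 50, 100, 200, 300, 500, 1000, 2000, 3000 and all features
#'   (sizes above `ncol(X)` are dropped).
#' @param step_frac Fraction of remaining features pruned per round.
#' @param cv Folds for the per-size cross-validated scores.
#' @param compute_scores Record per-size CV scores (set `FALSE` to run the
#'   elimination path only; the smallest target is then chosen).
#' @return An object of class `rfe_result`: `ranked_features` (most
#'   important first: survivors by final gain, then eliminated features in
#'   reverse elimination order), `feature_sets` (per-size name lists),
#'   `per_size_scores` (per-size `evaluation_report`s), `chosen_size`, and
#'   `selected_features`.
#' @export
rfe_select <- function(X, y, target_sizes = NULL, step_frac = 0.1,
                       cv = 3L, seed = 1L, params = list(),
                       compute_scores = TRUE) {
  check_xy(X, y)
  p <- ncol(X)
  if (is.null(target_sizes)) {
    target_sizes <- c(50L, 100L, 200L, 300L, 500L, 1000L, 2000L, 3000L, p)
  }
  target_sizes <- sort(unique(as.integer(target_sizes)))
  if (length(target_sizes) == 0L) stop("target_sizes must be non-empty")
  if (any(target_sizes < 1L)) stop("target_sizes must be positive")
  target_sizes <- target_sizes[target_sizes <= p]
  if (length(target_sizes) == 0L) {
    stop("all target_sizes exceed the number of features (", p, ")")
  }

  current <- colnames(X)
  eliminated <- character(0)   # chronological elimination order
  feature_sets <- list()
  last_gain <- NULL
  for (tsize in rev(target_sizes)) {    # largest first
    while (length(current) > tsize) {
      booster <- fit_booster(X[, current, drop = FALSE], y, params, seed)
      gain <- booster_importance(booster, current)
      drop_n <- max(1L, as.integer(floor(step_frac * length(current))))
      drop_n <- min(drop_n, length(current) - tsize)
      # least important first; ties broken by column order (stable)
      ord <- order(gain, seq_along(gain), decreasing = FALSE)
      dropped <- current[ord[seq_len(drop_n)]]
      eliminated <- c(eliminated, dropped)
      current <- setdiff(current, dropped)
      last_gain <- gain[current]
    }
    feature_sets[[as.character(tsize)]] <- current
  }

  per_size_scores <- NULL
  if (compute_scores) {
    per_size_scores <- lapply(feature_sets, function(feats) {
      kfold_cv(X[, feats, drop = FALSE], y, k = cv, seed = seed,
               params = params)
    })
    sizes <- as.integer(names(per_size_scores))
    pccs <- vapply(per_size_scores, function(r) r$pcc, numeric(1))
    best <- order(-pccs, sizes)[1L]      # ties toward the smaller size
    chosen_size <- sizes[best]
  } else {
    chosen_size <- min(target_sizes)
  }

  survivors <- if (is.null(last_gain)) {
    booster <- fit_booster(X[, current, drop = FALSE], y, params, seed)
    gain <- booster_importance(booster, current)
    current[order(-gain, seq_along(gain))]
  } else {
    current[order(-last_gain, seq_along(last_gain))]
  }
  structure(list(ranked_features = c(survivors, rev(eliminated)),
                 target_sizes = target_sizes,
                 feature_sets = feature_sets,
                 per_size_scores = per_size_scores,
                 chosen_size = chosen_size,
                 selected_features =
                   feature_sets[[as.character(chosen_size)]]),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("Recursive feature elimination over sizes {",
      paste(x$target_sizes, collapse = ", "), "}\n", sep = "")
  if (!is.null(x$per_size_scores)) {
    pccs <- vapply(x$per_size_scores, function(r) r$pcc, numeric(1))
    cat("  CV PCC:", paste(sprintf("%s=%.3f", names(pccs), pccs),
                           collapse = " "), "\n")
  }
  cat("  chosen size:", x$chosen_size, "\n")
  invisible(x)
}

#' Run recursive feature elimination to the default final-model size
#'
#' Convenience wrapper around [rfe_select()] that prunes straight to the
#' final predictor's default retained-feature count ([final_model_size()],
#' 200) and returns the selected feature names.
#'
#' @inheritParams rfe_select
#' @param size Stop criterion: number of features to retain.
#' @return Character vector of the retained feature names, most important
#'   first.
#' @export
select_features <- function(X, y, size = final_model_size(), seed = 1L,
                            params = list()) {
  size <- min(as.integer(size), ncol(X))
  res <- rfe_select(X, y, target_sizes = size, seed = seed, params = params,
                    compute_scores = FALSE)
  res$ranked_features[seq_len(size)]
}

#' Recursive feature elimination with cross-validated size choice
#'
#' Runs the elimination path and picks the retained-feature count by
#' cross-validated PCC (default 3-fold), ties toward the smaller size.
#'
#' @inheritParams rfe_select
#' @param cv Folds of the size-selection cross-validation (default 3).
#' @return An `rfe_result` (see [rfe_select()]).
#' @export
rfecv_select <- function(X, y, cv = 3L, target_sizes = NULL,
                         step_frac = 0.1, seed = 1L, params = list()) {
  rfe_select(X, y, target_sizes = target_sizes, step_frac = step_frac,
             cv = cv, seed = seed, params = params, compute_scores = TRUE)
}

#' Table of per-size cross-validated metrics
#'
#' @param result An `rfe_result` with recorded scores.
#' @return Data frame with one row per candidate size and the five metrics.
#' @export
selection_table <- function(result) {
  stopifnot(inherits(result, "rfe_result"), !is.null(result$per_size_scores))
  sizes <- as.integer(names(result$per_size_scores))
  rows <- lapply(result$per_size_scores, function(r) {
    data.frame(pcc = r$pcc, rmse = r$rmse, r2 = r$r2, mse = r$mse,
               mae = r$mae)
  })
  out <- cbind(data.frame(n_features = sizes), do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$n_features), ]
}

# ---- baseline algorithm bake-off -------------------------------------------

baseline_engines <- function() {
  c("decision_tree", "random_forest", "linear_svr", "gbrt", "xgboost",
    "lightgbm", "mlp")
}

need_pkg <- function(pkg, algo) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("baseline '", algo, "' needs the ", pkg, " package")
  }
}

make_engine <- function(algo, seed) {
  force(seed)
  switch(algo,
    decision_tree = function(X, y) {
      need_pkg("rpart", "decision_tree")
      df <- data.frame(y = y, X, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df)
      structure(list(fit = fit), class = "ts_rpart")
    },
    random_forest = function(X, y) {
      need_pkg("randomForest", "random_forest")
      fit <- withr::with_seed(seed, randomForest::randomForest(X, y))
      structure(list(fit = fit), class = "ts_rf")
    },
    linear_svr = function(X, y) {
      need_pkg("e1071", "linear_svr")
      fit <- e1071::svm(X, y, kernel = "linear", type = "eps-regression",
                        scale = TRUE)
      structure(list(fit = fit), class = "ts_svm")
    },
    gbrt = function(X, y) {   # depth-wise exact boosting, shallow trees
      fit_booster(X, y, list(max_depth = 3L, eta = 0.1,
                             tree_method = "exact"), seed)
    },
    xgboost = function(X, y) {
      fit_booster(X, y, list(eta = 0.3), seed)
    },
    lightgbm = function(X, y) {  # histogram + leaf-wise growth, 31 leaves
      fit_booster(X, y, list(tree_method = "hist",
                             grow_policy = "lossguide",
                             max_leaves = 31L, max_depth = 0L,
                             eta = 0.1), seed)
    },
    mlp = function(X, y) {
      need_pkg("nnet", "mlp")
      ctr <- list(mu = colMeans(X), sd = pmax(apply(X, 2, stats::sd), 1e-8),
                  ymu = mean(y), ysd = max(stats::sd(y), 1e-8))
      Xs <- scale(X, ctr$mu, ctr$sd)
      ys <- (y - ctr$ymu) / ctr$ysd
      fit <- withr::with_seed(seed, nnet::nnet(Xs, ys, size = 20,
                                               linout = TRUE, maxit = 300,
                                               decay = 1e-4, trace = FALSE,
                                               MaxNWts = 100000))
      structure(list(fit = fit, ctr = ctr), class = "ts_mlp")
    },
    stop("unknown baseline algorithm: ", algo))
}

#' @export
predict.ts_rpart <- function(object, X, ...) {
  as.numeric(stats::predict(object$fit,
                            newdata = as.data.frame(X, check.names = FALSE)))
}
#' @export
predict.ts_rf <- function(object, X, ...) {
  as.numeric(stats::predict(object$fit, X))
}
#' @export
predict.ts_svm <- function(object, X, ...) {
  as.numeric(stats::predict(object$fit, X))
}
#' @export
predict.ts_mlp <- function(object, X, ...) {
  Xs <- scale(X, object$ctr$mu, object$ctr$sd)
  as.numeric(stats::predict(object$fit, Xs)) * object$ctr$ysd + object$ctr$ymu
}

#' Cross-validated comparison of baseline regression algorithms
#'
#' Evaluates a set of regression algorithms under identical fold
#' assignments so their reports are directly comparable. The ensemble
#' variants run on the package's boosting engine with the preset named
#' after each algorithm family; decision tree, random forest, linear
#' support vector regression and the single-hidden-layer perceptron use the
#' corresponding standard packages with their defaults.
#'
#' @inheritParams kfold_cv
#' @param algorithms Subset of the names returned by [baseline_engines()].
#' @return Named list of `evaluation_report`s sharing one fold assignment.
#' @export
baseline_regressors <- function(X, y, algorithms = baseline_engines(),
                                k = 10L, seed = 1L) {
  check_xy(X, y)
  unknown <- setdiff(algorithms, baseline_engines())
  if (length(unknown) > 0L) {
    stop("unknown algorithm name(s): ", paste(unknown, collapse = ", "))
  }
  folds <- fold_assignment(nrow(X), k, seed)
  out <- lapply(algorithms, function(a) {
    kfold_cv(X, y, folds = folds, engine = make_engine(a, seed))
  })
  names(out) <- algorithms
  out
}

# ---- persistence -----------------------------------------------------------

#' Save a trained model to a single-file bundle
#'
#' The bundle holds the serialized ensemble bytes plus the feature-name
#' contract, hyperparameters, seed, descriptor-configuration fingerprint and
#' package version; reloading reproduces predictions bit-identically.
#'
#' @param model A `tm_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_tm_model <- function(model, path) {
  stopifnot(inherits(model, "tm_model"))
  bundle <- list(magic = MODEL_MAGIC,
                 raw = xgboost::xgb.save.raw(model$booster),
                 selected_features = model$selected_features,
                 params = model$params,
                 seed = model$seed,
                 descriptor_fingerprint = model$descriptor_fingerprint,
                 version = model$version)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a model bundle written by [save_tm_model()]
#'
#' @param path Path to a model bundle.
#' @return A `tm_model`.
#' @export
load_tm_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  bundle <- tryCatch(readRDS(path),
                     error = function(e) stop("cannot read model bundle: ",
                                              conditionMessage(e)))
  if (!is.list(bundle) || !identical(bundle$magic, MODEL_MAGIC)) {
    stop("not a thermostab model bundle (or an incompatible version): ",
         path)
  }
  structure(list(booster = xgboost::xgb.load.raw(bundle$raw),
                 selected_features = bundle$selected_features,
                 params = bundle$params,
                 seed = bundle$seed,
                 descriptor_fingerprint = bundle$descriptor_fingerprint,
                 version = bundle$version),
            class = "tm_model")
}
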