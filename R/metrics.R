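# Regression evaluation: Pearson correlation, RMSE, MSE, MAE, R-squared
# (population 1/N normalization throughout), and the 3-class melting
# temperature binning with thresholds 55 and 65 degrees C.

check_pair <- function(y_pred, y_true, min_n = 1L) {
  if (length(y_pred) != length(y_true)) {
    stop("y_pred and y_true must have equal length")
  }
  if (length(y_true) < min_n) stop("need at least ", min_n, " observations")
  if (anyNA(y_pred) || anyNA(y_true) ||
      any(!is.finite(y_pred)) || any(!is.finite(y_true))) {
    stop("inputs must be finite and free of missing values")
  }
  invisible(NULL)
}

#' Pearson correlation coefficient
#'
#' Covariance of the two vectors divided by the product of their standard
#' deviations. Undefined (error) when either input has zero variance.
#'
#' @param y_pred Predicted values.
#' @param y_true Observed values.
#' @return A number in \[-1, 1\].
#' @export
pcc <- function(y_pred, y_true) {
  check_pair(y_pred, y_true, 2L)
  if (stats::sd(y_pred) == 0 || stats::sd(y_true) == 0) {
    stop("pcc undefined: zero variance in an input")
  }
  stats::cor(y_pred, y_true)
}

#' Root mean square error (same unit as the target, degrees C for Tm)
#' @inheritParams pcc
#' @return RMSE >= 0.
#' @export
rmse <- function(y_pred, y_true) {
  check_pair(y_pred, y_true)
  sqrt(mean((y_pred - y_true)^2))
}

#' Mean squared error (squared target unit)
#' @inheritParams pcc
#' @return MSE >= 0.
#' @export
mse <- function(y_pred, y_true) {
  check_pair(y_pred, y_true)
  mean((y_pred - y_true)^2)
}

#' Mean absolute error (same unit as the target)
#' @inheritParams pcc
#' @return MAE >= 0.
#' @export
mae <- function(y_pred, y_true) {
  check_pair(y_pred, y_true)
  mean(abs(y_pred - y_true))
}

#' Coefficient of determination
#'
#' `1 - SSres / SStot` with SSres the sum of squared residuals and SStot the
#' total sum of squares of the observed values. May be negative when the
#' predictor is worse than the constant mean. Errors on a constant truth
#' vector (SStot = 0).
#'
#' @inheritParams pcc
#' @return A number <= 1.
#' @export
r2 <- function(y_pred, y_true) {
  check_pair(y_pred, y_true, 2L)
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0) stop("r2 undefined: constant y_true")
  1 - sum((y_pred - y_true)^2) / sstot
}

#' Three-category melting temperature class
#'
#' Bins Tm at 55 and 65 degrees C: `low` below 55, `mid` in \[55, 65),
#' `high` at or above 65 (boundaries on the upper category's closed side).
#'
#' @param tm Numeric vector of melting temperatures (degrees C).
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
tm_class <- function(tm) {
  if (anyNA(tm) || any(!is.finite(tm))) stop("tm must be finite")
  cut(tm, breaks = c(-Inf, 55, 65, Inf), labels = c("low", "mid", "high"),
      right = FALSE)
}

#' Three-class agreement between predicted and observed Tm
#'
#' @param pred_tms Predicted Tm values (degrees C).
#' @param true_tms Observed Tm values (degrees C).
#' @return Proportion of records whose predicted and observed classes match.
#' @export
class_accuracy <- function(pred_tms, true_tms) {
  check_pair(pred_tms, true_tms)
  mean(tm_class(pred_tms) == tm_class(true_tms))
}

#' Full evaluation report for one prediction set
#'
#' Computes the five regression measures (PCC, RMSE, MSE, MAE, R-squared)
#' and, optionally, the 3-class accuracy. MSE is reported in squared degrees
#' (the natural unit of a squared error).
#'
#' @inheritParams pcc
#' @param classes Also compute the 3-class Tm accuracy (default `TRUE`).
#' @return An object of class `evaluation_report`: a list with elements
#'   `pcc`, `rmse`, `mse`, `mae`, `r2`, `n` and `class_accuracy`.
#' @export
evaluate_predictions <- function(y_pred, y_true, classes = TRUE) {
  structure(list(pcc = pcc(y_pred, y_true),
                 rmse = rmse(y_pred, y_true),
                 mse = mse(y_pred, y_true),
                 mae = mae(y_pred, y_true),
                 r2 = r2(y_pred, y_true),
                 n = length(y_true),
                 class_accuracy = if (classes)
                   class_accuracy(y_pred, y_true) else NA_real_),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation on", x$n, "records\n")
  cat(sprintf("  PCC  %7.4f\n  RMSE %7.4f degC\n  MSE  %7.4f degC^2\n",
              x$pcc, x$rmse, x$mse))
  cat(sprintf("  MAE  %7.4f degC\n  R2   %7.4f\n", x$mae, x$r2))
  if (is.finite(x$class_accuracy)) {
    cat(sprintf("  3-class accuracy %.1f%%\n", 100 * x$class_accuracy))
  }
  invisible(x)
}

#' Write an evaluation report to TSV or JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path; `.json` selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  fields <- report[c("pcc", "rmse", "mse", "mae", "r2", "n",
                     "class_accuracy")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(fields)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
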