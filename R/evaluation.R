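# Evaluation metrics and stratified reports.
#
# Regression metrics are computed on the fractional yield scale [0,1];
# classification uses exact-match accuracy over the four yield classes.

.check_metric_input <- function(y, yhat, min_n = 1L) {
  if (length(y) != length(yhat)) {
    rxy_abort("rxy_shape_error", "y and yhat must have equal length")
  }
  if (length(y) < min_n) {
    rxy_abort("rxy_undefined_metric_error",
              sprintf("metric needs at least %d observations", min_n))
  }
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; undefined for constant `y`.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Scalar R-squared.
#' @export
r_squared <- function(y, yhat) {
  .check_metric_input(y, yhat, min_n = 2L)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    rxy_abort("rxy_undefined_metric_error", "R^2 undefined for constant y")
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute error
#' @inheritParams r_squared
#' @return Scalar MAE.
#' @export
mae <- function(y, yhat) {
  .check_metric_input(y, yhat)
  mean(abs(y - yhat))
}

#' Root mean squared error
#' @inheritParams r_squared
#' @return Scalar RMSE (always >= MAE).
#' @export
rmse <- function(y, yhat) {
  .check_metric_input(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Classification accuracy
#'
#' Fraction of exact label matches.
#'
#' @param labels True labels.
#' @param predicted Predicted labels.
#' @return Scalar accuracy in `[0,1]`.
#' @export
accuracy <- function(labels, predicted) {
  .check_metric_input(labels, predicted)
  mean(as.character(labels) == as.character(predicted))
}

#' Evaluate a task model on test strata defined by training group size
#'
#' For each threshold, restricts the test set to records whose reaction
#' group has strictly more than that many members in the training set (see
#' [filter_test_by_group_size()]) and evaluates the model there. Empty
#' strata are reported with `n = 0` and missing metrics rather than an
#' error.
#'
#' @param task_model An `rxy_task_model`.
#' @param train_records,test_records Reaction record data.frames.
#' @param thresholds Integer vector of group-size thresholds.
#' @return data.frame with one row per threshold: `min_group_size`, `n`, and
#'   the metrics of the head kind (regression: `r2`, `mae`, `rmse` on the
#'   fractional scale; multiclass: `accuracy`).
#' @export
group_size_report <- function(task_model, train_records, test_records,
                              thresholds = c(5, 10, 15, 20, 25, 30, 35, 40, 50, 60)) {
  stopifnot(inherits(task_model, "rxy_task_model"))
  kind <- task_model$head$config$kind
  rows <- lapply(thresholds, function(th) {
    sub <- filter_test_by_group_size(test_records, train_records, th)
    base <- data.frame(min_group_size = th, n = nrow(sub))
    if (nrow(sub) == 0L) {
      if (kind == "regression") {
        return(cbind(base, r2 = NA_real_, mae = NA_real_, rmse = NA_real_))
      }
      return(cbind(base, accuracy = NA_real_))
    }
    pred <- predict_yields(task_model, sub)
    if (kind == "regression") {
      y <- sub$yield_percent / 100
      r2 <- if (nrow(sub) >= 2L && stats::var(y) > 0)
        r_squared(y, pred$yield_fraction) else NA_real_
      cbind(base, r2 = r2, mae = mae(y, pred$yield_fraction),
            rmse = rmse(y, pred$yield_fraction))
    } else {
      cbind(base, accuracy = accuracy(bin_yield(sub$yield_percent), pred$pred_bin))
    }
  })
  do.call(rbind, rows)
}
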