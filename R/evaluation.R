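.check_pair <- function(Y, Yhat) {
  Y <- as.numeric(Y); Yhat <- as.numeric(Yhat)
  if (length(Y) == 0L) stopf("empty input")
  if (length(Y) != length(Yhat))
    stopf("length mismatch: %d ground-truth vs %d predicted values",
          length(Y), length(Yhat))
  if (!all(is.finite(Y)) || !all(is.finite(Yhat))) stopf("inputs must be finite")
  list(Y = Y, Yhat = Yhat)
}

#' Root mean square error
#'
#' `sqrt(mean((Y - Yhat)^2))` over the N evaluated points.
#'
#' @param Y Ground-truth values (mm).
#' @param Yhat Predicted values (mm), same length.
#' @return RMSE in mm.
#' @export
rmse <- function(Y, Yhat) {
  p <- .check_pair(Y, Yhat)
  sqrt(mean((p$Y - p$Yhat)^2))
}

#' Mean absolute error
#'
#' `mean(|Y - Yhat|)` over the N evaluated points.
#'
#' @inheritParams rmse
#' @return MAE in mm.
#' @export
mae <- function(Y, Yhat) {
  p <- .check_pair(Y, Yhat)
  mean(abs(p$Y - p$Yhat))
}

#' Normalized root mean square error
#'
#' RMSE divided by the ground-truth range `max(Y) - min(Y)`, making the score
#' scale-free so signals of different breathing amplitude are comparable:
#' `nrmse(a*Y + b, a*Yhat + b) == nrmse(Y, Yhat)` for any `a != 0`.
#'
#' @inheritParams rmse
#' @return Unitless NRMSE.
#' @export
nrmse <- function(Y, Yhat) {
  p <- .check_pair(Y, Yhat)
  rng <- max(p$Y) - min(p$Y)
  if (rng == 0) stopf("constant ground truth: NRMSE denominator is zero")
  rmse(p$Y, p$Yhat) / rng
}

#' Two-sided variance-ratio F-test between ground truth and predictions
#'
#' Tests whether the predicted series reproduces the variability of the real
#' series: `F = var(Y) / var(Yhat)` (sample variances, n-1 degrees of freedom
#' each) with a two-sided p-value from the F distribution. Identical series
#' give F = 1, p = 1.
#'
#' @inheritParams rmse
#' @param alpha Significance level for the returned flag (default 0.05).
#' @return List with `f_stat`, `p_value`, `df1`, `df2` and logical
#'   `significant` (p < alpha).
#' @export
f_test <- function(Y, Yhat, alpha = 0.05) {
  p <- .check_pair(Y, Yhat)
  if (length(p$Y) < 2L) stopf("need at least 2 observations per series")
  v1 <- stats::var(p$Y); v2 <- stats::var(p$Yhat)
  if (v1 == 0 || v2 == 0) stopf("zero variance: F statistic undefined")
  df1 <- length(p$Y) - 1L; df2 <- length(p$Yhat) - 1L
  f <- v1 / v2
  pv <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  pv <- min(pv, 1)
  list(f_stat = f, p_value = pv, df1 = df1, df2 = df2,
       significant = pv < alpha)
}

#' Box-plot statistics with a 2.7-SD outlier rule
#'
#' Quartiles use the inclusive linear-interpolation convention
#' (`stats::quantile` type 7). Outliers are points more than 2.7 sample
#' standard deviations from the mean; whiskers extend to the most extreme
#' non-outlier points.
#'
#' @param errors Numeric vector (length >= 4).
#' @return List with `median`, `q25`, `q75`, `whisker_low`, `whisker_high`,
#'   `outliers`, `mean`, `sd`.
#' @export
box_stats <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 4L) stopf("need at least 4 values for box statistics")
  if (!all(is.finite(errors))) stopf("values must be finite")
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(errors); s <- stats::sd(errors)
  is_out <- if (s > 0) abs(errors - m) > 2.7 * s else rep(FALSE, length(errors))
  inliers <- errors[!is_out]
  list(median = q[2], q25 = q[1], q75 = q[3],
       whisker_low = min(inliers), whisker_high = max(inliers),
       outliers = errors[is_out], mean = m, sd = s)
}

#' Relative improvement of one error over a reference error
#'
#' `100 * (reference - achieved) / reference`, the percentage by which the
#' achieved error undercuts the reference (e.g. a clinical hybrid predictor's
#' error of 0.14 mm against an achieved 0.108 mm gives ~22.9%, "almost 23%").
#'
#' @param reference_mm Reference error (> 0).
#' @param achieved_mm Achieved error.
#' @return Improvement in percent (negative if `achieved_mm` is worse).
#' @export
improvement_pct <- function(reference_mm, achieved_mm) {
  assert_scalar_num(reference_mm, "reference_mm", positive = TRUE)
  assert_scalar_num(achieved_mm, "achieved_mm")
  100 * (reference_mm - achieved_mm) / reference_mm
}

#' Evaluate a trained predictor on a supervised set
#'
#' Predictions are made on the normalized scale, then both predictions and
#' targets are denormalized to mm before any metric is computed, so the report
#' is in physical units. One report covers one signal/segment; use
#' [aggregate_reports()] for cohort-level mean and SD.
#'
#' @param trained A `trained_predictor`.
#' @param test_set A non-empty supervised_set on the normalized scale.
#' @param norm The [normalizer()] fitted on the training segment.
#' @return An object of class `metrics_report`: `n`, `rmse_mm`, `mae_mm`,
#'   `nrmse`, `f_stat`, `p_value`, `y_min_mm`, `y_max_mm`.
#' @export
evaluate_split <- function(trained, test_set, norm) {
  if (!inherits(trained, "trained_predictor")) stopf("`trained` must be a trained_predictor")
  if (!inherits(norm, "normalizer")) stopf("`norm` must be a normalizer")
  if (n_pairs(test_set) == 0L) stopf("test set is empty")
  pred <- predict(trained, test_set)
  Y <- denormalize(as.numeric(test_set$targets), norm)
  Yhat <- denormalize(as.numeric(pred), norm)
  ft <- tryCatch(f_test(Y, Yhat), error = function(e) list(f_stat = NA_real_, p_value = NA_real_))
  structure(list(n = length(Y), rmse_mm = rmse(Y, Yhat), mae_mm = mae(Y, Yhat),
                 nrmse = nrmse(Y, Yhat), f_stat = ft$f_stat, p_value = ft$p_value,
                 y_min_mm = min(Y), y_max_mm = max(Y)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d: RMSE %.4f mm, MAE %.4f mm, NRMSE %.4f, F=%.3f (p=%.3g)\n",
              x$n, x$rmse_mm, x$mae_mm, x$nrmse, x$f_stat, x$p_value))
  invisible(x)
}

#' Aggregate per-signal metric reports into cohort mean and SD
#'
#' @param reports List of `metrics_report` objects.
#' @return Data frame with one row per metric (`rmse_mm`, `mae_mm`, `nrmse`)
#'   and columns `mean`, `sd`, `n_signals`.
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stopf("no reports to aggregate")
  pull <- function(f) vapply(reports, function(r) r[[f]], numeric(1))
  metrics <- c("rmse_mm", "mae_mm", "nrmse")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(pull(m)), numeric(1)),
    sd = vapply(metrics, function(m) if (length(reports) > 1L) stats::sd(pull(m)) else 0,
                numeric(1)),
    n_signals = length(reports),
    row.names = NULL
  )
}
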