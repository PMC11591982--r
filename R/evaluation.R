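#' @title Device-validation metrics
#' @description Accuracy metrics (MAE, MAPE, RMSE), error summaries with 95%
#'   confidence intervals, the AAMI pass/fail criterion and BHS letter
#'   grading for blood-pressure estimators against a reference device.
#' @name evaluation
NULL

check_pair <- function(actual, predicted) {
  if (length(actual) == 0L || length(actual) != length(predicted)) {
    stop_invalid("`actual` and `predicted` must be equal-length, non-empty vectors")
  }
}

#' Mean absolute error
#'
#' `MAE = (1/N) sum |A_i - F_i|` between reference values `A` and predictions
#' `F`, in mmHg.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return Scalar MAE.
#' @export
mae <- function(actual, predicted) {
  check_pair(actual, predicted)
  mean(abs(actual - predicted))
}

#' Mean absolute percentage error
#'
#' `MAPE = (1/N) sum |A_i - F_i| / A_i * 100`, in percent. Every reference
#' value must be nonzero.
#'
#' @inheritParams mae
#' @return Scalar MAPE in percent.
#' @export
mape <- function(actual, predicted) {
  check_pair(actual, predicted)
  if (any(actual == 0)) {
    palmbp_stop("MAPE undefined: a reference value is zero", "division_by_zero")
  }
  mean(abs(actual - predicted) / abs(actual)) * 100
}

#' Root mean square error
#'
#' `RMSE = sqrt((1/N) sum (F_i - A_i)^2)`, in mmHg.
#'
#' @inheritParams mae
#' @return Scalar RMSE.
#' @export
rmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((predicted - actual)^2))
}

#' AAMI accuracy criterion
#'
#' A device passes when the mean absolute error does not exceed 5 mmHg and
#' the sample standard deviation of the signed errors (n-1 denominator) does
#' not exceed 8 mmHg.
#'
#' @param errors Signed differences (predicted - reference), mmHg; length
#'   >= 2.
#' @param mae_limit,sd_limit The two bounds (defaults 5 and 8 mmHg).
#' @return List with `pass` (logical), `mae`, `sd` and the limits.
#' @export
aami_check <- function(errors, mae_limit = 5, sd_limit = 8) {
  if (length(errors) < 2L) stop_invalid("AAMI check needs at least 2 errors")
  m <- mean(abs(errors))
  s <- stats::sd(errors)
  list(pass = m <= mae_limit && s <= sd_limit, mae = m, sd = s,
       mae_limit = mae_limit, sd_limit = sd_limit)
}

#' BHS cumulative-error grade
#'
#' Computes the cumulative percentages of absolute errors within 5, 10 and
#' 15 mmHg and grades them A (>= 60/85/95%), B (>= 50/75/90%),
#' C (>= 40/65/85%) or D (worse). The thresholds follow the published BHS
#' protocol and are overridable.
#'
#' @param errors Signed differences in mmHg; length >= 1.
#' @param thresholds 3x3 numeric matrix, rows A/B/C, columns the required
#'   percentages within 5/10/15 mmHg.
#' @return List with `grade` and `p5`, `p10`, `p15` percentages.
#' @export
bhs_grade <- function(errors,
                      thresholds = matrix(c(60, 85, 95,
                                            50, 75, 90,
                                            40, 65, 85),
                                          nrow = 3, byrow = TRUE,
                                          dimnames = list(c("A", "B", "C"), NULL))) {
  if (length(errors) == 0L) stop_invalid("BHS grading needs at least 1 error")
  a <- abs(errors)
  p <- c(mean(a <= 5), mean(a <= 10), mean(a <= 15)) * 100
  grade <- "D"
  for (g in c("C", "B", "A")) {
    if (all(p >= thresholds[g, ])) grade <- g
  }
  list(grade = grade, p5 = p[1], p10 = p[2], p15 = p[3])
}

#' Full accuracy and agreement report
#'
#' Combines the error metrics, the signed-error mean and SD with a
#' normal-approximation 95% confidence interval (`mean +/- 1.96 SD/sqrt(n)`),
#' value-level summaries of the reference and predicted series in the same
#' CI form, the AAMI verdict and the BHS grade.
#'
#' @inheritParams mae
#' @return List of class `metrics_report`.
#' @export
bp_summary <- function(actual, predicted) {
  check_pair(actual, predicted)
  err <- predicted - actual
  n <- length(err)
  ci <- function(v) {
    m <- mean(v)
    half <- 1.96 * stats::sd(v) / sqrt(length(v))
    c(m - half, m + half)
  }
  aami <- if (n >= 2L) aami_check(err) else NULL
  structure(list(
    n = n,
    mae = mae(actual, predicted),
    mape = if (all(actual != 0)) mape(actual, predicted) else NA_real_,
    rmse = rmse(actual, predicted),
    mean_error = mean(err),
    sd_error = if (n >= 2L) stats::sd(err) else NA_real_,
    ci95_mean_error = if (n >= 2L) ci(err) else c(NA_real_, NA_real_),
    mean_actual = mean(actual),
    ci95_mean_actual = if (n >= 2L) ci(actual) else c(NA_real_, NA_real_),
    mean_predicted = mean(predicted),
    ci95_mean_predicted = if (n >= 2L) ci(predicted) else c(NA_real_, NA_real_),
    aami = if (is.null(aami)) NA else aami$pass,
    bhs_grade = bhs_grade(err)$grade
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d\n", x$n))
  cat(sprintf("  MAE %.2f mmHg | MAPE %s%% | RMSE %.2f mmHg\n",
              x$mae, ifelse(is.na(x$mape), "NA", sprintf("%.2f", x$mape)), x$rmse))
  cat(sprintf("  error %.2f +/- %.2f mmHg, 95%% CI (%.2f, %.2f)\n",
              x$mean_error, x$sd_error, x$ci95_mean_error[1], x$ci95_mean_error[2]))
  cat(sprintf("  AAMI: %s | BHS grade: %s\n",
              if (isTRUE(x$aami)) "PASS" else "FAIL", x$bhs_grade))
  invisible(x)
}

#' Serialize a metrics report to JSON (and back)
#'
#' @param report A `metrics_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path)
  doc$ci95_mean_error <- as.numeric(doc$ci95_mean_error)
  doc$ci95_mean_actual <- as.numeric(doc$ci95_mean_actual)
  doc$ci95_mean_predicted <- as.numeric(doc$ci95_mean_predicted)
  structure(doc, class = "metrics_report")
}
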