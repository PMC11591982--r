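#' @title Blood-pressure formula calibration and prediction
#' @description The two calibration routes: the empirical nonlinear formula
#'   `BP = alpha0 + alpha1 x + BMI (1 + alpha2 x)` fitted per BMI interval by
#'   the hybrid Nelder-Mead/particle-swarm optimizer, and the multivariate
#'   linear regression `BP = gamma0 + gamma1 BMI + gamma2 E` fitted by
#'   ordinary least squares. `x`/`E` is the Epeak feature for systolic and
#'   the Evalley feature for diastolic pressure.
#' @name bp_models
NULL

#' Body mass index
#'
#' @param height Height in metres (> 0).
#' @param weight Weight in kilograms (> 0).
#' @return BMI in kg/m^2, `weight / height^2`.
#' @export
compute_bmi <- function(height, weight) {
  if (!is.numeric(height) || !is.numeric(weight) ||
      any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0)) {
    stop_invalid("`height` and `weight` must be positive and finite")
  }
  weight / height^2
}

#' Evaluate the empirical blood-pressure formula
#'
#' `BP = alpha0 + alpha1 * x + BMI * (1 + alpha2 * x)`; with `x = Epeak` this
#' is the systolic estimate, with `x = Evalley` the diastolic one.
#'
#' @param x Pulse feature (Epeak or Evalley), possibly vectorized.
#' @param bmi Body mass index, kg/m^2.
#' @param alpha Length-3 coefficient vector (alpha0, alpha1, alpha2).
#' @return Estimated pressure in mmHg.
#' @export
predict_formula <- function(x, bmi, alpha) {
  if (length(alpha) != 3L || !all(is.finite(alpha))) {
    stop_invalid("`alpha` must be 3 finite coefficients")
  }
  alpha[1] + alpha[2] * x + bmi * (1 + alpha[3] * x)
}

#' Evaluate the regression blood-pressure formula
#'
#' `BP = gamma0 + gamma1 * BMI + gamma2 * E`.
#'
#' @param bmi Body mass index, kg/m^2.
#' @param e_value Pulse feature (Epeak for SBP, Evalley for DBP).
#' @param gamma Length-3 coefficient vector (gamma0, gamma1, gamma2).
#' @return Estimated pressure in mmHg.
#' @export
predict_regression <- function(bmi, e_value, gamma) {
  if (length(gamma) != 3L || !all(is.finite(gamma))) {
    stop_invalid("`gamma` must be 3 finite coefficients")
  }
  gamma[1] + gamma[2] * bmi + gamma[3] * e_value
}

#' Default BMI stratification intervals
#'
#' Half-open intervals `[lo, hi)` following the Taiwanese Ministry of Health
#' and Welfare convention: underweight below 18.5, normal 18.5-24,
#' overweight 24-27, obese 27 and above. Fully overridable wherever a
#' `bmi_intervals` argument is accepted.
#'
#' @return Data frame with columns `lo` and `hi`.
#' @export
default_bmi_intervals <- function() {
  data.frame(lo = c(10, 18.5, 24, 27), hi = c(18.5, 24, 27, 60))
}

#' Look up the formula parameters for a BMI value
#'
#' Intervals are half-open `[lo, hi)`: a boundary value belongs to the upper
#' interval.
#'
#' @param bmi Body mass index to locate.
#' @param table A `bp_formula_table` from [fit_nmpso()], or any data frame
#'   with columns `lo`, `hi`, `alpha0`, `alpha1`, `alpha2`.
#' @return The matching row (one-row data frame).
#' @export
bmi_interval_lookup <- function(bmi, table) {
  if (!is_scalar_num(bmi)) stop_invalid("`bmi` must be a finite scalar")
  if (nrow(table) == 0L) stop_invalid("empty parameter table")
  hit <- which(bmi >= table$lo & bmi < table$hi)
  if (length(hit) == 0L) {
    palmbp_stop(sprintf("BMI %.2f falls outside every calibrated interval", bmi),
                "out_of_range")
  }
  table[hit[1], , drop = FALSE]
}

records_columns <- function(records, target) {
  target <- match.arg(target, c("SBP", "DBP"))
  list(
    y = if (target == "SBP") records$sbp_device else records$dbp_device,
    e = if (target == "SBP") records$e_peak else records$e_valley,
    target = target
  )
}

#' Calibrate the empirical formula per BMI interval with NM-PSO
#'
#' For each BMI interval the coefficients (alpha0, alpha1, alpha2) minimize
#' the mean squared error between [predict_formula()] and the device reading
#' over that interval's subjects, via [nmpso_minimize()] in 3 dimensions.
#' The search box is widened to `[-120, 120]` per coefficient so intercept
#' corrections may be negative.
#'
#' @param records Data frame with columns `bmi`, `sbp_device`, `dbp_device`,
#'   `e_peak`, `e_valley` (see [generate_cohort()]).
#' @param target `"SBP"` or `"DBP"`.
#' @param bmi_intervals Data frame of half-open `[lo, hi)` intervals;
#'   defaults to [default_bmi_intervals()]. Intervals containing no subject
#'   are dropped; intervals with 1-2 subjects are an error (three unknowns
#'   need at least three records).
#' @param config An [nmpso_config()]; its `x_bounds` default is overridden
#'   to `c(-120, 120)` unless explicitly set by the caller.
#' @return A `bp_formula_table`: data frame with `lo`, `hi`, `alpha0`,
#'   `alpha1`, `alpha2`, `mse`, `n`, and attribute `target`.
#' @export
fit_nmpso <- function(records, target = c("SBP", "DBP"),
                      bmi_intervals = default_bmi_intervals(),
                      config = nmpso_config(x_bounds = c(-120, 120))) {
  cols <- records_columns(records, match.arg(target))
  rows <- list()
  for (r in seq_len(nrow(bmi_intervals))) {
    lo <- bmi_intervals$lo[r]; hi <- bmi_intervals$hi[r]
    sel <- records$bmi >= lo & records$bmi < hi
    n_sel <- sum(sel)
    if (n_sel == 0L) next
    if (n_sel < 3L) {
      palmbp_stop(sprintf("BMI interval [%.1f, %.1f) holds only %d record(s); need >= 3",
                          lo, hi, n_sel), "insufficient_data")
    }
    e <- cols$e[sel]; y <- cols$y[sel]; bmi <- records$bmi[sel]
    if (stats::sd(e) == 0) {
      palmbp_stop(sprintf("degenerate fit in BMI interval [%.1f, %.1f): the pulse feature is constant, alpha1/alpha2 are not identifiable",
                          lo, hi), "degenerate_fit")
    }
    obj <- function(a) mean((predict_formula(e, bmi, a) - y)^2)
    res <- nmpso_minimize(obj, 3L, config)
    rows[[length(rows) + 1L]] <- data.frame(
      lo = lo, hi = hi, alpha0 = res$x_best[1], alpha1 = res$x_best[2],
      alpha2 = res$x_best[3], mse = res$f_best, n = n_sel)
  }
  if (length(rows) == 0L) stop_invalid("no BMI interval contains any record")
  out <- do.call(rbind, rows)
  attr(out, "target") <- cols$target
  class(out) <- c("bp_formula_table", class(out))
  out
}

#' Calibrate the regression formula by ordinary least squares
#'
#' Solves `beta = (X'X)^{-1} X'y` for the design `X = [1, BMI, E]` through a
#' QR least-squares decomposition (numerically stable and mathematically
#' equal to the normal equations).
#'
#' @inheritParams fit_nmpso
#' @return List of class `regression_params` with `gamma` (length 3),
#'   `target`, `n` and `sigma` (residual SD).
#' @export
fit_regression <- function(records, target = c("SBP", "DBP")) {
  cols <- records_columns(records, match.arg(target))
  n <- length(cols$y)
  if (n < 3L) stop_invalid("regression needs at least 3 records")
  design <- cbind(1, records$bmi, cols$e)
  if (qr(design)$rank < 3L) {
    palmbp_stop("design matrix [1, BMI, E] is rank deficient", "singular_design")
  }
  fit <- stats::lm.fit(design, cols$y)
  gamma <- unname(fit$coefficients)
  structure(list(gamma = gamma, target = cols$target, n = n,
                 sigma = sqrt(sum(fit$residuals^2) / max(n - 3L, 1L))),
            class = "regression_params")
}

#' Serialize calibration parameters to JSON
#'
#' Formula tables use
#' `{"target": "SBP", "intervals": [{"lo": ..., "hi": ..., "alpha": [...]}]}`;
#' regression parameters use `{"target": "DBP", "gamma": [...]}`.
#'
#' @param params A `bp_formula_table` or `regression_params`.
#' @param path Output JSON path.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "bp_formula_table")) {
    doc <- list(
      method = "nmpso", target = attr(params, "target"),
      intervals = lapply(seq_len(nrow(params)), function(i) {
        list(lo = params$lo[i], hi = params$hi[i],
             alpha = c(params$alpha0[i], params$alpha1[i], params$alpha2[i]))
      })
    )
  } else if (inherits(params, "regression_params")) {
    doc <- list(method = "regression", target = params$target,
                gamma = params$gamma)
  } else {
    stop_invalid("`params` must be a bp_formula_table or regression_params")
  }
  fp <- attr(params, "fingerprint")
  if (!is.null(fp)) doc$fingerprint <- fp
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- if (identical(doc$method, "nmpso")) {
    tab <- do.call(rbind, lapply(doc$intervals, function(iv) {
      data.frame(lo = iv$lo, hi = iv$hi, alpha0 = iv$alpha[1],
                 alpha1 = iv$alpha[2], alpha2 = iv$alpha[3])
    }))
    attr(tab, "target") <- doc$target
    class(tab) <- c("bp_formula_table", class(tab))
    tab
  } else if (identical(doc$method, "regression")) {
    structure(list(gamma = unlist(doc$gamma), target = doc$target),
              class = "regression_params")
  } else {
    stop_invalid("parameter JSON must have method 'nmpso' or 'regression'")
  }
  if (!is.null(doc$fingerprint)) attr(out, "fingerprint") <- doc$fingerprint
  out
}
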