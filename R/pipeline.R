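#' @title End-to-end measurement pipeline
#' @description Orchestrates frames/trace -> ROI trace -> ICA -> peak/valley
#'   features -> blood-pressure prediction, with provenance metadata binding
#'   calibration coefficients to the exact preprocessing settings that
#'   produced their features.
#' @name pipeline
NULL

#' Preprocessing configuration and fingerprint
#'
#' Collects every setting that shapes the extracted Epeak/Evalley features.
#' Because the formula coefficients absorb the feature scale, a calibration
#' is only valid for predictions made under the identical preprocessing; the
#' fingerprint (a short hash of the canonical JSON of these settings) is
#' stored with calibration output and checked at measurement time.
#'
#' @param min_interval_s Minimum peak-trough interval in seconds.
#' @param prenormalize Z-score the channel trace before ICA.
#' @param ica An [ica_config()]; `n_components = NULL` adapts to the
#'   dimensions retained by whitening.
#' @param band Physiologic frequency band (Hz) for pulse-component
#'   selection.
#' @return A list of class `preprocessing_config`.
#' @export
preprocessing_config <- function(min_interval_s = 0.25, prenormalize = TRUE,
                                 ica = ica_config(n_components = NULL),
                                 band = c(0.7, 3.0)) {
  structure(list(min_interval_s = min_interval_s, prenormalize = prenormalize,
                 ica = unclass(ica), band = band),
            class = "preprocessing_config")
}

#' @rdname preprocessing_config
#' @param config A `preprocessing_config`.
#' @export
preprocessing_fingerprint <- function(config) {
  stopifnot(inherits(config, "preprocessing_config"))
  json <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE,
                           null = "null")
  string_fingerprint(as.character(json))
}

input_duration <- function(input) {
  if (inherits(input, "pulse_trace")) length(input$samples) / input$fps
  else if (inherits(input, "rgb_trace")) nrow(input$rgb) / input$fps
  else if (is.list(input) && !is.null(input$frames)) length(input$frames) / input$fps
  else stop_invalid("input must be a pulse_trace, rgb_trace, or frames+landmarks list")
}

#' Extract Epeak/Evalley features from any supported input
#'
#' Accepts a single-channel [pulse_trace()] (used directly), an
#' [rgb_trace()] (normalized, ICA-decomposed, pulse component selected), or
#' a frames+landmarks list as produced by [render_synthetic_frames()] (ROI
#' channel means first, then the rgb path). Ends in [ten_window_summary()].
#'
#' @param input The signal input.
#' @param config A [preprocessing_config()].
#' @return A `peak_valley_summary`.
#' @export
extract_features <- function(input, config = preprocessing_config()) {
  if (is.list(input) && !is.null(input$frames) && !inherits(input, "pulse_trace")) {
    d <- dim(input$frames[[1]])
    poly <- roi_polygon(input$landmarks[[1]], d[2], d[1])
    input <- channel_means(input$frames, poly, input$fps)
  }
  if (inherits(input, "rgb_trace")) {
    tr <- if (isTRUE(config$prenormalize)) normalize_trace(input) else input
    ica_cfg <- do.call(ica_config, config$ica)
    res <- ica_decompose(t(tr$rgb), ica_cfg)
    input <- select_pulse_component(res$y, tr$fps, config$band)
  }
  stopifnot(inherits(input, "pulse_trace"))
  ten_window_summary(input, config$min_interval_s)
}

#' One non-contact blood-pressure measurement
#'
#' Runs the full chain: BMI from height and weight, feature extraction from
#' the input signal, then prediction through the calibrated formula
#' (`method = "nmpso"`, with BMI-interval parameter lookup) or the
#' regression formula (`method = "regression"`). The input must cover at
#' least 10 s and the calibration's preprocessing fingerprint must match the
#' supplied configuration.
#'
#' @param input A [pulse_trace()], [rgb_trace()] or frames+landmarks list.
#' @param height,weight Subject height (m) and weight (kg).
#' @param calibration A `bp_calibration` from [calibrate_cohort()].
#' @param config The [preprocessing_config()] in force.
#' @return List of class `measurement_result` with `sbp`, `dbp`, `method`,
#'   `e_peak`, `e_valley`, `bmi`, `windows_used` and the fingerprint.
#' @export
measure_bp <- function(input, height, weight, calibration,
                       config = preprocessing_config()) {
  if (!inherits(calibration, "bp_calibration")) {
    stop_invalid("`calibration` must come from calibrate_cohort()")
  }
  if (input_duration(input) < 10) {
    stop_invalid("measurement input must cover at least 10 s")
  }
  fp <- preprocessing_fingerprint(config)
  if (!identical(fp, calibration$fingerprint)) {
    palmbp_stop("preprocessing configuration does not match the calibration fingerprint; recalibrate or restore the original settings",
                "calibration_mismatch")
  }
  bmi <- compute_bmi(height, weight)
  feats <- extract_features(input, config)
  if (calibration$method == "nmpso") {
    ps <- bmi_interval_lookup(bmi, calibration$sbp)
    pd <- bmi_interval_lookup(bmi, calibration$dbp)
    sbp <- predict_formula(feats$e_peak, bmi, c(ps$alpha0, ps$alpha1, ps$alpha2))
    dbp <- predict_formula(feats$e_valley, bmi, c(pd$alpha0, pd$alpha1, pd$alpha2))
  } else {
    sbp <- predict_regression(bmi, feats$e_peak, calibration$sbp$gamma)
    dbp <- predict_regression(bmi, feats$e_valley, calibration$dbp$gamma)
  }
  structure(list(sbp = sbp, dbp = dbp, method = calibration$method,
                 e_peak = feats$e_peak, e_valley = feats$e_valley,
                 bmi = bmi, windows_used = feats$windows_used,
                 preprocessing_fingerprint = fp),
            class = "measurement_result")
}

#' @export
print.measurement_result <- function(x, ...) {
  cat(sprintf("<measurement_result> SBP %.1f / DBP %.1f mmHg (%s method)\n",
              x$sbp, x$dbp, x$method))
  cat(sprintf("  BMI %.1f, Epeak %.4f, Evalley %.4f, %d/10 windows\n",
              x$bmi, x$e_peak, x$e_valley, x$windows_used))
  invisible(x)
}

validate_subject <- function(s, i) {
  need <- c("sbp_device", "dbp_device")
  for (field in need) {
    if (is.null(s[[field]]) || !is_scalar_num(s[[field]])) {
      palmbp_stop(sprintf("subject %d is missing a finite `%s`", i, field),
                  "validation")
    }
  }
  if (is.null(s$bmi)) {
    if (is.null(s$height) || is.null(s$weight)) {
      palmbp_stop(sprintf("subject %d needs `bmi` or `height`+`weight`", i),
                  "validation")
    }
  }
  invisible(TRUE)
}

#' Calibrate both formulas from raw signals and device readings
#'
#' Runs the full feature path on every subject's signal, assembles the
#' calibration records, and dispatches to [fit_nmpso()] (per BMI interval)
#' or [fit_regression()]. The result embeds the preprocessing fingerprint so
#' later measurements can verify they use the same feature path.
#'
#' @param subjects List of subjects; each is a list with `input` (a
#'   [pulse_trace()], [rgb_trace()] or frames+landmarks list), device
#'   readings `sbp_device` and `dbp_device`, and either `bmi` or
#'   `height`+`weight`.
#' @param method `"nmpso"` or `"regression"`.
#' @param config The [preprocessing_config()].
#' @param bmi_intervals Intervals for the nmpso route.
#' @param nm_config Optimizer settings for the nmpso route.
#' @return List of class `bp_calibration` with `method`, `sbp`, `dbp`
#'   parameter objects, `records` and `fingerprint`.
#' @export
calibrate_cohort <- function(subjects, method = c("nmpso", "regression"),
                             config = preprocessing_config(),
                             bmi_intervals = default_bmi_intervals(),
                             nm_config = nmpso_config(x_bounds = c(-120, 120))) {
  method <- match.arg(method)
  records <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    validate_subject(s, i)
    bmi <- if (!is.null(s$bmi)) s$bmi else compute_bmi(s$height, s$weight)
    feats <- extract_features(s$input, config)
    data.frame(bmi = bmi, sbp_device = s$sbp_device, dbp_device = s$dbp_device,
               e_peak = feats$e_peak, e_valley = feats$e_valley)
  }))
  cal <- if (method == "nmpso") {
    list(sbp = fit_nmpso(records, "SBP", bmi_intervals, nm_config),
         dbp = fit_nmpso(records, "DBP", bmi_intervals, nm_config))
  } else {
    list(sbp = fit_regression(records, "SBP"),
         dbp = fit_regression(records, "DBP"))
  }
  structure(list(method = method, sbp = cal$sbp, dbp = cal$dbp,
                 records = records,
                 fingerprint = preprocessing_fingerprint(config)),
            class = "bp_calibration")
}

#' Synthetic closed-loop study subjects
#'
#' Builds a cohort of subjects whose pulse traces differ in heart rate and
#' harmonic content (so the normalized Epeak/Evalley features genuinely vary
#' across subjects) and whose device readings are generated by applying the
#' true formula coefficients to the features extracted through the given
#' preprocessing path, optionally plus Gaussian device noise. Calibrating on
#' such a cohort and re-measuring its members closes the loop exactly when
#' the pipeline is self-consistent.
#'
#' @param n Number of subjects.
#' @param alpha_sbp,alpha_dbp True length-3 formula coefficients.
#' @param config The [preprocessing_config()] the study uses throughout.
#' @param bmi_range Uniform BMI range.
#' @param duration,fps Capture length (s) and rate (frames/s).
#' @param noise_sd Device noise SD, mmHg.
#' @param input_type `"trace"` hands each subject's pulse trace to the
#'   feature path directly; `"frames"` renders synthetic palm frames and
#'   exercises the full ROI -> ICA chain.
#' @param seed RNG seed.
#' @return List of subject lists compatible with [calibrate_cohort()].
#' @export
synthetic_subjects <- function(n, alpha_sbp = c(65, 15, 0.4),
                               alpha_dbp = c(60, 12, -0.25),
                               config = preprocessing_config(),
                               bmi_range = c(18.5, 30),
                               duration = 10.5, fps = 20,
                               noise_sd = 0,
                               input_type = c("trace", "frames"),
                               seed = 0L) {
  input_type <- match.arg(input_type)
  draws <- with_seed(seed, {
    data.frame(
      bmi = stats::runif(n, bmi_range[1], bmi_range[2]),
      hr_hz = stats::runif(n, 1.05, 1.5),
      phase = stats::runif(n, 0, 2 * pi),
      a2 = stats::runif(n, 0.05, 0.2),
      b2 = stats::runif(n, -0.1, 0.1),
      noise_sbp = stats::rnorm(n, 0, noise_sd),
      noise_dbp = stats::rnorm(n, 0, noise_sd)
    )
  })
  lapply(seq_len(n), function(i) {
    # random systolic phase: rotate harmonic k by k * phase so no subject has
    # its peaks pinned to the analysis-window boundaries
    rot <- function(ab, theta) {
      c(ab[1] * cos(theta) + ab[2] * sin(theta),
        -ab[1] * sin(theta) + ab[2] * cos(theta))
    }
    p <- pulse_model_params(
      a0 = 0,
      harmonics = rbind(rot(c(1, 0), draws$phase[i]),
                        rot(c(draws$a2[i], draws$b2[i]), 2 * draws$phase[i])),
      omega_h = 2 * pi * draws$hr_hz[i]
    )
    trace <- simulate_pulse_wave(p, fps = fps, duration = duration)
    input <- if (input_type == "frames") {
      # amplitude 5 intensity units on an 8-bit baseline of 120
      scaled <- pulse_trace(5 * trace$samples, trace$fps)
      render_synthetic_frames(scaled, seed = seed + i)
    } else {
      trace
    }
    feats <- extract_features(input, config)
    list(
      input = input,
      bmi = draws$bmi[i],
      sbp_device = predict_formula(feats$e_peak, draws$bmi[i], alpha_sbp) +
        draws$noise_sbp[i],
      dbp_device = predict_formula(feats$e_valley, draws$bmi[i], alpha_dbp) +
        draws$noise_dbp[i]
    )
  })
}
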