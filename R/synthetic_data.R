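#' Harmonic pulse-waveform model parameters
#'
#' Parameterizes the radial-resonance description of the arterial pulse: a
#' baseline intensity plus `N` harmonics of a fundamental cardiac angular
#' frequency, each harmonic attenuated by `exp(-k * z / c)` where `z` is the
#' subject-to-lens distance and `c` the wave speed.
#'
#' @param a0 Baseline amplitude (arbitrary intensity units).
#' @param harmonics Numeric matrix with columns `a` and `b` (cosine and sine
#'   amplitudes), one row per harmonic `k = 1..N`; may have zero rows.
#' @param omega_h Fundamental angular frequency in rad/s; for a heart rate of
#'   `f` beats per second this is `2 * pi * f`.
#' @param z Subject-to-lens distance in metres (default 0: no attenuation).
#' @param c_wave Wave propagation speed in m/s.
#' @return An object of class `pulse_model_params`.
#' @export
pulse_model_params <- function(a0 = 0, harmonics = NULL, omega_h = 2 * pi * 1.2,
                               z = 0, c_wave = 1) {
  if (is.null(harmonics)) {
    harmonics <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  }
  harmonics <- as.matrix(harmonics)
  if (ncol(harmonics) != 2L) stop_invalid("`harmonics` needs columns (a, b)")
  colnames(harmonics) <- c("a", "b")
  if (!is_scalar_num(omega_h) || omega_h <= 0) stop_invalid("`omega_h` must be > 0")
  if (!is_scalar_num(c_wave) || c_wave <= 0) stop_invalid("`c_wave` must be > 0")
  if (!is_scalar_num(z) || z < 0) stop_invalid("`z` must be >= 0")
  if (!is_scalar_num(a0)) stop_invalid("`a0` must be a finite scalar")
  structure(
    list(a0 = a0, harmonics = harmonics, omega_h = omega_h, z = z,
         c_wave = c_wave, n_harmonics = nrow(harmonics)),
    class = "pulse_model_params"
  )
}

#' Uniformly sampled pulse signal
#'
#' @param samples Numeric vector of intensities.
#' @param fps Sampling rate in frames per second (> 0).
#' @return An object of class `pulse_trace`.
#' @export
pulse_trace <- function(samples, fps) {
  samples <- as.numeric(samples)
  if (!is_scalar_num(fps) || fps <= 0) stop_invalid("`fps` must be > 0")
  if (length(samples) < 1L || !all(is.finite(samples))) {
    stop_invalid("`samples` must be non-empty and finite")
  }
  structure(list(samples = samples, fps = fps), class = "pulse_trace")
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf("<pulse_trace> %d samples at %g fps (%.2f s)\n",
              length(x$samples), x$fps, length(x$samples) / x$fps))
  invisible(x)
}

#' Simulate a harmonic pulse waveform
#'
#' Samples the radial-resonance pulse model
#' `p(t) = a0 + sum_k (a_k cos(w k t) + b_k sin(w k t)) exp(-k z / c)`
#' at `fps` frames per second for `duration` seconds, optionally adding
#' i.i.d. Gaussian sensor noise.
#'
#' @param params A [pulse_model_params()] object.
#' @param fps Sampling rate, frames/s.
#' @param duration Length of the capture, seconds.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units, >= 0).
#' @param seed RNG seed used for the noise draw.
#' @return A [pulse_trace()].
#' @export
simulate_pulse_wave <- function(params, fps, duration, noise_sd = 0, seed = 0L) {
  stopifnot(inherits(params, "pulse_model_params"))
  if (!is_scalar_num(fps) || fps <= 0) stop_invalid("`fps` must be > 0")
  if (!is_scalar_num(duration) || duration <= 0) stop_invalid("`duration` must be > 0")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  n <- floor(duration * fps)
  if (n < 2L) stop_invalid("`duration * fps` must be >= 2")
  t <- (seq_len(n) - 1) / fps
  p <- rep(params$a0, n)
  if (params$n_harmonics > 0L) {
    for (k in seq_len(params$n_harmonics)) {
      att <- exp(-k * params$z / params$c_wave)
      p <- p + (params$harmonics[k, "a"] * cos(params$omega_h * k * t) +
                params$harmonics[k, "b"] * sin(params$omega_h * k * t)) * att
    }
  }
  if (noise_sd > 0) p <- p + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  pulse_trace(p, fps)
}

#' Mix source signals through a known mixing matrix
#'
#' Forms the observed multichannel matrix `X = A S`, the forward model that
#' blind and semi-blind source separation invert.
#'
#' @param sources Matrix `S`, `n_sources x n_samples`.
#' @param mixing Matrix `A`, `n_channels x n_sources`.
#' @param require_full_rank If `TRUE`, error when `A` is column-rank
#'   deficient (required for semi-blind unmixing downstream).
#' @return List with the observed matrix `x`, and `mixing`/`sources` retained
#'   for semi-blind tests.
#' @export
mix_sources <- function(sources, mixing, require_full_rank = FALSE) {
  sources <- as.matrix(sources)
  mixing <- as.matrix(mixing)
  if (ncol(mixing) != nrow(sources)) {
    palmbp_stop(sprintf("non-conformable: mixing is %dx%d but sources has %d rows",
                        nrow(mixing), ncol(mixing), nrow(sources)),
                "dimension_error")
  }
  if (require_full_rank && qr(mixing)$rank < ncol(mixing)) {
    palmbp_stop("mixing matrix is column-rank deficient; semi-blind unmixing needs full column rank",
                "singular_matrix")
  }
  list(x = mixing %*% sources, mixing = mixing, sources = sources)
}

#' Generate a synthetic calibration cohort
#'
#' Draws subjects with BMI and normalized pulse features uniform over the
#' given ranges, then assigns device systolic/diastolic readings from the
#' empirical blood-pressure formula
#' `BP = alpha0 + alpha1 * x + BMI * (1 + alpha2 * x)` (x = Epeak for SBP,
#' Evalley for DBP) plus Gaussian device noise. Stands in for a volunteer
#' cohort measured against a cuff reference.
#'
#' @param n Number of subjects.
#' @param alpha_sbp,alpha_dbp Length-3 coefficient vectors (alpha0, alpha1,
#'   alpha2) generating the device readings.
#' @param bmi_range Length-2 interval for BMI (kg/m^2).
#' @param feature_range Length-2 interval for the normalized Epeak/Evalley
#'   draws; `e_peak > e_valley` is enforced by swapping.
#' @param noise_sd Device noise SD in mmHg (>= 0).
#' @param seed RNG seed; the cohort is a pure function of it.
#' @return A data frame with columns `bmi`, `sbp_device`, `dbp_device`,
#'   `e_peak`, `e_valley` (one row per subject).
#' @export
generate_cohort <- function(n, alpha_sbp, alpha_dbp,
                            bmi_range = c(18.5, 30),
                            feature_range = c(0, 1),
                            noise_sd = 2, seed = 0L) {
  if (!is_scalar_num(n) || n < 1) stop_invalid("`n` must be >= 1")
  if (!is_scalar_num(noise_sd) || noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (diff(bmi_range) <= 0 || diff(feature_range) <= 0) {
    stop_invalid("`bmi_range` and `feature_range` must be non-empty intervals")
  }
  stopifnot(length(alpha_sbp) == 3L, length(alpha_dbp) == 3L)
  n <- as.integer(n)
  with_seed(seed, {
    bmi <- stats::runif(n, bmi_range[1], bmi_range[2])
    e1 <- stats::runif(n, feature_range[1], feature_range[2])
    e2 <- stats::runif(n, feature_range[1], feature_range[2])
    e_peak <- pmax(e1, e2)
    e_valley <- pmin(e1, e2)
    sbp <- predict_formula(e_peak, bmi, alpha_sbp)
    dbp <- predict_formula(e_valley, bmi, alpha_dbp)
    if (noise_sd > 0) {
      sbp <- sbp + stats::rnorm(n, 0, noise_sd)
      dbp <- dbp + stats::rnorm(n, 0, noise_sd)
    }
    data.frame(bmi = bmi, sbp_device = sbp, dbp_device = dbp,
               e_peak = e_peak, e_valley = e_valley)
  })
}

#' Render synthetic palm frames from a pulse trace
#'
#' Produces an RGB frame sequence in which the green channel inside a palm
#' polygon follows `baseline + trace`, clipped to the 8-bit range, while
#' pixels outside the polygon hold a static seeded background. Per-frame hand
#' landmarks are emitted with points 1, 5, 17 and 0 at the polygon's
#' vertices, so the region-of-interest extraction stage can be exercised
#' without a camera.
#'
#' @param trace A [pulse_trace()] whose samples modulate the green channel.
#' @param frame_size Length-2 integer (width, height) in pixels.
#' @param palm_polygon 4x2 matrix of polygon vertices in pixel coordinates
#'   (0-based, x then y), in the cyclic order of landmarks 1, 5, 17, 0.
#' @param baseline Green-channel resting intensity inside the palm.
#' @param seed Seed for the static background.
#' @return List with `frames` (list of height x width x 3 arrays, values in
#'   0..255), `landmarks` (list of 21x2 matrices in normalized \[0,1\]
#'   coordinates, one per frame) and `fps`.
#' @export
render_synthetic_frames <- function(trace, frame_size = c(48L, 48L),
                                    palm_polygon = NULL, baseline = 120,
                                    seed = 0L) {
  stopifnot(inherits(trace, "pulse_trace"))
  w <- as.integer(frame_size[1]); h <- as.integer(frame_size[2])
  if (w < 2L || h < 2L) stop_invalid("`frame_size` must be at least 2x2")
  if (is.null(palm_polygon)) {
    palm_polygon <- matrix(c(
      0.15 * w, 0.70 * h,   # 1  THUMB_CMC
      0.30 * w, 0.15 * h,   # 5  INDEX_FINGER_MCP
      0.80 * w, 0.25 * h,   # 17 PINKY_MCP
      0.70 * w, 0.85 * h    # 0  WRIST
    ), ncol = 2, byrow = TRUE)
  }
  palm_polygon <- as.matrix(palm_polygon)
  if (nrow(palm_polygon) != 4L || ncol(palm_polygon) != 2L) {
    stop_invalid("`palm_polygon` must be a 4x2 vertex matrix")
  }
  if (any(palm_polygon[, 1] < 0) || any(palm_polygon[, 1] > w - 1) ||
      any(palm_polygon[, 2] < 0) || any(palm_polygon[, 2] > h - 1)) {
    stop_invalid("`palm_polygon` must lie inside the frame bounds")
  }
  if (polygon_area(palm_polygon) <= 0) {
    palmbp_stop("palm polygon is degenerate (zero area)", "degenerate_roi")
  }
  n_frames <- length(trace$samples)
  if (n_frames > 100000L) stop_invalid("trace longer than the frame budget (1e5 frames)")

  mask <- polygon_pixel_mask(palm_polygon, w, h)
  if (!any(mask)) palmbp_stop("palm polygon contains no pixel centers", "degenerate_roi")

  background <- with_seed(seed, {
    arr <- array(0, dim = c(h, w, 3))
    arr[, , 1] <- matrix(stats::runif(h * w, 60, 90), h, w)
    arr[, , 2] <- matrix(stats::runif(h * w, 60, 90), h, w)
    arr[, , 3] <- matrix(stats::runif(h * w, 60, 90), h, w)
    arr
  })
  # inside the palm: fixed red/blue skin tone; green carries the pulse
  red_in <- 150; blue_in <- 110

  # landmarks in normalized [0,1] image coordinates; unused points sit at
  # the polygon centroid
  centroid <- colMeans(palm_polygon)
  lm <- matrix(rep(centroid, each = 21), ncol = 2)
  lm[2, ] <- palm_polygon[1, ]   # index 1
  lm[6, ] <- palm_polygon[2, ]   # index 5
  lm[18, ] <- palm_polygon[3, ]  # index 17
  lm[1, ] <- palm_polygon[4, ]   # index 0
  lm[, 1] <- lm[, 1] / (w - 1)
  lm[, 2] <- lm[, 2] / (h - 1)

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    fr <- background
    r <- fr[, , 1]; g <- fr[, , 2]; b <- fr[, , 3]
    r[mask] <- red_in
    g[mask] <- pmin(pmax(baseline + trace$samples[i], 0), 255)
    b[mask] <- blue_in
    fr[, , 1] <- r; fr[, , 2] <- g; fr[, , 3] <- b
    frames[[i]] <- fr
  }
  list(frames = frames, landmarks = rep(list(lm), n_frames), fps = trace$fps,
       polygon = palm_polygon)
}

#' Write / read a calibration cohort as CSV
#'
#' Plain UTF-8 CSV with header `bmi,sbp_device,dbp_device,e_peak,e_valley`.
#'
#' @param cohort Data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("bmi", "sbp_device", "dbp_device", "e_peak", "e_valley")
  if (!all(cols %in% names(cohort))) {
    stop_invalid(sprintf("cohort must have columns %s", paste(cols, collapse = ", ")))
  }
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("bmi", "sbp_device", "dbp_device", "e_peak", "e_valley")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop_invalid(sprintf("cohort CSV missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  df[cols]
}

#' Write / read a signal trace as CSV
#'
#' Single-channel traces use header `t,value`; three-channel traces use
#' `t,r,g,b`.
#'
#' @param trace A [pulse_trace()] or an `rgb_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "pulse_trace")) {
    t <- (seq_along(trace$samples) - 1) / trace$fps
    utils::write.csv(data.frame(t = t, value = trace$samples), path,
                     row.names = FALSE, quote = FALSE)
  } else if (inherits(trace, "rgb_trace")) {
    t <- (seq_len(nrow(trace$rgb)) - 1) / trace$fps
    utils::write.csv(data.frame(t = t, r = trace$rgb[, 1], g = trace$rgb[, 2],
                                b = trace$rgb[, 3]),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    stop_invalid("`trace` must be a pulse_trace or rgb_trace")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) < 2L) stop_invalid("trace CSV needs at least 2 rows")
  fps <- 1 / stats::median(diff(df$t))
  if (all(c("r", "g", "b") %in% names(df))) {
    rgb_trace(as.matrix(df[c("r", "g", "b")]), fps)
  } else if ("value" %in% names(df)) {
    pulse_trace(df$value, fps)
  } else {
    stop_invalid("trace CSV must have columns t,value or t,r,g,b")
  }
}
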