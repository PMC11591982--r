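#' @title Pulse-wave peak/valley feature extraction
#' @description Local extrema detection with plateau handling, the 0.25 s
#'   refractory interval filter between neighbouring peaks and troughs, and
#'   the ten-window averaging that yields the Epeak/Evalley features entering
#'   the blood-pressure formulas.
#' @name pulse_features
NULL

# Strict 3-point local extrema after run-length compressing plateaus; a run
# of equal samples contributes one candidate at its first index. Returns
# 1-based sample indices.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(peaks = integer(0), valleys = integer(0)))
  r <- rle(v)
  vals <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  m <- length(vals)
  if (m < 3L) return(list(peaks = integer(0), valleys = integer(0)))
  i <- 2:(m - 1L)
  is_peak <- vals[i] > vals[i - 1L] & vals[i] > vals[i + 1L]
  is_valley <- vals[i] < vals[i - 1L] & vals[i] < vals[i + 1L]
  list(peaks = starts[i][is_peak], valleys = starts[i][is_valley])
}

#' Detect peaks and valleys with a minimum peak-trough interval
#'
#' Local maxima and minima are found by strict three-point comparison (runs
#' of equal samples count once, at the run's first sample). Then any
#' adjacent peak-trough pair closer than `round(min_interval_s * fps)`
#' samples is discarded, both members, repeatedly until every neighbouring
#' pair of retained extrema is at least that far apart. Because extrema
#' alternate and whole adjacent pairs are removed, the retained extrema
#' still alternate in time.
#'
#' @param trace A [pulse_trace()].
#' @param min_interval_s Minimum peak-trough spacing in seconds
#'   (default 0.25).
#' @return List with `hd` (peak values), `hl` (valley values),
#'   `peak_idx`/`valley_idx` (1-based sample indices). Traces shorter than 3
#'   samples yield empty results.
#' @export
detect_peaks_valleys <- function(trace, min_interval_s = 0.25) {
  stopifnot(inherits(trace, "pulse_trace"))
  if (!is_scalar_num(min_interval_s) || min_interval_s < 0) {
    stop_invalid("`min_interval_s` must be >= 0")
  }
  v <- trace$samples
  ext <- local_extrema(v)
  idx <- c(ext$peaks, ext$valleys)
  type <- rep(c(1L, -1L), c(length(ext$peaks), length(ext$valleys)))
  o <- order(idx)
  idx <- idx[o]; type <- type[o]
  min_gap <- round(min_interval_s * trace$fps)
  repeat {
    if (length(idx) < 2L) break
    gaps <- diff(idx)
    bad <- which(gaps < min_gap)
    if (!length(bad)) break
    drop_at <- bad[1]
    keep <- setdiff(seq_along(idx), c(drop_at, drop_at + 1L))
    idx <- idx[keep]; type <- type[keep]
  }
  list(hd = v[idx[type == 1L]], hl = v[idx[type == -1L]],
       peak_idx = idx[type == 1L], valley_idx = idx[type == -1L])
}

#' Average retained peak / valley values
#'
#' The Epeak (resp. Evalley) statistic: the arithmetic mean of the retained
#' peak (valley) intensities.
#'
#' @param hd,hl Numeric vectors of retained peak / valley values.
#' @return The mean, a scalar.
#' @export
average_peaks <- function(hd) {
  if (length(hd) == 0L) palmbp_stop("no retained peaks to average", "no_beats")
  sum(hd) / length(hd)
}

#' @rdname average_peaks
#' @export
average_valleys <- function(hl) {
  if (length(hl) == 0L) palmbp_stop("no retained valleys to average", "no_beats")
  sum(hl) / length(hl)
}

#' Ten-window Epeak/Evalley summary of a measurement
#'
#' Splits the first 10 s of the trace into ten consecutive, non-overlapping
#' 1 s windows. In each window the extrema are detected, interval-filtered
#' and averaged to one peak value and one valley value; the measurement's
#' Epeak/Evalley are the means of the per-window values. Windows in which no
#' extremum survives are skipped; `windows_used` records how many actually
#' contributed.
#'
#' @param trace A [pulse_trace()] of duration >= 10 s.
#' @param min_interval_s Minimum peak-trough spacing passed to
#'   [detect_peaks_valleys()].
#' @return List of class `peak_valley_summary` with fields `hd`, `hl`
#'   (retained peak/valley values pooled over windows), `n1`, `n2` (their
#'   counts), `e_peak`, `e_valley`, and `windows_used`.
#' @export
ten_window_summary <- function(trace, min_interval_s = 0.25) {
  stopifnot(inherits(trace, "pulse_trace"))
  n <- length(trace$samples)
  if (n / trace$fps < 10) {
    stop_invalid(sprintf("trace lasts %.2f s; the measurement needs >= 10 s",
                         n / trace$fps))
  }
  peak_means <- numeric(0)
  valley_means <- numeric(0)
  hd_all <- numeric(0)
  hl_all <- numeric(0)
  used <- 0L
  for (wdw in 1:10) {
    lo <- floor((wdw - 1) * trace$fps) + 1L
    hi <- min(floor(wdw * trace$fps), n)
    sub <- pulse_trace(trace$samples[lo:hi], trace$fps)
    pv <- detect_peaks_valleys(sub, min_interval_s)
    if (length(pv$hd) == 0L && length(pv$hl) == 0L) next
    used <- used + 1L
    if (length(pv$hd)) {
      peak_means <- c(peak_means, mean(pv$hd))
      hd_all <- c(hd_all, pv$hd)
    }
    if (length(pv$hl)) {
      valley_means <- c(valley_means, mean(pv$hl))
      hl_all <- c(hl_all, pv$hl)
    }
  }
  if (used == 0L) palmbp_stop("no window retained any pulse extremum", "no_beats")
  structure(list(
    hd = hd_all, hl = hl_all, n1 = length(hd_all), n2 = length(hl_all),
    e_peak = if (length(peak_means)) mean(peak_means) else NA_real_,
    e_valley = if (length(valley_means)) mean(valley_means) else NA_real_,
    windows_used = used
  ), class = "peak_valley_summary")
}

#' @export
print.peak_valley_summary <- function(x, ...) {
  cat(sprintf("<peak_valley_summary> Epeak %.4f (n1=%d), Evalley %.4f (n2=%d), %d/10 windows\n",
              x$e_peak, x$n1, x$e_valley, x$n2, x$windows_used))
  invisible(x)
}
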