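#' @title Independent component analysis for pulse denoising
#' @description Centering, eigenvalue whitening with a noise-variance
#'   rejection threshold, deflationary FastICA, and fast semi-blind unmixing
#'   when the mixing matrix is known. Channels are rows, samples columns.
#' @name ica_denoise
NULL

#' FastICA configuration
#'
#' @param n_components Number of independent components to estimate, or
#'   `NULL` to use every dimension retained by whitening. Default 3 (the
#'   three observed color channels).
#' @param max_iter Iteration cap per component.
#' @param tol Convergence tolerance: a component is converged when the inner
#'   product between successive unit weight vectors exceeds `1 - tol`.
#' @param var_threshold Relative eigenvalue cutoff for whitening: directions
#'   whose covariance eigenvalue is below `var_threshold * sum(eigenvalues)`
#'   are rejected as noise.
#' @param contrast Nonlinearity, `"logcosh"` (robust default) or `"cube"`
#'   (kurtosis-based).
#' @param seed Seed for the random initial weight vectors.
#' @return A list of class `ica_config`.
#' @export
ica_config <- function(n_components = 3L, max_iter = 200L, tol = 1e-6,
                       var_threshold = 1e-6, contrast = c("logcosh", "cube"),
                       seed = 0L) {
  contrast <- match.arg(contrast)
  if (!is.null(n_components) && (!is_scalar_num(n_components) || n_components < 1)) {
    stop_invalid("`n_components` must be >= 1 or NULL")
  }
  if (!is_scalar_num(tol) || tol <= 0) stop_invalid("`tol` must be > 0")
  if (!is_scalar_num(var_threshold) || var_threshold < 0 || var_threshold >= 1) {
    stop_invalid("`var_threshold` must be in [0, 1)")
  }
  structure(list(n_components = n_components, max_iter = as.integer(max_iter),
                 tol = tol, var_threshold = var_threshold, contrast = contrast,
                 seed = seed),
            class = "ica_config")
}

#' Center a multichannel signal matrix
#'
#' Subtracts the per-channel mean so every row of the result has mean zero;
#' the mean is returned so the transform can be inverted.
#'
#' @param x Numeric matrix, channels x samples, with >= 2 samples.
#' @return List with `xhat` (centered matrix) and `mean` (per-channel means).
#' @export
ica_center <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_invalid("centering needs at least 2 samples per channel")
  mu <- rowMeans(x)
  list(xhat = x - mu, mean = mu)
}

#' Whiten a centered signal matrix with noise rejection
#'
#' Eigendecomposes the (population) sample covariance, drops directions whose
#' eigenvalue falls below `var_threshold` times the total variance, and
#' rescales the rest to unit variance, so the output has identity covariance
#' on the retained dimensions.
#'
#' @param xhat Centered matrix (channels x samples).
#' @param var_threshold Relative eigenvalue cutoff in \[0, 1).
#' @return List with `z` (whitened data, retained_dims x samples), `v` (the
#'   whitening matrix, `z = v %*% xhat`) and `eigenvalues`.
#' @export
ica_whiten <- function(xhat, var_threshold = 1e-6) {
  xhat <- as.matrix(xhat)
  n <- ncol(xhat)
  cov_x <- tcrossprod(xhat) / n
  eg <- eigen(cov_x, symmetric = TRUE)
  total <- sum(pmax(eg$values, 0))
  if (total <= 0) palmbp_stop("input has zero variance; no signal to whiten", "no_signal")
  keep <- eg$values >= var_threshold * total & eg$values > 0
  if (!any(keep)) {
    palmbp_stop("all eigenvalues fall below the noise-rejection threshold", "no_signal")
  }
  d <- eg$values[keep]
  e <- eg$vectors[, keep, drop = FALSE]
  v <- diag(1 / sqrt(d), nrow = length(d)) %*% t(e)
  list(z = v %*% xhat, v = v, eigenvalues = eg$values)
}

contrast_funs <- function(contrast) {
  if (contrast == "logcosh") {
    list(g = function(u) tanh(u), dg = function(u) 1 - tanh(u)^2)
  } else {
    list(g = function(u) u^3, dg = function(u) 3 * u^2)
  }
}

#' Deflationary FastICA on whitened data
#'
#' Estimates unmixing weight vectors one at a time by the fixed-point update
#' `w <- E[z g(w'z)] - E[g'(w'z)] w`, with Gram-Schmidt decorrelation against
#' previously found components and renormalization to unit norm after every
#' step. Iteration for a component stops when the absolute inner product of
#' successive weight vectors exceeds `1 - tol`, or at `max_iter` (in which
#' case the result is returned with `converged = FALSE`).
#'
#' @param z Whitened matrix (retained_dims x samples), e.g. from
#'   [ica_whiten()].
#' @param config An [ica_config()].
#' @return List of class `ica_result` with the unmixing matrix `w` (rows are
#'   unit weight vectors), components `y = w %*% z`, per-component
#'   `iterations`, and a `converged` flag.
#' @export
fastica <- function(z, config = ica_config()) {
  z <- as.matrix(z)
  d <- nrow(z)
  nc <- if (is.null(config$n_components)) d else as.integer(config$n_components)
  if (nc > d) {
    stop_invalid(sprintf("n_components (%d) exceeds the %d whitened dimensions", nc, d))
  }
  fns <- contrast_funs(config$contrast)
  n <- ncol(z)
  w <- matrix(0, nc, d)
  iters <- integer(nc)
  converged <- logical(nc)
  init <- with_seed(config$seed, matrix(stats::rnorm(nc * d), nc, d))
  for (i in seq_len(nc)) {
    wi <- init[i, ]
    wi <- wi / sqrt(sum(wi^2))
    for (it in seq_len(config$max_iter)) {
      wu <- drop(wi %*% z)
      w_new <- drop(z %*% fns$g(wu)) / n - mean(fns$dg(wu)) * wi
      if (i > 1L) {
        # decorrelate against components already extracted
        proj <- w[seq_len(i - 1L), , drop = FALSE]
        w_new <- w_new - drop(crossprod(proj, proj %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < .Machine$double.eps) {
        # degenerate direction; restart from a perturbed seed
        w_new <- init[i, ] + it
        w_new <- w_new / sqrt(sum(w_new^2))
      } else {
        w_new <- w_new / nrm
      }
      done <- abs(sum(w_new * wi)) > 1 - config$tol
      wi <- w_new
      if (done) break
    }
    w[i, ] <- wi
    iters[i] <- it
    converged[i] <- done
  }
  structure(list(w = w, y = w %*% z, iterations = iters,
                 converged = all(converged)),
            class = "ica_result")
}

#' Run the full ICA chain on a signal matrix
#'
#' Convenience wrapper: center, whiten with noise rejection, then FastICA.
#'
#' @param x Channels x samples matrix.
#' @param config An [ica_config()].
#' @return The [fastica()] result, augmented with the centering mean and
#'   whitening matrix.
#' @export
ica_decompose <- function(x, config = ica_config()) {
  cen <- ica_center(x)
  wh <- ica_whiten(cen$xhat, config$var_threshold)
  cfg <- config
  if (!is.null(cfg$n_components)) {
    cfg$n_components <- min(cfg$n_components, nrow(wh$z))
  }
  res <- fastica(wh$z, cfg)
  res$mean <- cen$mean
  res$v <- wh$v
  res
}

#' Semi-blind source separation with a known mixing matrix
#'
#' When the mixing matrix `A` is known the unmixing matrix is its
#' (pseudo-)inverse, recovering the centered sources directly and much faster
#' than blind estimation.
#'
#' @param x Observed matrix (channels x samples).
#' @param a Mixing matrix with full column rank.
#' @return List with `s_est` (estimated centered sources), `w` (unmixing
#'   matrix) and the centering `mean`.
#' @export
semiblind_unmix <- function(x, a) {
  a <- as.matrix(a)
  if (qr(a)$rank < ncol(a)) {
    palmbp_stop("mixing matrix is rank deficient; cannot invert", "singular_matrix")
  }
  cen <- ica_center(x)
  w <- if (nrow(a) == ncol(a)) solve(a) else MASS::ginv(a)
  list(s_est = w %*% cen$xhat, w = w, mean = cen$mean)
}

#' Select the pulse component by physiologic band power
#'
#' Picks the component whose discrete Fourier spectrum concentrates the
#' largest fraction of power inside the physiologic heart-rate band
#' (default 0.7-3 Hz, i.e. 42-180 beats/min), then aligns its sign so that
#' the mean of its local maxima exceeds the mean of its local minima.
#'
#' @param y Components x samples matrix (e.g. `fastica(...)$y`), or a vector.
#' @param fps Sampling rate of the components, frames/s.
#' @param band Length-2 frequency band in Hz; its upper edge must respect
#'   the Nyquist limit `fps / 2`.
#' @return A [pulse_trace()] holding the selected, sign-aligned component.
#' @export
select_pulse_component <- function(y, fps, band = c(0.7, 3.0)) {
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  y <- as.matrix(y)
  if (nrow(y) < 1L) stop_invalid("need at least one component")
  if (band[2] >= fps / 2) {
    stop_invalid(sprintf("band upper edge %.2f Hz is not below the Nyquist frequency %.2f Hz",
                         band[2], fps / 2))
  }
  n <- ncol(y)
  freqs <- (0:(n - 1)) * fps / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  frac <- apply(y, 1, function(v) {
    pw <- Mod(stats::fft(v - mean(v)))^2
    tot <- sum(pw[-1])      # drop DC
    if (tot == 0) 0 else sum(pw[in_band]) / tot
  })
  best <- drop(y[which.max(frac), ])
  ext <- local_extrema(best)
  if (length(ext$peaks) && length(ext$valleys) &&
      mean(best[ext$peaks]) < mean(best[ext$valleys])) {
    best <- -best
  }
  pulse_trace(best, fps)
}
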