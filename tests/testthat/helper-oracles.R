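# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force local maxima count by 3-point comparison.
count_local_maxima <- function(v) {
  n <- length(v)
  sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n])
}

# Brute-force extrema with plateau compression, mirroring the documented
# rule but written independently (index scan, no rle()).
oracle_extrema <- function(v) {
  peaks <- integer(0); valleys <- integer(0)
  i <- 2L
  n <- length(v)
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L  # plateau [i, j]
    if (j < n) {
      if (v[i] > v[i - 1L] && v[i] > v[j + 1L]) peaks <- c(peaks, i)
      if (v[i] < v[i - 1L] && v[i] < v[j + 1L]) valleys <- c(valleys, i)
    }
    i <- j + 1L
  }
  list(peaks = peaks, valleys = valleys)
}

# Reference global-best PSO (independent of the package implementation).
reference_pso <- function(f, n_dim, n_particles, n_iter, bounds, w, c1, c2,
                          v_max, seed) {
  set.seed(seed)
  x <- matrix(runif(n_particles * n_dim, bounds[1], bounds[2]), n_particles)
  v <- matrix(0, n_particles, n_dim)
  fit <- apply(x, 1, f)
  pb <- x; pbf <- fit
  gi <- which.min(fit); gx <- x[gi, ]; gf <- fit[gi]
  for (it in seq_len(n_iter)) {
    for (i in seq_len(n_particles)) {
      r1 <- runif(n_dim); r2 <- runif(n_dim)
      v[i, ] <- w * v[i, ] + r1 * c1 * (pb[i, ] - x[i, ]) + r2 * c2 * (gx - x[i, ])
      v[i, ] <- pmin(pmax(v[i, ], -v_max), v_max)
      x[i, ] <- pmin(pmax(x[i, ] + v[i, ], bounds[1]), bounds[2])
      fi <- f(x[i, ])
      if (fi < pbf[i]) { pb[i, ] <- x[i, ]; pbf[i] <- fi }
      if (fi < gf) { gx <- x[i, ]; gf <- fi }
    }
  }
  list(x = gx, f = gf)
}

sphere <- function(x) sum(x^2)
rosenbrock <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2

# A small noiseless cohort whose device readings obey the formula exactly.
exact_cohort <- function(n, alpha_sbp = c(60, 40, 0.5),
                         alpha_dbp = c(30, 25, 0.3), seed = 1) {
  generate_cohort(n, alpha_sbp, alpha_dbp, bmi_range = c(18.5, 30),
                  feature_range = c(0.2, 0.8), noise_sd = 0, seed = seed)
}
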