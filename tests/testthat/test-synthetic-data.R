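test_that("simulate_pulse_wave matches the harmonic closed form", {
  # no harmonics: constant baseline
  p0 <- pulse_model_params(a0 = 1)
  tr <- simulate_pulse_wave(p0, fps = 20, duration = 2)
  expect_equal(tr$samples, rep(1, 40))

  # one harmonic, z = 0: a0 + cos(w t) exactly (attenuation e^0 = 1)
  p1 <- pulse_model_params(a0 = 2, harmonics = rbind(c(1, 0)), omega_h = 2 * pi)
  tr1 <- simulate_pulse_wave(p1, fps = 25, duration = 2)
  t <- (0:49) / 25
  expect_equal(tr1$samples, 2 + cos(2 * pi * t), tolerance = 1e-14)

  # 1.2 Hz fundamental over 10 s: brute-force count gives 12 maxima
  p2 <- pulse_model_params(a0 = 0, harmonics = rbind(c(0, 1)),
                           omega_h = 2 * pi * 1.2)
  tr2 <- simulate_pulse_wave(p2, fps = 20, duration = 10)
  expect_identical(count_local_maxima(tr2$samples), 12L)
})

test_that("attenuated multi-harmonic wave equals its k<=1 restriction at z=0", {
  harm <- rbind(c(0.8, 0.3))
  full <- simulate_pulse_wave(
    pulse_model_params(a0 = 1.5, harmonics = harm, omega_h = 2 * pi * 1.1,
                       z = 0, c_wave = 3),
    fps = 30, duration = 5)
  t <- (0:(length(full$samples) - 1)) / 30
  manual <- 1.5 + 0.8 * cos(2 * pi * 1.1 * t) + 0.3 * sin(2 * pi * 1.1 * t)
  expect_equal(full$samples, manual, tolerance = 1e-12)

  # with z > 0 the first harmonic is scaled by exp(-z/c)
  att <- simulate_pulse_wave(
    pulse_model_params(a0 = 1.5, harmonics = harm, omega_h = 2 * pi * 1.1,
                       z = 0.15, c_wave = 3),
    fps = 30, duration = 5)
  expect_equal(att$samples - 1.5, (full$samples - 1.5) * exp(-0.15 / 3),
               tolerance = 1e-12)
})

test_that("simulate_pulse_wave validates its arguments", {
  p <- pulse_model_params(a0 = 1)
  expect_error(simulate_pulse_wave(p, fps = 0, duration = 10), class = "palmbp_invalid_argument")
  expect_error(simulate_pulse_wave(p, fps = 20, duration = -1), class = "palmbp_invalid_argument")
  expect_error(simulate_pulse_wave(p, fps = 20, duration = 10, noise_sd = -1),
               class = "palmbp_invalid_argument")
  # noise is reproducible from the seed
  a <- simulate_pulse_wave(p, 20, 2, noise_sd = 1, seed = 7)
  b <- simulate_pulse_wave(p, 20, 2, noise_sd = 1, seed = 7)
  expect_identical(a$samples, b$samples)
})

test_that("mix_sources is the plain linear forward model", {
  s <- rbind(sin(seq(0, 4 * pi, length.out = 50)),
             rep(c(1, -1), each = 25))
  expect_equal(mix_sources(s, diag(2))$x, s)

  a <- matrix(c(1, 0.5, 0.5, 1), 2, byrow = TRUE)
  got <- mix_sources(s, a)$x
  expect_equal(got[1, ], s[1, ] + 0.5 * s[2, ], tolerance = 1e-14)
  expect_equal(got[2, ], 0.5 * s[1, ] + s[2, ], tolerance = 1e-14)

  expect_error(mix_sources(s, matrix(1, 2, 3)), class = "palmbp_dimension_error")
  rank2 <- cbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 2))  # third col = sum
  expect_error(mix_sources(matrix(rnorm(30), 3), rank2, require_full_rank = TRUE),
               class = "palmbp_singular_matrix")
})

test_that("generate_cohort obeys its generating model and seed contract", {
  alpha_s <- c(60, 40, 0.5); alpha_d <- c(30, 25, 0.3)
  co <- exact_cohort(50)
  expect_equal(co$sbp_device, predict_formula(co$e_peak, co$bmi, alpha_s))
  expect_equal(co$dbp_device, predict_formula(co$e_valley, co$bmi, alpha_d))
  expect_true(all(co$e_peak >= co$e_valley))

  # byte-identical serialization for equal seeds
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(20, alpha_s, alpha_d, seed = 9), f1)
  write_cohort(generate_cohort(20, alpha_s, alpha_d, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(read_cohort(f1), generate_cohort(20, alpha_s, alpha_d, seed = 9),
               tolerance = 1e-6)

  # device-noise SD: with n = 1000 and sd 2 the sample SD of the residual
  # lies inside the chi-square 99.9% bracket [1.8, 2.2]
  noisy <- generate_cohort(1000, alpha_s, alpha_d, bmi_range = c(18.5, 30),
                           feature_range = c(0.2, 0.8), noise_sd = 2, seed = 4)
  resid <- noisy$sbp_device - predict_formula(noisy$e_peak, noisy$bmi, alpha_s)
  expect_gt(sd(resid), 1.8)
  expect_lt(sd(resid), 2.2)

  expect_error(generate_cohort(10, alpha_s, alpha_d, bmi_range = c(25, 20)),
               class = "palmbp_invalid_argument")
})

test_that("rendered frames carry the trace in the palm and are static outside", {
  flat <- pulse_trace(rep(3, 5), fps = 20)
  fs <- render_synthetic_frames(flat, frame_size = c(32, 32), seed = 2)
  for (i in 2:5) expect_identical(fs$frames[[i]], fs$frames[[1]])

  p <- pulse_model_params(a0 = 0, harmonics = rbind(c(5, 0)), omega_h = 2 * pi * 1.2)
  tr <- simulate_pulse_wave(p, fps = 20, duration = 3)
  fs2 <- render_synthetic_frames(tr, frame_size = c(32, 32), seed = 2)
  # outside pixels never change across frames
  d <- dim(fs2$frames[[1]])
  mask <- palmbp:::polygon_pixel_mask(fs2$polygon, d[2], d[1])
  out1 <- fs2$frames[[1]][, , 2][!mask]
  out2 <- fs2$frames[[20]][, , 2][!mask]
  expect_identical(out1, out2)

  # round trip: channel means over the ROI recover the trace up to affine scale
  cm <- channel_means(fs2$frames, fs2$polygon, fs2$fps)
  expect_gte(cor(cm$rgb[, 2], tr$samples), 0.999)

  degen <- matrix(c(5, 5, 10, 10, 15, 15, 20, 20), ncol = 2, byrow = TRUE)
  expect_error(render_synthetic_frames(flat, c(32, 32), degen),
               class = "palmbp_degenerate_roi")
})
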