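test_that("BMI and both formula evaluators match hand computation", {
  expect_equal(compute_bmi(1.75, 70), 70 / 1.75^2)
  expect_equal(compute_bmi(2.0, 80), 20.0)
  expect_error(compute_bmi(0, 70), class = "palmbp_invalid_argument")

  expect_equal(predict_formula(100, 22, c(0, 1, 0)), 122)
  expect_equal(predict_formula(100, 0, c(50, 0.5, 0)), 100)
  expect_equal(predict_formula(3, 20, c(10, 2, 0.1)), 10 + 6 + 20 * 1.3)

  expect_equal(predict_regression(0, 80, c(0, 0, 1)), 80)
  expect_equal(predict_regression(25, 0, c(100, 1, 0)), 125)
  expect_equal(predict_regression(24, 50, c(60, 1.2, 0.3)), 103.8)

  # structural limit: alpha2 = 0 coincides with gamma = (alpha0, 1, alpha1)
  set.seed(8)
  x <- runif(50); bmi <- runif(50, 18, 30)
  expect_equal(predict_formula(x, bmi, c(12, 3, 0)),
               predict_regression(bmi, x, c(12, 1, 3)))
})

test_that("OLS calibration equals the normal equations and interpolates exact data", {
  set.seed(9)
  n <- 40
  co <- data.frame(bmi = runif(n, 18, 32), e_peak = runif(n, 0.2, 0.8))
  co$e_valley <- co$e_peak - 0.1
  co$sbp_device <- 100 + 0.5 * co$bmi + 10 * co$e_peak
  co$dbp_device <- 60 + 0.3 * co$bmi + 5 * co$e_valley
  fit <- fit_regression(co, "SBP")
  expect_equal(fit$gamma, c(100, 0.5, 10), tolerance = 1e-8)

  # noisy data: QR solution equals the explicit (X'X)^-1 X'y oracle and the
  # residuals are orthogonal to the design columns
  co2 <- co
  co2$sbp_device <- co2$sbp_device + rnorm(n, 0, 3)
  fit2 <- fit_regression(co2, "SBP")
  x <- cbind(1, co2$bmi, co2$e_peak)
  beta <- solve(t(x) %*% x, t(x) %*% co2$sbp_device)
  expect_equal(fit2$gamma, drop(beta), tolerance = 1e-8)
  resid <- co2$sbp_device - x %*% beta
  expect_lt(max(abs(t(x) %*% resid)), 1e-6)

  co3 <- co; co3$bmi <- 25
  expect_error(fit_regression(co3, "SBP"), class = "palmbp_singular_design")
})

test_that("NM-PSO calibration recovers generating parameters on clean cohorts", {
  co <- exact_cohort(40, seed = 2)
  one_iv <- data.frame(lo = 18.5, hi = 30)
  tab <- fit_nmpso(co, "SBP", one_iv)
  pred <- predict_formula(co$e_peak, co$bmi, c(tab$alpha0, tab$alpha1, tab$alpha2))
  expect_lte(rmse(co$sbp_device, pred), 0.5)
  # the optimizer at least matches the generator's (zero) training MSE
  expect_lte(tab$mse, mean((co$sbp_device - predict_formula(co$e_peak, co$bmi, c(60, 40, 0.5)))^2) + 1e-8)

  # constant feature: alpha1/alpha2 are not identifiable
  degen <- co; degen$e_peak <- 0.5
  expect_error(fit_nmpso(degen, "SBP", one_iv), class = "palmbp_degenerate_fit")

  # under-populated interval is named
  expect_error(fit_nmpso(co[1:2, ], "SBP", one_iv), class = "palmbp_insufficient_data")
})

test_that("held-out error on noisy cohorts sits at the device-noise floor", {
  rmses <- vapply(1:10, function(s) {
    co <- generate_cohort(200, c(60, 40, 0.5), c(30, 25, 0.3),
                          bmi_range = c(18.5, 30), feature_range = c(0.2, 0.8),
                          noise_sd = 2, seed = s)
    tab <- fit_nmpso(co[1:150, ], "SBP", data.frame(lo = 18.5, hi = 30),
                     nmpso_config(x_bounds = c(-120, 120), seed = s))
    hold <- co[151:200, ]
    rmse(hold$sbp_device,
         predict_formula(hold$e_peak, hold$bmi, c(tab$alpha0, tab$alpha1, tab$alpha2)))
  }, numeric(1))
  expect_true(all(rmses >= 1.5 & rmses <= 3.5))
})

test_that("BMI interval lookup uses half-open intervals with no extrapolation", {
  tab <- data.frame(lo = c(18.5, 24), hi = c(24, 27),
                    alpha0 = c(1, 2), alpha1 = c(0, 0), alpha2 = c(0, 0))
  expect_equal(bmi_interval_lookup(24, tab)$alpha0, 2)   # boundary goes up
  expect_equal(bmi_interval_lookup(18.5, tab)$alpha0, 1)
  expect_error(bmi_interval_lookup(17, tab), class = "palmbp_out_of_range")
  expect_error(bmi_interval_lookup(27, tab), class = "palmbp_out_of_range")

  # each in-range BMI matches exactly one interval (exhaustive scan oracle)
  full <- default_bmi_intervals()
  set.seed(10)
  for (b in runif(50, 10, 59.99)) {
    hits <- sum(b >= full$lo & b < full$hi)
    expect_identical(hits, 1L)
  }
})

test_that("parameter tables round-trip through their JSON form", {
  co <- exact_cohort(30, seed = 3)
  tab <- fit_nmpso(co, "SBP", data.frame(lo = 18.5, hi = 30))
  path <- tempfile(fileext = ".json")
  write_params(tab, path)
  back <- read_params(path)
  expect_equal(back$alpha0, tab$alpha0, tolerance = 1e-12)
  expect_identical(attr(back, "target"), "SBP")

  reg <- fit_regression(co, "DBP")
  write_params(reg, path)
  back2 <- read_params(path)
  expect_equal(back2$gamma, reg$gamma, tolerance = 1e-12)
})
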