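test_that("nm_step reproduces the hand-computed reflection on the sphere", {
  cfg <- nmpso_config(x_bounds = c(-5, 5))
  sx <- simplex_state(rbind(c(1, 0), c(0, 1), c(1, 1)), sphere)
  out <- nm_step(sx, sphere, cfg)
  # worst vertex (1,1) reflects through centroid (0.5, 0.5) to (0, 0), f = 0;
  # the expansion point (-0.5, -0.5) has f = 0.5 > 0, so (0, 0) is kept
  expect_equal(out$vertices[1, ], c(0, 0))
  expect_equal(out$fitness[1], 0)
  expect_false(any(apply(out$vertices, 1, function(v) all(v == c(1, 1)))))

  # all-equal simplex is a shrink fixed point
  same <- simplex_state(rbind(c(2, 2), c(2, 2), c(2, 2)), sphere)
  expect_equal(nm_step(same, sphere, cfg)$vertices, same$vertices)

  bad <- function(x) NaN
  expect_error(nm_step(sx, bad, cfg), class = "palmbp_objective_error")
})

test_that("nm_step never worsens the best vertex (100 random simplexes)", {
  cfg <- nmpso_config(x_bounds = c(-5, 5))
  set.seed(42)
  for (i in 1:100) {
    vtx <- matrix(rnorm(6, sd = 3), 3, 2)
    sx <- simplex_state(vtx, sphere)
    out <- nm_step(sx, sphere, cfg)
    expect_lte(out$fitness[1], sx$fitness[1])
  }
})

test_that("pso_step follows the velocity/position update with forced randoms", {
  cfg <- nmpso_config(w = 0.5, c1 = 1.5, c2 = 1.5, x_bounds = c(0, 120))
  particles <- list(x = matrix(2, 1, 1), v = matrix(0, 1, 1),
                    pbest = matrix(2, 1, 1), pbest_f = 4, f = 4)
  gbest <- list(x = 0, f = 0)
  out <- pso_step(particles, gbest, sphere, cfg,
                  rand_fn = function(n) rep(1, n))
  # v = 0.5*0 + 1*1.5*(2-2) + 1*1.5*(0-2) = -3; x = 2 - 3 = -1, clamped to 0
  expect_equal(out$particles$v[1, 1], -3)
  expect_equal(out$particles$x[1, 1], 0)

  # x = Pbest = Gbest with v = 0: stationary
  still <- list(x = matrix(1, 1, 1), v = matrix(0, 1, 1),
                pbest = matrix(1, 1, 1), pbest_f = 1, f = 1)
  out2 <- pso_step(still, list(x = 1, f = 1), sphere, cfg)
  expect_equal(out2$particles$x[1, 1], 1)
  expect_equal(out2$particles$v[1, 1], 0)

  # with all randoms forced to zero, motion is pure inertia
  mov <- list(x = matrix(10, 1, 1), v = matrix(4, 1, 1),
              pbest = matrix(0, 1, 1), pbest_f = 0, f = 100)
  out3 <- pso_step(mov, list(x = 0, f = 0), sphere, cfg,
                   rand_fn = function(n) rep(0, n))
  expect_equal(out3$particles$v[1, 1], 0.5 * 4)
  expect_equal(out3$particles$x[1, 1], 12)
})

test_that("the swarm holds 3N+1 particles and solves standard test functions", {
  r3 <- nmpso_minimize(sphere, 3, nmpso_config(x_bounds = c(-5, 5), n_iter = 5))
  expect_identical(r3$n_particles, 10L)

  rs <- nmpso_minimize(sphere, 2, nmpso_config(x_bounds = c(-5, 5), seed = 0))
  expect_lte(rs$f_best, 1e-6)

  best <- min(vapply(0:4, function(s) {
    nmpso_minimize(rosenbrock, 2,
                   nmpso_config(x_bounds = c(-5, 5), n_iter = 300, seed = s))$f_best
  }, numeric(1)))
  expect_lte(best, 1e-3)
})

test_that("best-so-far fitness is monotone and positions stay in bounds", {
  trap <- function(x) sum(x^2) + 3 * sum(sin(3 * x)^2)
  r <- nmpso_minimize(trap, 2, nmpso_config(x_bounds = c(-4, 4), seed = 5))
  expect_true(all(diff(r$history) <= 0))
  expect_true(all(r$x_best >= -4 & r$x_best <= 4))

  # determinism
  r2 <- nmpso_minimize(trap, 2, nmpso_config(x_bounds = c(-4, 4), seed = 5))
  expect_identical(r$x_best, r2$x_best)
  expect_identical(r$history, r2$history)
})

test_that("disabling a phase reduces the hybrid to plain PSO or Nelder-Mead", {
  cfg <- nmpso_config(x_bounds = c(-5, 5), n_iter = 200, seed = 1)
  pso_only <- nmpso_minimize(sphere, 2, cfg, nm_phase = FALSE)
  ref <- reference_pso(sphere, 2, 7, 200, c(-5, 5), w = 0.5, c1 = 1.5,
                       c2 = 1.5, v_max = 120, seed = 1)
  expect_lt(abs(pso_only$f_best - ref$f), 1e-6)

  nm_only <- nmpso_minimize(sphere, 2, nmpso_config(x_bounds = c(-5, 5),
                                                    n_iter = 500, seed = 1),
                            pso_phase = FALSE)
  ref_nm <- stats::optim(c(3, -2), sphere, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-14))
  expect_lt(abs(nm_only$f_best - ref_nm$value), 1e-6)
})

test_that("configuration invariants are enforced", {
  expect_error(nmpso_config(alpha = 0), class = "palmbp_configuration")
  expect_error(nmpso_config(gamma = 0.5), class = "palmbp_configuration")
  expect_error(nmpso_config(beta = 1.2), class = "palmbp_configuration")
  expect_error(nmpso_config(x_bounds = c(5, -5)), class = "palmbp_configuration")
  expect_error(nmpso_minimize(sphere, 0, nmpso_config()), class = "palmbp_configuration")
})
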