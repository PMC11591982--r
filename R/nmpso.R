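#' @title Hybrid Nelder-Mead particle swarm optimizer
#' @description Box-bounded minimizer combining one Nelder-Mead simplex
#'   iteration on the best N+1 particles with a global-best particle-swarm
#'   velocity update of the remaining 2N, per iteration. For an N-dimensional
#'   problem the swarm holds 3N+1 particles.
#' @name nmpso
NULL

#' NM-PSO configuration
#'
#' Defaults follow the standard parameterization of the hybrid: reflection
#' `alpha = 1`, expansion `gamma = 2`, contraction `beta = 0.5`, inertia
#' `w = 0.5`, acceleration `c1 = c2 = 1.5`, 100 iterations, and speed /
#' position bounds of magnitude 120.
#'
#' @param alpha Reflection coefficient (> 0).
#' @param gamma Expansion coefficient (> alpha).
#' @param beta Contraction coefficient in (0, 1).
#' @param w Inertia weight.
#' @param c1,c2 Cognitive / social acceleration weights.
#' @param n_particles Swarm size; `NULL` means `3 N + 1` for problem
#'   dimension N.
#' @param n_iter Iteration cap.
#' @param v_max Maximum velocity magnitude per dimension.
#' @param x_bounds Length-2 position box applied to every dimension. The
#'   nominal box is \[0, 120\]; calibration widens it to \[-120, 120\] so
#'   coefficients may go negative.
#' @param seed RNG seed; the optimizer is deterministic given it.
#' @return A list of class `nmpso_config`.
#' @export
nmpso_config <- function(alpha = 1, gamma = 2, beta = 0.5, w = 0.5,
                         c1 = 1.5, c2 = 1.5, n_particles = NULL,
                         n_iter = 100L, v_max = 120, x_bounds = c(0, 120),
                         seed = 0L) {
  if (!is_scalar_num(alpha) || alpha <= 0) palmbp_stop("`alpha` must be > 0", "configuration")
  if (!is_scalar_num(gamma) || gamma <= alpha) palmbp_stop("`gamma` must exceed `alpha`", "configuration")
  if (!is_scalar_num(beta) || beta <= 0 || beta >= 1) palmbp_stop("`beta` must be in (0, 1)", "configuration")
  if (x_bounds[1] >= x_bounds[2]) palmbp_stop("`x_bounds` must be an ordered interval", "configuration")
  if (!is_scalar_num(v_max) || v_max <= 0) palmbp_stop("`v_max` must be > 0", "configuration")
  structure(list(alpha = alpha, gamma = gamma, beta = beta, w = w,
                 c1 = c1, c2 = c2, n_particles = n_particles,
                 n_iter = as.integer(n_iter), v_max = v_max,
                 x_bounds = as.numeric(x_bounds), seed = seed),
            class = "nmpso_config")
}

eval_objective <- function(f, x) {
  val <- f(x)
  if (!is.numeric(val) || length(val) != 1L || is.na(val)) {
    palmbp_stop("objective returned a non-finite or non-scalar fitness", "objective_error")
  }
  val
}

#' Simplex state for the Nelder-Mead phase
#'
#' @param vertices (N+1) x N matrix of vertex positions.
#' @param f Objective function, evaluated at each vertex.
#' @return List of class `simplex_state` with `vertices` and `fitness`,
#'   sorted ascending by fitness (stable).
#' @export
simplex_state <- function(vertices, f) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != ncol(vertices) + 1L) {
    stop_invalid("a simplex over N dimensions needs N+1 vertices")
  }
  fit <- apply(vertices, 1, function(x) eval_objective(f, x))
  o <- order(fit)          # stable: ties keep row order
  structure(list(vertices = vertices[o, , drop = FALSE], fitness = fit[o]),
            class = "simplex_state")
}

#' One Nelder-Mead simplex iteration
#'
#' Using the best vertex `Pl`, second-best `Ps` and worst `Ph`: reflect the
#' worst through the centroid of the others; if the reflection beats the
#' best, try expansion and keep the better of the two; if it is no better
#' than the second-best, contract toward the worst and keep the contraction
#' only when it improves on the worst, otherwise shrink all non-best
#' vertices halfway toward the best; in the remaining case accept the
#' reflection. The returned simplex is re-sorted.
#'
#' @param simplex A [simplex_state()].
#' @param f Objective function.
#' @param config An [nmpso_config()] supplying alpha, gamma, beta.
#' @return The updated, sorted [simplex_state()].
#' @export
nm_step <- function(simplex, f, config = nmpso_config()) {
  stopifnot(inherits(simplex, "simplex_state"))
  vtx <- simplex$vertices
  fit <- simplex$fitness
  n <- nrow(vtx)
  ph <- vtx[n, ]                       # worst
  cen <- colMeans(vtx[-n, , drop = FALSE])
  xr <- cen + config$alpha * (cen - ph)
  fr <- eval_objective(f, xr)
  if (fr < fit[1]) {
    xe <- cen + config$gamma * (xr - cen)
    fe <- eval_objective(f, xe)
    if (fe < fr) { vtx[n, ] <- xe; fit[n] <- fe } else { vtx[n, ] <- xr; fit[n] <- fr }
  } else if (fr >= fit[2]) {
    xc <- cen + config$beta * (ph - cen)
    fc <- eval_objective(f, xc)
    if (fc < fit[n]) {
      vtx[n, ] <- xc; fit[n] <- fc
    } else {
      # shrink all non-best vertices halfway toward the best
      for (i in 2:n) {
        vtx[i, ] <- vtx[1, ] + 0.5 * (vtx[i, ] - vtx[1, ])
        fit[i] <- eval_objective(f, vtx[i, ])
      }
    }
  } else {
    vtx[n, ] <- xr; fit[n] <- fr
  }
  o <- order(fit)
  structure(list(vertices = vtx[o, , drop = FALSE], fitness = fit[o]),
            class = "simplex_state")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' One particle-swarm velocity/position update
#'
#' For each particle and dimension, with fresh uniform draws `rand1`,
#' `rand2`:
#' `v <- w v + rand1 c1 (Pbest - x) + rand2 c2 (Gbest - x)`, the velocity is
#' clamped to magnitude `v_max`, then `x <- x + v` clamped to the position
#' box. Personal and global bests are refreshed after evaluation.
#'
#' @param particles List with matrices `x`, `v`, `pbest` (n x N) and vector
#'   `pbest_f`.
#' @param gbest List with `x` (position) and `f` (fitness) of the swarm best.
#' @param f Objective function.
#' @param config An [nmpso_config()].
#' @param active Integer indices of the particles to move (default: all).
#' @param rand_fn Uniform generator called as `rand_fn(n)`; exposed so the
#'   update rule can be exercised with forced random numbers.
#' @return List with the updated `particles` and `gbest`.
#' @export
pso_step <- function(particles, gbest, f, config = nmpso_config(),
                     active = seq_len(nrow(particles$x)),
                     rand_fn = stats::runif) {
  x <- particles$x; v <- particles$v
  n_dim <- ncol(x)
  for (i in active) {
    r1 <- rand_fn(n_dim)
    r2 <- rand_fn(n_dim)
    vi <- config$w * v[i, ] +
      r1 * config$c1 * (particles$pbest[i, ] - x[i, ]) +
      r2 * config$c2 * (gbest$x - x[i, ])
    vi <- clamp(vi, -config$v_max, config$v_max)
    xi <- clamp(x[i, ] + vi, config$x_bounds[1], config$x_bounds[2])
    v[i, ] <- vi
    x[i, ] <- xi
    fi <- eval_objective(f, xi)
    if (fi < particles$pbest_f[i]) {
      particles$pbest[i, ] <- xi
      particles$pbest_f[i] <- fi
    }
    if (fi < gbest$f) gbest <- list(x = xi, f = fi)
    particles$f[i] <- fi
  }
  particles$x <- x
  particles$v <- v
  list(particles = particles, gbest = gbest)
}

#' Minimize an objective with the hybrid Nelder-Mead / particle swarm
#'
#' Initializes `3 N + 1` particles uniformly inside the position box. Each
#' iteration sorts the swarm by fitness, applies one Nelder-Mead step to the
#' simplex formed by the best `N + 1` particles (their velocities reset to
#' zero when moved), then applies the particle-swarm update to the poorer
#' `2 N` particles only, the best `N + 1` being retained unchanged. Stops
#' after `n_iter` iterations or as soon as the swarm's fitness spread falls
#' below `1e-10`.
#'
#' @param f Objective function taking a length-N numeric vector.
#' @param n_dim Problem dimension N (>= 1).
#' @param config An [nmpso_config()].
#' @param nm_phase,pso_phase Enable/disable the two phases. With the NM
#'   phase off the algorithm is plain global-best PSO; with the PSO phase
#'   off the whole swarm forms one (over-complete) simplex and the algorithm
#'   reduces to Nelder-Mead.
#' @return List with `x_best`, `f_best`, `history` (best-so-far fitness per
#'   iteration) and `iterations` run.
#' @export
nmpso_minimize <- function(f, n_dim, config = nmpso_config(),
                           nm_phase = TRUE, pso_phase = TRUE) {
  if (!is_scalar_num(n_dim) || n_dim < 1) palmbp_stop("`n_dim` must be >= 1", "configuration")
  if (!inherits(config, "nmpso_config")) palmbp_stop("`config` must be an nmpso_config", "configuration")
  n_dim <- as.integer(n_dim)
  n_part <- if (is.null(config$n_particles)) 3L * n_dim + 1L else as.integer(config$n_particles)
  if (n_part < n_dim + 1L) palmbp_stop("swarm smaller than a simplex", "configuration")
  lo <- config$x_bounds[1]; hi <- config$x_bounds[2]

  with_seed(config$seed, {
    x <- matrix(stats::runif(n_part * n_dim, lo, hi), n_part, n_dim)
    v <- matrix(0, n_part, n_dim)
    fit <- apply(x, 1, function(p) eval_objective(f, p))
    particles <- list(x = x, v = v, pbest = x, pbest_f = fit, f = fit)
    gi <- which.min(fit)
    gbest <- list(x = x[gi, ], f = fit[gi])
    history <- numeric(0)
    iter_done <- 0L

    for (iter in seq_len(config$n_iter)) {
      o <- order(particles$f)          # stable sort; ties by particle index
      particles$x <- particles$x[o, , drop = FALSE]
      particles$v <- particles$v[o, , drop = FALSE]
      particles$pbest <- particles$pbest[o, , drop = FALSE]
      particles$pbest_f <- particles$pbest_f[o]
      particles$f <- particles$f[o]

      if (nm_phase) {
        top <- if (pso_phase) seq_len(n_dim + 1L) else seq_len(n_part)
        sx <- particles$x[top, , drop = FALSE]
        sf <- particles$f[top]
        so <- order(sf)
        simplex <- structure(list(vertices = sx[so, , drop = FALSE],
                                  fitness = sf[so]),
                             class = "simplex_state")
        simplex <- nm_step(simplex, f, config)
        moved <- clamp(simplex$vertices, lo, hi)
        for (j in seq_along(top)) {
          i <- top[j]
          newx <- moved[j, ]
          newf <- if (all(newx == simplex$vertices[j, ])) simplex$fitness[j] else eval_objective(f, newx)
          if (any(newx != particles$x[i, ])) particles$v[i, ] <- 0
          particles$x[i, ] <- newx
          particles$f[i] <- newf
          if (newf < particles$pbest_f[i]) {
            particles$pbest[i, ] <- newx
            particles$pbest_f[i] <- newf
          }
          if (newf < gbest$f) gbest <- list(x = newx, f = newf)
        }
      }

      if (pso_phase) {
        worst <- if (n_part > n_dim + 1L && nm_phase) (n_dim + 2L):n_part else seq_len(n_part)
        upd <- pso_step(particles, gbest, f, config, active = worst)
        particles <- upd$particles
        gbest <- upd$gbest
      }

      history <- c(history, gbest$f)
      iter_done <- iter
      if (max(particles$f) - min(particles$f) < 1e-10) break
    }

    list(x_best = gbest$x, f_best = gbest$f, history = history,
         iterations = iter_done, n_particles = n_part)
  })
}
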