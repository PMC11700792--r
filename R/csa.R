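#' Box bounds for the swarm optimizer
#'
#' @param lower,upper numeric vectors of per-dimension bounds with
#'   `lower < upper` everywhere.
#' @return object of class `csa_bounds`.
#' @export
csa_bounds <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L) {
    stopf("lower and upper must be equal-length non-empty vectors")
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stopf("bounds must be finite with lower < upper in every dimension")
  }
  structure(list(lower = lower, upper = upper, d = length(lower)),
            class = "csa_bounds")
}

#' Chameleon swarm hyperparameters
#'
#' Movement constants of the three CSA stages. `Pp` is the per-element
#' probability of the exploratory (random-walk) branch of the prey-search
#' update; `p_scale` scales the two attraction coefficients (each drawn as
#' `p_scale * U(0,1)`); `gamma`, `alpha`, `beta` shape the exploration decay
#' `mu = gamma * exp(-(alpha * t / T)^beta)`; `omega_start`/`omega_end` give
#' the linearly decaying inertia of the tongue-attack (hunting) stage with
#' attraction coefficients `c1`, `c2` and acceleration constant `accel`;
#' `rot_angle` bounds the eye-rotation angle (radians).
#'
#' @param Pp,p_scale,gamma,alpha,beta,omega_start,omega_end,c1,c2,accel,rot_angle
#'   numeric constants, all overridable.
#' @return named list of class `csa_hyperparams`.
#' @export
csa_hyperparams <- function(Pp = 0.1, p_scale = 1.75, gamma = 2.0, alpha = 4.0,
                            beta = 3.0, omega_start = 0.9, omega_end = 0.4,
                            c1 = 1.75, c2 = 1.75, accel = 2590,
                            rot_angle = pi / 6) {
  structure(list(Pp = Pp, p_scale = p_scale, gamma = gamma, alpha = alpha,
                 beta = beta, omega_start = omega_start, omega_end = omega_end,
                 c1 = c1, c2 = c2, accel = accel, rot_angle = rot_angle),
            class = "csa_hyperparams")
}

clamp_box <- function(y, bounds) {
  pmin(pmax(y, matrix(bounds$lower, nrow(y), bounds$d, byrow = TRUE)),
       matrix(bounds$upper, nrow(y), bounds$d, byrow = TRUE))
}

## every stochastic stage draws from its own derived seed so composed calls
## are fully reproducible regardless of what the objective does to the RNG
csa_rng <- function(state, expr) {
  with_seed(derive_seed(state$seed, "csa-stage", state$rng_counter), expr)
}

#' Initialize a chameleon swarm
#'
#' Positions drawn uniformly inside the box, velocities zero, fitness unset
#' until the first [evaluate_swarm()].
#'
#' @param n population size (>= 2).
#' @param bounds a [csa_bounds()] box.
#' @param seed integer seed; all later stage randomness derives from it.
#' @param hyperparams a [csa_hyperparams()] set.
#' @return object of class `swarm_state`.
#' @export
init_swarm <- function(n, bounds, seed = 1, hyperparams = csa_hyperparams()) {
  if (n < 2L) stopf("population size n must be >= 2")
  stopifnot(inherits(bounds, "csa_bounds"))
  d <- bounds$d
  state <- structure(list(
    positions = NULL, velocities = matrix(0, n, d), fitness = rep(NA_real_, n),
    pbest_pos = NULL, pbest_fit = rep(Inf, n),
    gbest_pos = NULL, gbest_fit = Inf,
    t = 0L, T = 1L, n = as.integer(n), d = d, bounds = bounds,
    hyper = hyperparams, seed = as.integer(seed), rng_counter = 1L,
    n_evals = 0L, evaluated = FALSE), class = "swarm_state")
  state$positions <- csa_rng(state, {
    matrix(runif(n * d), n, d) *
      matrix(bounds$upper - bounds$lower, n, d, byrow = TRUE) +
      matrix(bounds$lower, n, d, byrow = TRUE)
  })
  state$pbest_pos <- state$positions
  state$rng_counter <- state$rng_counter + 1L
  state
}

#' Evaluate the swarm on an objective
#'
#' Sets each individual's fitness (lower is better), updates personal and
#' global bests (elitist: the global best never worsens) and the objective
#' call count. A non-finite objective value is treated as `+Inf` with a
#' warning.
#'
#' @param state a `swarm_state`.
#' @param objective function mapping a position vector to a scalar.
#' @return the updated `swarm_state`.
#' @export
evaluate_swarm <- function(state, objective) {
  stopifnot(inherits(state, "swarm_state"))
  for (i in seq_len(state$n)) {
    val <- objective(state$positions[i, ])
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      warning(sprintf("objective returned a non-finite value for individual %d; treated as +Inf", i),
              call. = FALSE)
      val <- Inf
    }
    state$fitness[i] <- val
    if (val < state$pbest_fit[i]) {
      state$pbest_fit[i] <- val
      state$pbest_pos[i, ] <- state$positions[i, ]
    }
  }
  b <- which.min(state$pbest_fit)
  if (state$pbest_fit[b] < state$gbest_fit) {
    state$gbest_fit <- state$pbest_fit[b]
    state$gbest_pos <- state$pbest_pos[b, ]
  }
  state$n_evals <- state$n_evals + state$n
  state$evaluated <- TRUE
  state
}

#' Prey-search (color-changing) position update
#'
#' Per element, with probability `1 - Pp` the position moves by a blend of
#' attractions toward the personal best `P` and global best `G`:
#' `y + p1 (P - G) r2 + p2 (G - y) r1`; otherwise it takes an exploratory
#' step `mu ((u - l) r3 + l) sgn(rand - 0.5)` whose magnitude
#' `mu = gamma exp(-(alpha t / T)^beta)` decays over iterations. Positions
#' are clamped to the box.
#'
#' @param state an evaluated `swarm_state`.
#' @return the updated `swarm_state`.
#' @export
position_update <- function(state) {
  stopifnot(inherits(state, "swarm_state"))
  if (!state$evaluated) stopf("swarm must be evaluated before a position update")
  h <- state$hyper
  n <- state$n; d <- state$d
  mu <- h$gamma * exp(-(h$alpha * state$t / state$T)^h$beta)
  G <- matrix(state$gbest_pos, n, d, byrow = TRUE)
  P <- state$pbest_pos
  y <- state$positions
  lo <- matrix(state$bounds$lower, n, d, byrow = TRUE)
  up <- matrix(state$bounds$upper, n, d, byrow = TRUE)
  state$positions <- csa_rng(state, {
    r1 <- matrix(runif(n * d), n, d); r2 <- matrix(runif(n * d), n, d)
    r3 <- matrix(runif(n * d), n, d)
    p1 <- h$p_scale * matrix(runif(n * d), n, d)
    p2 <- h$p_scale * matrix(runif(n * d), n, d)
    follow <- matrix(runif(n * d), n, d) >= h$Pp
    sgn <- sign(matrix(runif(n * d), n, d) - 0.5)
    explore <- y + mu * ((up - lo) * r3 + lo) * sgn
    exploit <- y + p1 * (P - G) * r2 + p2 * (G - y) * r1
    ifelse(follow, exploit, explore)
  })
  state$rng_counter <- state$rng_counter + 1L
  state$positions <- clamp_box(state$positions, state$bounds)
  state
}

#' Eye-rotation position update
#'
#' Rotates each position about the global best by a seeded random angle in
#' `[-rot_angle, rot_angle]` within a random coordinate plane (preserving
#' the distance to the global best before clamping). In one dimension,
#' where rotation is undefined, positions get seeded jitter of magnitude at
#' most 1 percent of the box width.
#'
#' @param state an evaluated `swarm_state`.
#' @return the updated `swarm_state`.
#' @export
eye_rotation_update <- function(state) {
  stopifnot(inherits(state, "swarm_state"))
  if (!state$evaluated) stopf("swarm must be evaluated before an eye-rotation update")
  n <- state$n; d <- state$d
  G <- state$gbest_pos
  state$positions <- csa_rng(state, {
    y <- state$positions
    if (d == 1L) {
      width <- state$bounds$upper - state$bounds$lower
      y + matrix(runif(n, -1, 1) * 0.01 * width, n, 1)
    } else {
      for (i in seq_len(n)) {
        pl <- sample.int(d, 2L)
        th <- runif(1, -state$hyper$rot_angle, state$hyper$rot_angle)
        v <- y[i, ] - G
        a <- v[pl[1]]; b <- v[pl[2]]
        v[pl[1]] <- a * cos(th) - b * sin(th)
        v[pl[2]] <- a * sin(th) + b * cos(th)
        y[i, ] <- G + v
      }
      y
    }
  })
  state$rng_counter <- state$rng_counter + 1L
  state$positions <- clamp_box(state$positions, state$bounds)
  state
}

#' Hunting (tongue-attack) velocity update
#'
#' `v <- omega v + c1 (G - y) r1 + c2 (P - y) r2` with inertia `omega`
#' decaying linearly from `omega_start` to `omega_end` over iterations,
#' followed by the position step `y <- y + (v^2 - v_prev^2) / (2 a)`
#' element-wise with fixed acceleration constant `a`, clamped to the box.
#'
#' @param state an evaluated `swarm_state`.
#' @return the updated `swarm_state`.
#' @export
hunting_update <- function(state) {
  stopifnot(inherits(state, "swarm_state"))
  if (!state$evaluated) stopf("swarm must be evaluated before a hunting update")
  h <- state$hyper
  n <- state$n; d <- state$d
  omega <- h$omega_start - (h$omega_start - h$omega_end) * state$t / state$T
  G <- matrix(state$gbest_pos, n, d, byrow = TRUE)
  v_prev <- state$velocities
  y <- state$positions
  state$velocities <- csa_rng(state, {
    r1 <- matrix(runif(n * d), n, d); r2 <- matrix(runif(n * d), n, d)
    omega * v_prev + h$c1 * (G - y) * r1 + h$c2 * (state$pbest_pos - y) * r2
  })
  state$rng_counter <- state$rng_counter + 1L
  state$positions <- clamp_box(y + (state$velocities^2 - v_prev^2) / (2 * h$accel),
                               state$bounds)
  state
}

#' Run the full chameleon swarm optimization loop
#'
#' init -> evaluate -> \[prey-search -> eye-rotation -> hunting ->
#' evaluate\] x T, returning the elitist global best and the per-iteration
#' best-fitness trace (length `T + 1`, non-increasing). Minimizes; negate
#' the objective to maximize.
#'
#' @param objective function position -> scalar (lower is better).
#' @param bounds a [csa_bounds()] box.
#' @param n population size (>= 2).
#' @param T iteration count (>= 1).
#' @param seed integer seed; the run is fully deterministic given it.
#' @param hyperparams a [csa_hyperparams()] set.
#' @return list with `best_position`, `best_fitness`, `trace`, `n_evals`.
#' @export
csa_optimize <- function(objective, bounds, n = 20, T = 100, seed = 1,
                         hyperparams = csa_hyperparams()) {
  if (T < 1L) stopf("iteration count T must be >= 1")
  state <- init_swarm(n, bounds, seed, hyperparams)
  state$T <- as.integer(T)
  state <- evaluate_swarm(state, objective)
  trace <- numeric(T + 1L)
  trace[1L] <- state$gbest_fit
  for (t in seq_len(T)) {
    state$t <- t
    state <- position_update(state)
    state <- eye_rotation_update(state)
    state <- hunting_update(state)
    state <- evaluate_swarm(state, objective)
    trace[t + 1L] <- state$gbest_fit
  }
  list(best_position = state$gbest_pos, best_fitness = state$gbest_fit,
       trace = trace, n_evals = state$n_evals)
}

#' Pure random search over a box (benchmark baseline)
#'
#' Uniform sampling with the same evaluation-count budget as a swarm run;
#' used to benchmark the swarm's convergence behaviour.
#'
#' @param objective function position -> scalar (lower is better).
#' @param bounds a [csa_bounds()] box.
#' @param budget number of objective evaluations.
#' @param seed integer seed.
#' @return list with `best_position`, `best_fitness`, `n_evals`.
#' @export
random_search <- function(objective, bounds, budget, seed = 1) {
  stopifnot(inherits(bounds, "csa_bounds"), budget >= 1)
  d <- bounds$d
  with_seed(seed, {
    best_f <- Inf; best_y <- NULL
    for (i in seq_len(budget)) {
      y <- bounds$lower + runif(d) * (bounds$upper - bounds$lower)
      f <- objective(y)
      if (is.finite(f) && f < best_f) { best_f <- f; best_y <- y }
    }
    list(best_position = best_y, best_fitness = best_f, n_evals = budget)
  })
}
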