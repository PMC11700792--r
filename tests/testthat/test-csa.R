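sphere <- function(y) sum(y^2)

test_that("swarm initialization is feasible and deterministic", {
  b <- csa_bounds(c(-1, -1), c(1, 1))
  s1 <- init_swarm(5, b, seed = 3)
  s2 <- init_swarm(5, b, seed = 3)
  expect_identical(s1$positions, s2$positions)
  expect_true(all(s1$positions >= -1 & s1$positions <= 1))
  expect_true(all(s1$velocities == 0))
  tiny <- init_swarm(4, csa_bounds(0, 1e-12), seed = 1)
  expect_true(all(tiny$positions >= 0 & tiny$positions <= 1e-12))
  expect_error(init_swarm(1, b), ">= 2")
  expect_error(csa_bounds(c(0, 2), c(1, 1)), "lower < upper")
})

test_that("evaluation updates personal and global bests with elitism", {
  b <- csa_bounds(c(-5, -5), c(5, 5))
  s <- init_swarm(4, b, seed = 1)
  s <- evaluate_swarm(s, function(y) 3)
  expect_equal(s$gbest_fit, 3)
  s$positions[2, ] <- c(0, 0)
  s <- evaluate_swarm(s, sphere)
  expect_equal(s$gbest_fit, 0)
  expect_equal(s$gbest_pos, c(0, 0))
  # a NaN objective poisons only its own individual
  s3 <- init_swarm(3, b, seed = 2)
  bad <- function(y) if (abs(y[1] - s3$positions[1, 1]) < 1e-12) NaN else sphere(y)
  expect_warning(s3 <- evaluate_swarm(s3, bad), "non-finite")
  expect_equal(s3$fitness[1], Inf)
  expect_true(all(is.finite(s3$fitness[2:3])))
})

test_that("prey-search update respects its fixed point and the box", {
  b <- csa_bounds(c(-2, -2), c(2, 2))
  s <- init_swarm(6, b, seed = 4, hyperparams = csa_hyperparams(gamma = 0))
  s <- evaluate_swarm(s, sphere)
  s$T <- 10L; s$t <- 1L
  # put everyone at the global best: with no exploration term nothing moves
  for (i in 1:6) { s$positions[i, ] <- s$gbest_pos; s$pbest_pos[i, ] <- s$gbest_pos }
  moved <- position_update(s)
  expect_equal(moved$positions, matrix(rep(s$gbest_pos, each = 6), 6, 2))
  # generic update stays in bounds and is reproducible
  s2 <- init_swarm(6, b, seed = 4)
  s2 <- evaluate_swarm(s2, sphere); s2$T <- 10L; s2$t <- 1L
  u1 <- position_update(s2)
  u2 <- position_update(s2)
  expect_identical(u1$positions, u2$positions)
  expect_true(all(u1$positions >= -2 & u1$positions <= 2))
  expect_error(position_update(init_swarm(3, b, seed = 1)), "evaluated")
})

test_that("eye rotation preserves distance to the global best before clamping", {
  b <- csa_bounds(c(-100, -100, -100), c(100, 100, 100))  # wide: no clamping
  s <- init_swarm(8, b, seed = 6)
  s <- evaluate_swarm(s, sphere)
  before <- sqrt(rowSums((s$positions - matrix(s$gbest_pos, 8, 3, byrow = TRUE))^2))
  rot <- eye_rotation_update(s)
  after <- sqrt(rowSums((rot$positions - matrix(rot$gbest_pos, 8, 3, byrow = TRUE))^2))
  expect_equal(after, before, tolerance = 1e-9)
  # zero angle is the identity rotation
  s0 <- init_swarm(4, csa_bounds(c(-1, -1), c(1, 1)), seed = 2,
                   hyperparams = csa_hyperparams(rot_angle = 0))
  s0 <- evaluate_swarm(s0, sphere)
  expect_equal(eye_rotation_update(s0)$positions, s0$positions, tolerance = 1e-12)
  # 1-D degenerates to bounded jitter
  s1 <- init_swarm(4, csa_bounds(0, 10), seed = 2)
  s1 <- evaluate_swarm(s1, function(y) y^2)
  j <- eye_rotation_update(s1)
  expect_true(all(abs(j$positions - s1$positions) <= 0.1 + 1e-12))
})

test_that("hunting update honors its algebraic fixed point and bounds", {
  b <- csa_bounds(c(-3, -3), c(3, 3))
  s <- init_swarm(4, b, seed = 8)
  s <- evaluate_swarm(s, sphere)
  s$T <- 10L; s$t <- 1L
  i <- which.min(s$pbest_fit)
  s$positions[i, ] <- s$gbest_pos; s$pbest_pos[i, ] <- s$gbest_pos
  s$velocities[i, ] <- 0
  h <- hunting_update(s)
  expect_equal(h$positions[i, ], s$gbest_pos, tolerance = 1e-12)
  expect_true(all(h$positions >= -3 & h$positions <= 3))
  # with omega = 0 and c2 = 0 the velocity points from y toward G
  s2 <- init_swarm(4, b, seed = 9,
                   hyperparams = csa_hyperparams(omega_start = 0, omega_end = 0, c2 = 0))
  s2 <- evaluate_swarm(s2, sphere); s2$T <- 10L; s2$t <- 1L
  h2 <- hunting_update(s2)
  gap <- matrix(s2$gbest_pos, 4, 2, byrow = TRUE) - s2$positions
  expect_true(all(h2$velocities * gap >= 0))          # same sign as (G - y)
  expect_true(all(abs(h2$velocities) <= s2$hyper$c1 * abs(gap) + 1e-12))
})

test_that("the optimizer trace is elitist and the loop converges on easy problems", {
  res <- csa_optimize(sphere, csa_bounds(c(-5, -5), c(5, 5)), n = 20, T = 100, seed = 1)
  expect_true(all(diff(res$trace) <= 0))
  expect_lt(res$best_fitness, 0.1)
  expect_equal(res$n_evals, 20 * 101)
  q1 <- csa_optimize(function(y) (y - 3)^2, csa_bounds(0, 10), n = 10, T = 100, seed = 2)
  expect_lt(abs(q1$best_position - 3), 0.1)
  # degenerate run returns an initial position
  flat <- csa_optimize(function(y) 7, csa_bounds(c(0, 0), c(1, 1)), n = 2, T = 1, seed = 3)
  expect_equal(flat$best_fitness, 7)
  expect_length(flat$best_position, 2)
  # full determinism of the loop
  res2 <- csa_optimize(sphere, csa_bounds(c(-5, -5), c(5, 5)), n = 20, T = 100, seed = 1)
  expect_identical(res$best_position, res2$best_position)
  expect_identical(res$trace, res2$trace)
})

test_that("random search is deterministic and feasible", {
  b <- csa_bounds(c(-5, -5), c(5, 5))
  r1 <- random_search(sphere, b, budget = 200, seed = 4)
  r2 <- random_search(sphere, b, budget = 200, seed = 4)
  expect_identical(r1$best_fitness, r2$best_fitness)
  expect_true(all(r1$best_position >= -5 & r1$best_position <= 5))
})
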