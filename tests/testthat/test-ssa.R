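sphere <- function(x) sum(x^2)

test_that("init_population respects bounds, seeds, and degenerate boxes", {
  cfg <- swarm_config(5, 2, 0, 1, 10, seed = 4)
  s1 <- init_population(cfg, sphere)
  expect_equal(dim(s1$positions), c(5, 2))
  expect_true(all(s1$positions >= 0 & s1$positions <= 1))
  s2 <- init_population(cfg, sphere)
  expect_identical(s1$positions, s2$positions)

  dg <- swarm_config(4, 3, 2, 2, 10, seed = 1)
  sd <- init_population(dg, sphere)
  expect_true(all(sd$positions == 2))
})

test_that("producer update branches match hand-computed values", {
  cfg <- swarm_config(10, 2, -5, 5, 100)
  pos <- matrix(c(1, 2), 1, 2)
  # safe branch, rank 1, alpha 0.5, iter_max 100: multiplier exp(-1/50)
  out <- producer_update_ssa(pos, cfg, R2 = 0.1, alpha = 0.5)
  expect_equal(out, pos * exp(-1 / 50))
  # multiplier never increases magnitude
  expect_true(all(abs(out) <= abs(pos)))
  # alarm branch with Q = 0: unchanged
  out2 <- producer_update_ssa(pos, cfg, R2 = 0.9, Q = 0)
  expect_equal(out2, pos)
  expect_error(producer_update_ssa(matrix(numeric(0), 0, 2), cfg),
               "empty producer set")
})

test_that("scrounger update matches the 1xd pseudo-inverse expansion", {
  cfg <- swarm_config(10, 2, -10, 10, 100)
  a_pos <- c(0, 0)
  worst <- c(5, 5)
  # rank i <= n/2, position - a_pos = (2, -4), A = (+1, -1)
  pos <- matrix(c(2, -4), 1, 2)
  out <- scrounger_update(pos, ranks = 2, a_pos, worst, cfg,
                          A = matrix(c(1, -1), 1, 2))
  # brute-force A+ = A^T (A A^T)^-1; step = |gap| . A+ . ones
  A <- matrix(c(1, -1), 1, 2)
  Aplus <- t(A) %*% solve(A %*% t(A))
  step_bf <- drop(abs(c(2, -4)) %*% Aplus) * c(1, 1)
  expect_equal(drop(out), a_pos + step_bf)
  # at a_pos exactly: unchanged
  out0 <- scrounger_update(matrix(a_pos, 1), 2, a_pos, worst, cfg,
                           A = matrix(c(1, 1), 1, 2))
  expect_equal(drop(out0), a_pos)
  # rank > n/2 at the worst position: new position = Q per coordinate
  outw <- scrounger_update(matrix(worst, 1), 8, a_pos, worst, cfg, Q = 0.37)
  expect_equal(drop(outw), rep(0.37, 2))
})

test_that("scout update branches match hand-computed values", {
  cfg <- swarm_config(10, 2, -10, 10, 100)
  best <- c(1, 1); worst <- c(4, 4)
  # worse than global best with beta = 0: jump exactly to best
  out <- scout_update(matrix(c(3, 3), 1), fitnesses = 5, best, 1,
                      worst, 9, cfg, beta = 0)
  expect_equal(drop(out), best)
  # equal to global best: K = 0.5, |gap| = 2, fitness difference -1
  out2 <- scout_update(matrix(c(2, 2), 1), fitnesses = 1, best, 1,
                       worst, 2, cfg, K = 0.5)
  expect_equal(drop(out2), c(2, 2) + 0.5 * (2 / (-1 + cfg$epsilon)))
  # at the worst position with equal fitness and |gap| = 0: unchanged
  out3 <- scout_update(matrix(worst, 1), fitnesses = 1, best, 1,
                       worst, 2, cfg, K = 0.9)
  expect_equal(drop(out3), worst)
})

test_that("optimize_ssa converges deeply on the sphere and keeps contracts", {
  f <- make_benchmark("F1")
  res <- optimize_ssa(function(x) evaluate(f, x),
                      swarm_config(30, 30, -100, 100, 500, seed = 3))
  # loose bound: far below anything reachable without multiplicative collapse
  expect_lt(res$best_fitness, 1e-10)
  expect_true(all(diff(res$convergence_curve) <= 0))
  expect_true(all(res$best_position >= -100 & res$best_position <= 100))
})

test_that("same seed gives bit-identical SSA runs", {
  cfg <- swarm_config(10, 5, -5, 5, 50, seed = 99)
  r1 <- optimize_ssa(sphere, cfg)
  r2 <- optimize_ssa(sphere, cfg)
  expect_identical(r1$best_position, r2$best_position)
  expect_identical(r1$convergence_curve, r2$convergence_curve)
})

test_that("non-finite objectives abort with a diagnostic", {
  bad <- function(x) if (sum(x^2) < 1e4) NaN else sum(x^2)
  expect_error(optimize_ssa(bad, swarm_config(5, 2, -1, 1, 10, seed = 1)),
               "non-finite")
})

test_that("convergence curves round-trip through the text writer", {
  res <- optimize_ssa(sphere, swarm_config(5, 2, -1, 1, 10, seed = 8))
  path <- tempfile(fileext = ".tsv")
  write_convergence(res, path)
  tab <- read.delim(path)
  expect_equal(tab$best_fitness, res$convergence_curve)
})
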