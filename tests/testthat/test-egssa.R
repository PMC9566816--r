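sphere <- function(x) sum(x^2)

test_that("hungry-feature producer update matches hand-computed values", {
  cfg <- egssa_config(10, 3, -5, 5, 100, o = 2)
  # zero gap -> zero vector
  expect_equal(phfs_update(c(1, 2, 3), c(1, 2, 3), cfg, u = c(0.5, 0.5, 0.5)),
               c(0, 0, 0))
  # gap = ln 2, u = 0.5, o = 2: (1 - 0.5) * 0.5 * 2 = 0.5
  expect_equal(phfs_update(c(0, 0, 0), rep(log(2), 3), cfg, u = rep(0.5, 3)),
               rep(0.5, 3))
  # saturation: huge gap keeps the result inside [0, o)
  out <- phfs_update(rep(-1e6, 3), rep(1e6, 3), cfg, u = rep(0.999, 3))
  expect_true(all(out >= 0 & out < 2))
})

test_that("balance-factor producer update matches hand-computed values", {
  cfg <- egssa_config(10, 2, -5, 5, 100, delta = 2)
  cur <- c(1, 1); best <- c(2, 2)
  # para = 0.5 -> bf = 0: pure normal step
  expect_equal(eeps_update(cur, best, 10, cfg, para = 0.5, Q = c(0.3, -0.2)),
               c(0.3, -0.2))
  # final iteration -> bf = 0 regardless of para
  expect_equal(eeps_update(cur, best, 100, cfg, para = 1, Q = c(0, 0)),
               c(0, 0))
  # iter 0, para = 1, delta = 2, best - cur = (1, 1), Q = 0 -> offset (2, 2)
  expect_equal(eeps_update(cur, best, 0, cfg, para = 1, Q = c(0, 0)),
               c(2, 2))
})

test_that("Cauchy perturbation of the incumbent is greedy", {
  # u = 0.5 -> r = 0: candidate equals the incumbent
  p <- pes_perturb(c(1, 1), 2, sphere, -5, 5, u = 0.5)
  expect_equal(p$position, c(1, 1))
  expect_equal(p$fitness, 2)
  # u = 0.75 -> r = tan(pi/4) = 1: candidate = 2 * best (worse on sphere)
  p2 <- pes_perturb(c(1, 1), 2, sphere, -5, 5, u = 0.75)
  expect_equal(p2$position, c(1, 1))  # rejected, incumbent kept
  # an improving candidate is accepted: start away from 0, u pulling toward it
  p3 <- pes_perturb(c(2, 2), 8, sphere, -5, 5, u = 0.25)  # r = -1: candidate 0
  expect_equal(p3$position, c(0, 0))
  expect_equal(p3$fitness, 0)
  # fitness never exceeds the input across random draws
  set.seed(21)
  for (i in 1:50) {
    q <- pes_perturb(c(0.5, -0.3), sphere(c(0.5, -0.3)), sphere, -5, 5)
    expect_lte(q$fitness, sphere(c(0.5, -0.3)))
  }
})

test_that("experimental variant flags change only what they claim", {
  cfg <- egssa_config(10, 2, -5, 5, 100, phfs_anchored = TRUE)
  # anchored variant: incumbent + term instead of the absolute term
  base <- egssa_config(10, 2, -5, 5, 100)
  u <- c(0.4, 0.6)
  cur <- c(0, 0); best <- c(1, 2)
  expect_equal(phfs_update(cur, best, cfg, u = u),
               best + phfs_update(cur, best, base, u = u))
  # per-coordinate Cauchy: distinct draws per coordinate still greedy
  set.seed(8)
  p <- pes_perturb(c(1, -1), 2, function(x) sum(x^2), -5, 5,
                   per_coordinate = TRUE)
  expect_lte(p$fitness, 2)
})

test_that("the zero incumbent is a fixed point of the perturbation", {
  p <- pes_perturb(c(0, 0), 0, sphere, -5, 5, u = 0.9)
  expect_identical(p$position, c(0, 0))
})

test_that("optimize_egssa keeps the optimizer contracts", {
  f <- make_benchmark("F9")
  cfg <- egssa_config(20, f$dim, f$lower_bound, f$upper_bound, 100, seed = 5)
  res <- optimize_egssa(function(x) evaluate(f, x), cfg)
  expect_true(all(diff(res$convergence_curve) <= 0))
  expect_lte(res$best_fitness, res$convergence_curve[1])
  expect_true(all(res$best_position >= f$lower_bound &
                    res$best_position <= f$upper_bound))
  res2 <- optimize_egssa(function(x) evaluate(f, x), cfg)
  expect_identical(res$best_position, res2$best_position)
})

test_that("collapse to exactly 0.0 on an origin-optimum function", {
  f <- make_benchmark("F11")
  cfg <- egssa_config(30, f$dim, f$lower_bound, f$upper_bound, 200, seed = 17)
  res <- optimize_egssa(function(x) evaluate(f, x), cfg)
  expect_identical(res$best_fitness, 0)
})

test_that("optimizer contract properties hold over randomized cases", {
  set.seed(1234)
  for (case in 1:20) {
    d <- sample(2:5, 1)
    n <- sample(5:12, 1)
    lb <- runif(1, -10, -1); ub <- runif(1, 1, 10)
    seed <- sample.int(10000, 1)
    cfg <- egssa_config(n, d, lb, ub, 20, seed = seed)
    obj <- function(x) sum((x - 0.5)^2) + 0.1 * sum(abs(x))
    res <- optimize_egssa(obj, cfg)
    expect_true(all(diff(res$convergence_curve) <= 0))
    expect_true(all(res$best_position >= lb - 1e-12 &
                      res$best_position <= ub + 1e-12))
  }
})

test_that("run manifests capture config and strategy parameters", {
  cfg <- egssa_config(5, 2, -1, 1, 10, seed = 2, o = 2, delta = 2)
  res <- optimize_egssa(sphere, cfg)
  path <- tempfile(fileext = ".json")
  write_run_manifest(res, path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$optimizer, "egssa")
  expect_equal(man$o, 2)
  expect_equal(man$best_fitness, res$best_fitness)
})
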