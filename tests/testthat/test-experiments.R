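test_that("signed-rank machinery reproduces the printed comparison rows", {
  # 16 non-tied pairs all favoring A, 7 ties
  r <- paired_signed_rank(rep(0, 23), c(rep(1, 16), rep(0, 7)))
  expect_equal(r$n_better, 16)
  expect_equal(r$n_equal, 7)
  expect_equal(r$n_worse, 0)
  expect_equal(r$w_plus, 136)
  expect_equal(r$w_minus, 0)
  expect_equal(r$z, 68 / sqrt(374), tolerance = 1e-12)
  expect_equal(signif(r$p_two_sided, 3), 0.000438)

  # 19 uniformly signed pairs, 4 ties
  r2 <- paired_signed_rank(rep(0, 23), c(rep(1, 19), rep(0, 4)))
  expect_equal(r2$w_plus, 190)
  expect_equal(signif(r2$p_two_sided, 3), 0.000132)

  # mixed signs: rank sums split, totals preserved
  r3 <- paired_signed_rank(c(0, 0, 0, 0), c(3, -1, 2, 4))
  m <- r3$n_better + r3$n_worse
  expect_equal(r3$w_plus + r3$w_minus, m * (m + 1) / 2)
  expect_error(paired_signed_rank(c(1, 2), c(1, 2)), "no non-tied")
})

test_that("signed rank agrees with an independent enumeration oracle", {
  # exhaustive check on small m against wilcox.test's exact statistic
  set.seed(77)
  for (i in 1:10) {
    d <- round(runif(8, -5, 5), 2)
    d <- d[abs(d) > 0.01]
    r <- paired_signed_rank(rep(0, length(d)), d)
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = FALSE))
    expect_equal(unname(r$w_plus), unname(wt$statistic))
  }
})

test_that("benchmark suite aggregates seeded runs per cell", {
  rep <- run_benchmark_suite(functions = c("F1", "F9"),
                             optimizers = c("egssa", "ssa"),
                             runs = 2, pop_size = 10, iter_max = 30,
                             base_seed = 5)
  expect_equal(nrow(rep$summary), 4)
  expect_true(all(rep$summary$std >= 0))
  expect_true(all(lengths(rep$raw) == 2))
  raw <- rep$raw[["F1.egssa"]]
  expect_equal(rep$summary$avg[rep$summary$func == "F1" &
                                 rep$summary$optimizer == "egssa"],
               mean(raw))
  # single-run cells report std 0
  rep1 <- run_benchmark_suite("F9", "ssa", runs = 1, pop_size = 8,
                              iter_max = 10, base_seed = 1)
  expect_equal(rep1$summary$std, 0)
  # same protocol, same numbers
  rep2 <- run_benchmark_suite(functions = c("F1", "F9"),
                              optimizers = c("egssa", "ssa"),
                              runs = 2, pop_size = 10, iter_max = 30,
                              base_seed = 5)
  expect_identical(rep$raw, rep2$raw)
})

test_that("optimizer registry accepts plug-ins and rejects unknowns", {
  expect_true(all(c("egssa", "ssa") %in% optimizer_names()))
  register_optimizer("random_search", function(objective, pop_size, dim,
                                               lower, upper, iter_max, seed) {
    set.seed(seed)
    X <- matrix(runif(pop_size * iter_max * dim, lower, upper), ncol = dim)
    fits <- apply(X, 1, objective)
    list(best_fitness = min(fits), best_position = X[which.min(fits), ])
  })
  rep <- run_benchmark_suite("F16", c("random_search"), runs = 2,
                             pop_size = 5, iter_max = 20, base_seed = 2)
  expect_true(is.finite(rep$summary$avg))
  expect_error(get_optimizer("nope"), "unknown optimizer")
})

test_that("disease pipeline produces a coherent per-fold report", {
  ds <- synth_generate(n_samples = 80, n_informative = 3, n_noise = 1,
                       class_separation = 5, missing_rate = 0.02, seed = 55)
  rep <- run_disease_pipeline(ds, folds = 5, tune = cheap_tune(), seed = 6)
  expect_length(rep$fold_metrics, 5)
  accs <- vapply(rep$fold_metrics, function(f) f$acc, numeric(1))
  expect_equal(unname(rep$aggregate$acc["mean"]), mean(accs))
  expect_gte(rep$aggregate$acc["mean"], 0.8)  # clearly separable
  # paper-mode normalization runs end to end too
  rep2 <- run_disease_pipeline(ds, folds = 5, tune = cheap_tune(), seed = 6,
                               paper_mode = TRUE)
  expect_length(rep2$fold_metrics, 5)
})

test_that("benchmark report writers round-trip", {
  rep <- run_benchmark_suite("F16", c("egssa"), runs = 2, pop_size = 6,
                             iter_max = 10, base_seed = 3)
  tsv <- tempfile(fileext = ".tsv")
  write_benchmark_report(rep, tsv)
  back <- read.delim(tsv)
  expect_equal(back$avg, rep$summary$avg)
})
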