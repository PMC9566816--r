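# Experiment orchestration: (1) the benchmark comparison -- mean/std of the
# best objective value over R independent seeded runs per (function,
# optimizer) cell, compared pairwise with a Wilcoxon signed-rank test; and
# (2) the disease-prediction pipeline -- outer k-fold cross-validation with
# hyperparameter tuning on each training partition.

# registry of optimizers conforming to the optimize contract:
# f(objective, pop_size, dim, lower, upper, iter_max, seed) -> swarm_result.
.optimizer_registry <- new.env(parent = emptyenv())

#' Register or look up an optimizer plug-in
#'
#' Optimizers conform to the contract
#' `fun(objective, pop_size, dim, lower, upper, iter_max, seed)` returning a
#' list with at least `best_fitness`.  `"ssa"` and `"egssa"` are
#' pre-registered; third-party optimizers (PSO, GWO, ...) can be plugged in
#' for comparison studies.
#'
#' @param name Optimizer name.
#' @param fun Optimizer function (omit to look up).
#' @return `register_optimizer` invisibly returns `fun`; `get_optimizer`
#'   returns the registered function; `optimizer_names` the names.
#' @export
register_optimizer <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .optimizer_registry)
  invisible(fun)
}

#' @rdname register_optimizer
#' @export
get_optimizer <- function(name) {
  if (!exists(name, envir = .optimizer_registry, inherits = FALSE)) {
    stop("unknown optimizer: ", name,
         " (registered: ", paste(optimizer_names(), collapse = ", "), ")")
  }
  get(name, envir = .optimizer_registry, inherits = FALSE)
}

#' @rdname register_optimizer
#' @export
optimizer_names <- function() sort(ls(.optimizer_registry))

.register_builtin_optimizers <- function() {
  register_optimizer("ssa", function(objective, pop_size, dim, lower, upper,
                                     iter_max, seed) {
    optimize_ssa(objective, swarm_config(pop_size, dim, lower, upper,
                                         iter_max, seed = seed))
  })
  register_optimizer("egssa", function(objective, pop_size, dim, lower, upper,
                                       iter_max, seed) {
    optimize_egssa(objective, egssa_config(pop_size, dim, lower, upper,
                                           iter_max, seed = seed))
  })
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_optimizers()
}

#' Run the benchmark comparison suite
#'
#' For every (function, optimizer) pair, executes `runs` independent runs
#' with seeds `base_seed + r` and records the best objective value of each
#' run plus the per-cell mean and standard deviation.
#'
#' @param functions Character vector of benchmark names (see
#'   [benchmark_names()]).
#' @param optimizers Character vector of registered optimizer names.
#' @param runs Independent runs per cell (default 30).
#' @param pop_size,iter_max Population size and iteration budget
#'   (defaults 30, 500).
#' @param base_seed Base RNG seed; run `r` uses `base_seed + r`.
#' @return A `benchmark_report`: `summary` data frame (function, optimizer,
#'   avg, std, failures), `raw` matrix of run-level values, and the config
#'   snapshot.
#' @export
run_benchmark_suite <- function(functions = benchmark_names(),
                                optimizers = c("egssa", "ssa"),
                                runs = 30, pop_size = 30, iter_max = 500,
                                base_seed = 1) {
  stopifnot(runs >= 1)
  rows <- list()
  raw <- list()
  for (fname in functions) {
    f <- make_benchmark(fname)
    for (oname in optimizers) {
      opt <- get_optimizer(oname)
      vals <- rep(NA_real_, runs)
      for (r in seq_len(runs)) {
        res <- tryCatch(
          opt(function(x) evaluate(f, x), pop_size, f$dim,
              f$lower_bound, f$upper_bound, iter_max,
              seed = base_seed + r),
          error = function(e) NULL)
        if (!is.null(res)) vals[r] <- res$best_fitness
      }
      ok <- !is.na(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        func = fname, optimizer = oname,
        avg = mean(vals[ok]),
        std = if (sum(ok) > 1) stats::sd(vals[ok]) else 0,
        failures = sum(!ok), stringsAsFactors = FALSE)
      raw[[paste(fname, oname, sep = ".")]] <- vals
    }
  }
  structure(list(summary = do.call(rbind, rows), raw = raw,
                 config = list(runs = runs, pop_size = pop_size,
                               iter_max = iter_max, base_seed = base_seed)),
            class = "benchmark_report")
}

#' Paired Wilcoxon signed-rank comparison of two optimizers
#'
#' Compares per-function mean best values of algorithm A against B on a
#' minimization suite.  Differences `d_f = means_b - means_a` (positive
#' means A better) below `zero_tol` in absolute value are treated as ties
#' and dropped; the remaining `|d|` are ranked ascending with mid-ranks,
#' `W+` is the rank sum of positive differences and `W-` of negative ones,
#' and the two-sided p-value uses the normal approximation
#' `z = (W+ - m(m+1)/4) / sqrt(m(m+1)(2m+1)/24)` without continuity or tie
#' correction.
#'
#' @param means_a,means_b Equal-length vectors of per-function means.
#' @param zero_tol Absolute difference below which a pair counts as equal
#'   (default 1e-12, so display rounding never decides counts).
#' @return A `signed_rank_result`: `n_better`, `n_equal`, `n_worse`,
#'   `w_plus`, `w_minus`, `z`, `p_two_sided`.
#' @export
paired_signed_rank <- function(means_a, means_b, zero_tol = 1e-12) {
  stopifnot(length(means_a) == length(means_b), length(means_a) >= 1)
  d <- means_b - means_a
  tie <- abs(d) <= zero_tol
  n_equal <- sum(tie)
  d <- d[!tie]
  m <- length(d)
  if (m == 0) stop("no non-tied pairs")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  mu <- m * (m + 1) / 4
  sigma <- sqrt(m * (m + 1) * (2 * m + 1) / 24)
  z <- (w_plus - mu) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(n_better = sum(d > 0), n_equal = n_equal,
                 n_worse = sum(d < 0),
                 w_plus = w_plus, w_minus = w_minus,
                 z = z, p_two_sided = p),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("better %d  equal %d  worse %d  W+ %g  W- %g  z %.4f  p %.6f\n",
              x$n_better, x$n_equal, x$n_worse, x$w_plus, x$w_minus,
              x$z, x$p_two_sided))
  invisible(x)
}

#' Per-function two-sample rank-sum comparison (secondary mode)
#'
#' For completeness next to [paired_signed_rank()]: a Wilcoxon rank-sum
#' (Mann-Whitney) test per function over the raw run-level values of two
#' optimizers.
#'
#' @param report A `benchmark_report` covering both optimizers.
#' @param pair Character vector of the two optimizer names `(A, B)`.
#' @return Data frame with one row per function: `func`, `statistic`,
#'   `p_value`.
#' @export
ranksum_by_function <- function(report, pair) {
  stopifnot(inherits(report, "benchmark_report"), length(pair) == 2)
  funcs <- unique(report$summary$func)
  do.call(rbind, lapply(funcs, function(fn) {
    a <- report$raw[[paste(fn, pair[1], sep = ".")]]
    b <- report$raw[[paste(fn, pair[2], sep = ".")]]
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(func = fn, statistic = unname(wt$statistic),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  }))
}

#' Compare two optimizers within a benchmark report
#'
#' @param report A `benchmark_report`.
#' @param pair Character vector `(A, B)`; positive differences mean A
#'   better on minimization.
#' @return A `signed_rank_result` (see [paired_signed_rank()]).
#' @export
compare_optimizers <- function(report, pair = c("egssa", "ssa")) {
  s <- report$summary
  a <- s$avg[s$optimizer == pair[1]]
  b <- s$avg[s$optimizer == pair[2]]
  fa <- s$func[s$optimizer == pair[1]]
  fb <- s$func[s$optimizer == pair[2]]
  stopifnot(identical(fa, fb))
  paired_signed_rank(a, b)
}

#' Outer cross-validated disease-prediction pipeline
#'
#' For each outer fold: preprocess, tune `(k, c)` on the training partition
#' with [psas_tune()], train a KELM with the tuned values, and evaluate the
#' held-out fold with all four metrics.  The default protocol is
#' leakage-free: the min-max scaler is fitted on each outer training
#' partition and applied to its test fold.  `paper_mode = TRUE` instead
#' normalizes the full dataset once before splitting (the customary but
#' leakage-prone variant).
#'
#' @param ds A `disease_dataset` (missing rows are dropped internally).
#' @param folds Outer fold count (default 10).
#' @param tune A `tune_config` for the inner search (its `seed` is combined
#'   with the fold index so folds get independent streams).
#' @param seed Base seed for the outer fold partition and per-fold tuning.
#' @param paper_mode Normalize the whole dataset before splitting.
#' @return A `prediction_report`: per-fold `metric_set`s, per-fold tuned
#'   `(k, c)`, per-fold held-out predictions, aggregate mean/std per metric.
#' @export
run_disease_pipeline <- function(ds, folds = 10, tune = tune_config(),
                                 seed = 1, paper_mode = FALSE) {
  stopifnot(inherits(ds, "disease_dataset"))
  ds <- drop_missing(ds)
  if (paper_mode) ds <- normalize_minmax(ds)
  n <- nrow(ds$features)
  outer <- kfold_indices(n, folds, seed = seed)
  fold_metrics <- vector("list", length(outer))
  fold_params <- vector("list", length(outer))
  fold_predictions <- vector("list", length(outer))
  for (i in seq_along(outer)) {
    test_idx <- outer[[i]]
    train_idx <- setdiff(seq_len(n), test_idx)
    tr <- dataset(ds$features[train_idx, , drop = FALSE], ds$labels[train_idx],
                  provenance = ds$provenance)
    te_X <- ds$features[test_idx, , drop = FALSE]
    if (!paper_mode) {
      tr <- normalize_minmax(tr)
      sc <- attr(tr, "scaler")
      rng <- sc$max - sc$min
      te_X <- sweep(te_X, 2, sc$min)
      for (j in seq_len(ncol(te_X))) {
        te_X[, j] <- if (rng[j] == 0) 0 else 2 * te_X[, j] / rng[j] - 1
      }
    }
    tc <- tune
    tc$seed <- derive_seed(seed, i)
    tc$shuffle_seed <- derive_seed(seed, 1000 + i)
    fit <- tryCatch({
      tuned <- psas_tune(tr, tc)
      model <- kelm_train(tr$features, tr$labels, tuned$c_opt, tuned$k_opt)
      pred <- kelm_predict(model, te_X)
      list(metrics = compute_metrics(confusion(ds$labels[test_idx], pred$labels)),
           params = c(k = tuned$k_opt, c = tuned$c_opt),
           predictions = data.frame(index = test_idx,
                                    truth = ds$labels[test_idx],
                                    pred = pred$labels))
    }, error = function(e) {
      warning("fold ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) {
      fold_metrics[[i]] <- fit$metrics
      fold_params[[i]] <- fit$params
      fold_predictions[[i]] <- fit$predictions
    }
  }
  done <- !vapply(fold_metrics, is.null, logical(1))
  if (!all(done)) warning(sum(!done), " fold(s) failed; aggregating the rest")
  agg <- lapply(c("acc", "sensitivity", "specificity", "mcc"), function(m) {
    vals <- vapply(fold_metrics[done], function(f) f[[m]], numeric(1))
    c(mean = mean(vals), std = if (length(vals) > 1) stats::sd(vals) else 0)
  })
  names(agg) <- c("acc", "sensitivity", "specificity", "mcc")
  structure(list(fold_metrics = fold_metrics[done],
                 fold_params = fold_params[done],
                 fold_predictions = fold_predictions[done],
                 aggregate = agg, folds = folds, seed = seed,
                 paper_mode = paper_mode),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report: %d folds%s>\n", length(x$fold_metrics),
              if (x$paper_mode) ", paper-mode normalization" else ""))
  for (m in names(x$aggregate)) {
    cat(sprintf("  %-12s mean %.5f  std %.5f\n", m,
                x$aggregate[[m]]["mean"], x$aggregate[[m]]["std"]))
  }
  invisible(x)
}

#' Write a Table-4-shaped benchmark summary as delimited text
#'
#' @param report A `benchmark_report`.
#' @param path Output file.
#' @return The summary data frame, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  utils::write.table(report$summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(report$summary)
}
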