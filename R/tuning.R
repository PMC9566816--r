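# Self-adaptive KELM hyperparameter search: the enhanced sparrow optimizer
# searches (log2 k, log2 c) over a box, with 10-fold cross-validated error
# (1 - mean accuracy) as fitness.  The fold partition is fixed for the whole
# tuning run so candidate fitnesses are comparable, and the pairwise squared
# distance matrix of the training inputs is precomputed once: a candidate's
# kernel matrix is exp(-D / (2 k^2)), so only the exponential is re-done per
# candidate.

#' Tuning configuration
#'
#' Defaults follow the customary protocol for this tuner: a 2-dimensional
#' log2 search box `k, c in [2^-10, 2^10]`, 10 folds, population 10 and 50
#' iterations.
#'
#' @param k_bounds,c_bounds Positive bounds for the kernel width and the
#'   regularization coefficient (searched in log2 space).
#' @param folds Number of cross-validation folds.
#' @param pop_size,iter_max Optimizer population and iteration budget.
#' @param seed Integer seed driving the optimizer stream.
#' @param shuffle_seed Seed of the fold partition (defaults to `seed`).
#' @param ... Further arguments passed to [egssa_config()].
#' @return A `tune_config`.
#' @export
tune_config <- function(k_bounds = c(2^-10, 2^10), c_bounds = c(2^-10, 2^10),
                        folds = 10, pop_size = 10, iter_max = 50,
                        seed = NULL, shuffle_seed = NULL, ...) {
  stopifnot(all(k_bounds > 0), all(c_bounds > 0), folds >= 2)
  structure(list(k_bounds = k_bounds, c_bounds = c_bounds,
                 folds = as.integer(folds),
                 pop_size = as.integer(pop_size),
                 iter_max = as.integer(iter_max),
                 seed = seed, shuffle_seed = shuffle_seed %||% seed,
                 extra = list(...)),
            class = "tune_config")
}

# internal: CV error with a precomputed squared-distance matrix
cv_error_precomputed <- function(log2_k, log2_c, D2, labels, fold_list) {
  k <- 2^log2_k
  c <- 2^log2_c
  K <- exp(-D2 / (2 * k^2))
  accs <- vapply(fold_list, function(test_idx) {
    train_idx <- setdiff(seq_along(labels), test_idx)
    Ktr <- K[train_idx, train_idx, drop = FALSE]
    A <- Ktr + diag(1 / c, length(train_idx))
    L <- labels[train_idx]
    w <- tryCatch({
      R <- chol(A)
      drop(backsolve(R, backsolve(R, L, transpose = TRUE)))
    }, error = function(e) drop(qr.coef(qr(A, LAPACK = TRUE), L)))
    if (any(!is.finite(w))) return(NA_real_)
    scores <- drop(K[test_idx, train_idx, drop = FALSE] %*% w)
    pred <- ifelse(scores >= 0, 1, -1)
    mean(pred == labels[test_idx])
  }, numeric(1))
  if (anyNA(accs)) return(1)  # numerical failure: worst possible fitness
  1 - mean(accs)
}

#' Cross-validated KELM error for one hyperparameter candidate
#'
#' Fitness used by the tuner: `1 - mean accuracy` over a fixed k-fold
#' partition, training a fresh KELM with `(k, c) = (2^log2_k, 2^log2_c)` on
#' each fold complement.
#'
#' @param theta Length-2 numeric `(log2_k, log2_c)`.
#' @param ds A preprocessed `disease_dataset` (no missing values).
#' @param folds Number of folds.
#' @param shuffle_seed Seed of the fold partition.
#' @return Scalar in `[0, 1]` (lower is better).
#' @export
cv_fitness <- function(theta, ds, folds = 10, shuffle_seed = NULL) {
  stopifnot(inherits(ds, "disease_dataset"), length(theta) == 2)
  if (anyNA(ds$features)) stop("dataset contains missing values; run drop_missing() first")
  fold_list <- kfold_indices(nrow(ds$features), folds, seed = shuffle_seed)
  D2 <- sqdist(ds$features, ds$features)
  cv_error_precomputed(theta[1], theta[2], D2, ds$labels, fold_list)
}

#' Tune KELM hyperparameters with the enhanced sparrow optimizer
#'
#' Runs [optimize_egssa()] over the 2-dimensional `(log2 k, log2 c)` box
#' with [cv_fitness()] as the objective and returns the incumbent
#' transformed back to `(k_opt, c_opt)`.
#'
#' @param ds A preprocessed `disease_dataset`.
#' @param config A `tune_config`.
#' @return A `tune_result`: `k_opt`, `c_opt`, `cv_accuracy` (best CV accuracy
#'   found), `cv_fitness_history` (best-so-far error per iteration),
#'   `fold_assignments`.
#' @export
psas_tune <- function(ds, config = tune_config()) {
  stopifnot(inherits(ds, "disease_dataset"), inherits(config, "tune_config"))
  if (anyNA(ds$features)) stop("dataset contains missing values; run drop_missing() first")
  n <- nrow(ds$features)
  folds <- min(config$folds, n)
  fold_list <- kfold_indices(n, folds, seed = config$shuffle_seed)
  D2 <- sqdist(ds$features, ds$features)
  objective <- function(theta) {
    cv_error_precomputed(theta[1], theta[2], D2, ds$labels, fold_list)
  }
  opt_cfg <- do.call(egssa_config, c(
    list(pop_size = config$pop_size, dim = 2,
         lower = c(log2(config$k_bounds[1]), log2(config$c_bounds[1])),
         upper = c(log2(config$k_bounds[2]), log2(config$c_bounds[2])),
         iter_max = config$iter_max, seed = config$seed),
    config$extra))
  res <- optimize_egssa(objective, opt_cfg)
  structure(list(k_opt = 2^res$best_position[1],
                 c_opt = 2^res$best_position[2],
                 cv_accuracy = 1 - res$best_fitness,
                 cv_fitness_history = res$convergence_curve,
                 fold_assignments = fold_list,
                 seed = config$seed),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result: k = %.5g, c = %.5g, CV accuracy %.4f>\n",
              x$k_opt, x$c_opt, x$cv_accuracy))
  invisible(x)
}

#' Dense log2-grid oracle for the tuner
#'
#' Exhaustively evaluates [cv_fitness()] on an `m x m` log2 grid over the
#' same box the tuner searches; used as the brute-force near-optimality
#' reference.
#'
#' @param ds A preprocessed `disease_dataset`.
#' @param config A `tune_config` (bounds, folds, `shuffle_seed`).
#' @param m Grid resolution per axis.
#' @return List with `best_theta` (log2 scale), `best_accuracy`, and the
#'   full `grid` data frame.
#' @export
grid_tune <- function(ds, config = tune_config(), m = 20) {
  lk <- seq(log2(config$k_bounds[1]), log2(config$k_bounds[2]), length.out = m)
  lc <- seq(log2(config$c_bounds[1]), log2(config$c_bounds[2]), length.out = m)
  n <- nrow(ds$features)
  folds <- min(config$folds, n)
  fold_list <- kfold_indices(n, folds, seed = config$shuffle_seed)
  D2 <- sqdist(ds$features, ds$features)
  grid <- expand.grid(log2_k = lk, log2_c = lc)
  grid$error <- mapply(function(a, b) {
    cv_error_precomputed(a, b, D2, ds$labels, fold_list)
  }, grid$log2_k, grid$log2_c)
  best <- which.min(grid$error)
  list(best_theta = c(grid$log2_k[best], grid$log2_c[best]),
       best_accuracy = 1 - grid$error[best],
       grid = grid)
}

#' Write a tuning manifest as JSON
#'
#' @param result A `tune_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tune_manifest <- function(result, path) {
  jsonlite::write_json(
    list(k_opt = result$k_opt, c_opt = result$c_opt,
         cv_accuracy = result$cv_accuracy,
         history = result$cv_fitness_history,
         seed = result$seed,
         fold_assignments = result$fold_assignments),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
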