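# Baseline sparrow search algorithm (SSA).  Three population roles per
# iteration: producers (the fittest PD fraction) lead the search, scroungers
# follow, and a random SD fraction of scouts reacts to danger near the
# incumbent.  The enhanced optimizer reuses the scrounger/scout machinery and
# swaps the producer update (see optimize_egssa).
#
# RNG draw order is fixed per iteration: the alarm value R2, then per-producer
# draws in rank order, then per-scrounger draws in rank order, then scout
# selection, then per-scout draws.  Identical config and seed therefore give
# bit-identical runs.

#' Swarm configuration
#'
#' @param pop_size Population size n (>= 2).
#' @param dim Search-space dimension.
#' @param lower,upper Box bounds (scalar or length-`dim`).
#' @param iter_max Iteration budget.
#' @param ST Warning threshold in (0.5, 1); alarm value below `ST` selects the
#'   producers' safe branch.
#' @param PD Producer fraction (default 20%).
#' @param SD Scout (detection) fraction (default 10%).
#' @param epsilon Small constant guarding the scout-update denominator.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(pop_size, dim, lower, upper, iter_max,
                         ST = 0.8, PD = 0.2, SD = 0.1,
                         epsilon = 1e-50, seed = NULL) {
  stopifnot(pop_size >= 2, dim >= 1, iter_max >= 1,
            PD > 0, PD <= 1, SD > 0, SD <= 1,
            ST > 0.5, ST < 1, epsilon > 0)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  structure(list(pop_size = as.integer(pop_size), dim = as.integer(dim),
                 lower = lower, upper = upper,
                 iter_max = as.integer(iter_max), ST = ST, PD = PD, SD = SD,
                 epsilon = epsilon, seed = seed),
            class = "swarm_config")
}

# evaluate an objective over the rows of a position matrix
eval_rows <- function(objective, X) {
  vapply(seq_len(nrow(X)), function(i) objective(X[i, ]), numeric(1))
}

#' Initialize a swarm
#'
#' Positions are drawn coordinate-wise uniform on the box; fitnesses are
#' evaluated and the incumbent best/worst recorded.
#'
#' @param config A `swarm_config`.
#' @param objective Objective function over the box (minimized).
#' @return A `swarm_state` list (positions, fitnesses, incumbent, curve).
#' @export
init_population <- function(config, objective) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$pop_size; d <- config$dim
  positions <- matrix(stats::runif(n * d), n, d)
  positions <- sweep(positions, 2, config$upper - config$lower, "*")
  positions <- sweep(positions, 2, config$lower, "+")
  fit <- eval_rows(objective, positions)
  if (any(!is.finite(fit))) stop("objective returned non-finite value at initialization")
  b <- which.min(fit); w <- which.max(fit)
  structure(list(positions = positions, fitnesses = fit,
                 best_position = positions[b, ], best_fitness = fit[b],
                 worst_position = positions[w, ], worst_fitness = fit[w],
                 iteration = 0L, convergence_curve = numeric(0)),
            class = "swarm_state")
}

# ---- role updates ----------------------------------------------------------
# Each helper optionally takes explicit random draws so the branch arithmetic
# is unit-testable; the optimizers leave them NULL and draw from the stream.

#' Baseline SSA producer update
#'
#' With one shared alarm value `R2 ~ U(0,1)` per iteration: if `R2 < ST` the
#' rank-i producer contracts multiplicatively by `exp(-i / (alpha * iter_max))`
#' with `alpha ~ U(0,1]` per producer; otherwise it takes a normal step
#' `Q` broadcast over coordinates.
#'
#' @param positions Matrix of producer rows, in rank order (fittest first).
#' @param config A `swarm_config`.
#' @param R2,alpha,Q Optional explicit draws (testing); drawn internally when
#'   `NULL`.
#' @return Updated producer position matrix (not yet clipped).
#' @export
producer_update_ssa <- function(positions, config, R2 = NULL, alpha = NULL,
                                Q = NULL) {
  np <- nrow(positions)
  if (is.null(np) || np == 0L) stop("empty producer set")
  if (is.null(R2)) R2 <- stats::runif(1)
  if (R2 < config$ST) {
    if (is.null(alpha)) alpha <- 1 - stats::runif(np)  # U(0,1]
    mult <- exp(-(seq_len(np)) / (alpha * config$iter_max))
    positions * mult
  } else {
    if (is.null(Q)) Q <- stats::rnorm(np)
    positions + Q
  }
}

#' Scrounger update (Eq. 5 of the original SSA)
#'
#' Scroungers of whole-population rank `i > n/2` scatter around the current
#' worst; the rest follow the best producer position `a_pos` with a step
#' `|gap| . A^+ . L` where `A` is a random +/-1 row and `A^+ = A^T (A A^T)^-1`,
#' which reduces to adding `sum(|gap| * A) / d` to every coordinate.
#'
#' @param positions Scrounger rows in rank order.
#' @param ranks Whole-population 1-based ranks of those rows.
#' @param a_pos Best producer position after the producer update.
#' @param worst_pos Current-iteration worst position.
#' @param config A `swarm_config`.
#' @param Q Optional normal draws, one per scrounger.
#' @param A Optional matrix of +/-1 draws (`length(ranks) x dim`).
#' @return Updated scrounger matrix (not yet clipped).
#' @export
scrounger_update <- function(positions, ranks, a_pos, worst_pos, config,
                             Q = NULL, A = NULL) {
  ns <- nrow(positions)
  if (is.null(ns) || ns == 0L) return(positions)
  n <- config$pop_size; d <- config$dim
  if (is.null(Q)) Q <- stats::rnorm(ns)
  if (is.null(A)) {
    A <- matrix(sample(c(-1, 1), ns * d, replace = TRUE), ns, d)
  }
  out <- positions
  for (j in seq_len(ns)) {
    i <- ranks[j]
    if (i > n / 2) {
      out[j, ] <- Q[j] * exp((worst_pos - positions[j, ]) / i^2)
    } else {
      gap <- abs(positions[j, ] - a_pos)
      step <- sum(gap * A[j, ]) / d  # |gap| . A^T (A A^T)^-1 . L
      out[j, ] <- a_pos + step
    }
  }
  out
}

#' Scout (detection) update (Eq. 6 of the original SSA)
#'
#' Scouts worse than the global best jump toward it with a normal factor on
#' the absolute gap; scouts exactly at the best fitness drift relative to the
#' current worst, with `epsilon` guarding the fitness-difference denominator.
#'
#' @param positions Scout rows.
#' @param fitnesses Their current fitnesses.
#' @param best_pos,best_fit Incumbent position and fitness.
#' @param worst_pos,worst_fit Current-iteration worst position and fitness.
#' @param config A `swarm_config`.
#' @param beta,K Optional explicit draws, one per scout (`beta` standard
#'   normal, `K` uniform on (-1, 1)).
#' @return Updated scout matrix (not yet clipped).
#' @export
scout_update <- function(positions, fitnesses, best_pos, best_fit,
                         worst_pos, worst_fit, config,
                         beta = NULL, K = NULL) {
  nsc <- nrow(positions)
  if (is.null(nsc) || nsc == 0L) return(positions)
  if (is.null(beta)) beta <- stats::rnorm(nsc)
  if (is.null(K)) K <- stats::runif(nsc, -1, 1)
  out <- positions
  for (j in seq_len(nsc)) {
    if (fitnesses[j] > best_fit) {
      out[j, ] <- best_pos + beta[j] * abs(positions[j, ] - best_pos)
    } else if (fitnesses[j] == best_fit) {
      out[j, ] <- positions[j, ] + K[j] *
        (abs(positions[j, ] - worst_pos) /
           ((fitnesses[j] - worst_fit) + config$epsilon))
    }
  }
  out
}

# shared loop body pieces --------------------------------------------------

# sort state ascending by fitness; returns reordered positions/fitnesses
sort_swarm <- function(positions, fitnesses) {
  ord <- order(fitnesses)
  list(positions = positions[ord, , drop = FALSE], fitnesses = fitnesses[ord])
}

#' Run the baseline sparrow search algorithm
#'
#' Minimizes `objective` over the configured box.  Per iteration the
#' population is sorted by fitness, producers then scroungers then scouts are
#' updated, positions are clipped to the box and re-evaluated, and the greedy
#' incumbent is tracked, so the convergence curve is non-increasing.
#'
#' @param objective Function of a length-`dim` numeric vector returning a
#'   finite scalar.
#' @param config A `swarm_config`.
#' @return A `swarm_result`: `best_position`, `best_fitness`,
#'   `convergence_curve` (length `iter_max`), `evaluations`.
#' @export
optimize_ssa <- function(objective, config) {
  run_swarm(objective, config, producer_fn = function(prod, ranks, state, iter) {
    producer_update_ssa(prod, config)
  }, pes = FALSE)
}

# common optimizer loop; producer_fn(producer_positions, ranks, state, iter)
# returns updated producer rows.  pes toggles the greedy Cauchy perturbation
# of the incumbent (used by the enhanced variant).
run_swarm <- function(objective, config, producer_fn, pes = FALSE,
                      cauchy_scale = 1, cauchy_per_coordinate = FALSE) {
  state <- init_population(config, objective)
  n <- config$pop_size
  np <- ceiling(config$PD * n)
  nsc <- ceiling(config$SD * n)
  evals <- n
  for (iter in seq_len(config$iter_max)) {
    s <- sort_swarm(state$positions, state$fitnesses)
    X <- s$positions; fit <- s$fitnesses
    worst_pos <- X[n, ]; worst_fit <- fit[n]

    # producers (rank 1..np)
    X[seq_len(np), ] <- producer_fn(X[seq_len(np), , drop = FALSE],
                                    seq_len(np),
                                    list(best_position = state$best_position,
                                         best_fitness = state$best_fitness,
                                         worst_position = worst_pos),
                                    iter)
    X[seq_len(np), ] <- clip_box(X[seq_len(np), , drop = FALSE],
                                 matrix(config$lower, np, config$dim, byrow = TRUE),
                                 matrix(config$upper, np, config$dim, byrow = TRUE))
    # posi_a: the best location searched by the producers this iteration,
    # so producers are re-evaluated before the scroungers follow them
    pfit <- eval_rows(objective, X[seq_len(np), , drop = FALSE])
    evals <- evals + np
    if (any(!is.finite(pfit))) {
      stop("objective returned non-finite value at iteration ", iter)
    }
    a_pos <- X[which.min(pfit), ]

    # scroungers (rank np+1..n)
    if (np < n) {
      sc_idx <- seq.int(np + 1L, n)
      X[sc_idx, ] <- scrounger_update(X[sc_idx, , drop = FALSE], sc_idx,
                                      a_pos, worst_pos, config)
      X[sc_idx, ] <- clip_box(X[sc_idx, , drop = FALSE],
                              matrix(config$lower, length(sc_idx), config$dim, byrow = TRUE),
                              matrix(config$upper, length(sc_idx), config$dim, byrow = TRUE))
    }

    # scouts: a random SD fraction, resampled each iteration
    scouts <- sample.int(n, nsc)
    X[scouts, ] <- scout_update(X[scouts, , drop = FALSE], fit[scouts],
                                state$best_position, state$best_fitness,
                                worst_pos, worst_fit, config)
    X[scouts, ] <- clip_box(X[scouts, , drop = FALSE],
                            matrix(config$lower, nsc, config$dim, byrow = TRUE),
                            matrix(config$upper, nsc, config$dim, byrow = TRUE))

    fit <- eval_rows(objective, X)
    evals <- evals + n
    if (any(!is.finite(fit))) {
      stop("objective returned non-finite value at iteration ", iter)
    }

    b <- which.min(fit)
    if (fit[b] < state$best_fitness) {
      state$best_fitness <- fit[b]
      state$best_position <- X[b, ]
    }
    w <- which.max(fit)
    state$worst_position <- X[w, ]
    state$worst_fitness <- fit[w]
    state$positions <- X
    state$fitnesses <- fit

    if (pes) {
      p <- pes_perturb(state$best_position, state$best_fitness, objective,
                       lower = config$lower, upper = config$upper,
                       cauchy_scale = cauchy_scale,
                       per_coordinate = cauchy_per_coordinate)
      state$best_position <- p$position
      state$best_fitness <- p$fitness
      evals <- evals + 1L
    }

    state$iteration <- iter
    state$convergence_curve <- c(state$convergence_curve, state$best_fitness)
  }
  structure(list(best_position = state$best_position,
                 best_fitness = state$best_fitness,
                 convergence_curve = state$convergence_curve,
                 evaluations = evals, config = config),
            class = "swarm_result")
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result: best fitness %.6g after %d iterations>\n",
              x$best_fitness, length(x$convergence_curve)))
  invisible(x)
}

#' Write a convergence curve as two-column delimited text
#'
#' @param result A `swarm_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_convergence <- function(result, path) {
  utils::write.table(
    data.frame(iteration = seq_along(result$convergence_curve),
               best_fitness = result$convergence_curve),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
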