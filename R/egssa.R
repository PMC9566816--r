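# Enhanced global-search sparrow algorithm (EGSSA).  Three changes to the
# baseline SSA, all confined to the producers and the incumbent:
#
#  * PHFS (hunger-state foraging) replaces the producers' safe branch
#    (alarm value below ST): the new position is the hungry-feature map
#    (1 - exp(-|best_d - current_d|)) * u_d * o, coordinate-wise.  The map is
#    an absolute position, not an increment; once the gap to the incumbent
#    underflows exp(), the coordinate becomes exactly 0, which is why
#    origin-optimum functions (sphere, Rastrigin, Griewank) are solved to
#    exactly 0.0 in double precision.
#  * EEPS (exploration/exploitation balance) replaces the alarm branch: a
#    sign-randomized, linearly decaying balance factor steers producers
#    toward (or past) the incumbent, plus a normal step.
#  * PES (perturbation-exploration) multiplies the incumbent by a Cauchy
#    draw once per iteration and keeps the better of the two, so the
#    incumbent never worsens.

#' EGSSA configuration
#'
#' Extends [swarm_config()] with the three strategy parameters: `o`, the
#' hungry-feature adjustment factor (default 2); `delta`, the balance-factor
#' decay control (default 2); and `cauchy_scale`, the Cauchy scale of the
#' incumbent perturbation (default 1).
#'
#' @inheritParams swarm_config
#' @param o Adjustment parameter of the hungry-feature map (> 0).
#' @param delta Balance-factor control parameter (> 0).
#' @param cauchy_scale Cauchy scale of the incumbent perturbation (> 0).
#' @param phfs_anchored Experimental variant: treat the hungry-feature term
#'   as a displacement from the incumbent rather than an absolute position.
#'   Off by default (the absolute form is what reproduces the exact-zero
#'   collapse on origin-optimum functions).
#' @param cauchy_per_coordinate Experimental variant: draw one Cauchy scalar
#'   per coordinate in the incumbent perturbation instead of a single shared
#'   scalar. Off by default.
#' @return An `egssa_config` (also a `swarm_config`).
#' @export
egssa_config <- function(pop_size, dim, lower, upper, iter_max,
                         ST = 0.8, PD = 0.2, SD = 0.1, epsilon = 1e-50,
                         seed = NULL, o = 2, delta = 2, cauchy_scale = 1,
                         phfs_anchored = FALSE,
                         cauchy_per_coordinate = FALSE) {
  stopifnot(o > 0, delta > 0, cauchy_scale > 0)
  cfg <- swarm_config(pop_size, dim, lower, upper, iter_max,
                      ST = ST, PD = PD, SD = SD, epsilon = epsilon, seed = seed)
  cfg$o <- o
  cfg$delta <- delta
  cfg$cauchy_scale <- cauchy_scale
  cfg$phfs_anchored <- isTRUE(phfs_anchored)
  cfg$cauchy_per_coordinate <- isTRUE(cauchy_per_coordinate)
  class(cfg) <- c("egssa_config", class(cfg))
  cfg
}

#' Hunger-state producer update (PHFS)
#'
#' Coordinate-wise absolute reposition
#' `new_d = (1 - exp(-|best_d - current_d|)) * u_d * o` with a fresh
#' `u_d ~ U(0,1)` per coordinate.  The bracket is the hungry-feature form:
#' near the incumbent it vanishes, far from it it saturates at 1, so new
#' positions always lie in `[0, o)` before clipping.
#'
#' @param producer_position,best_position Numeric vectors of equal length.
#' @param config An `egssa_config` (uses `o`).
#' @param u Optional explicit uniform draws (testing).
#' @return The new (unclipped) position vector.
#' @export
phfs_update <- function(producer_position, best_position, config, u = NULL) {
  d <- length(producer_position)
  stopifnot(length(best_position) == d)
  if (is.null(u)) u <- stats::runif(d)
  term <- (1 - exp(-abs(best_position - producer_position))) * u * config$o
  if (isTRUE(config$phfs_anchored)) best_position + term else term
}

#' Balance-factor producer update (EEPS)
#'
#' Balance factor `bf = (2 * para - 1) * delta * (1 - iter / iter_max)` with
#' `para ~ U(0,1)` drawn once per producer; the new position is
#' `bf * (best - current) + Q` with `Q ~ N(0,1)` per coordinate.  `bf`
#' decays linearly to 0 at the final iteration, handing over from global
#' exploration to local exploitation.
#'
#' @param producer_position,best_position Numeric vectors of equal length.
#' @param iter Current iteration (0..`iter_max`).
#' @param config An `egssa_config` (uses `delta`, `iter_max`).
#' @param para,Q Optional explicit draws (testing).
#' @return The new (unclipped) position vector.
#' @export
eeps_update <- function(producer_position, best_position, iter, config,
                        para = NULL, Q = NULL) {
  d <- length(producer_position)
  stopifnot(length(best_position) == d, iter >= 0, iter <= config$iter_max)
  if (is.null(para)) para <- stats::runif(1)
  if (is.null(Q)) Q <- stats::rnorm(d)
  bf <- (2 * para - 1) * (config$delta * (1 - iter / config$iter_max))
  bf * (best_position - producer_position) + Q
}

#' Greedy Cauchy perturbation of the incumbent (PES)
#'
#' Draws one standard-Cauchy scalar `r = tan((u - 0.5) * pi)` (scaled by
#' `cauchy_scale`), forms the candidate `best + r * best`, clips it to the
#' box, evaluates it, and returns whichever of incumbent and candidate is
#' better.  The returned fitness never exceeds the input fitness.
#'
#' @param best_position Incumbent position.
#' @param best_fitness Its cached objective value.
#' @param objective The objective function.
#' @param lower,upper Box bounds for clipping.
#' @param cauchy_scale Cauchy scale parameter (default 1).
#' @param per_coordinate Draw one Cauchy scalar per coordinate instead of a
#'   single shared scalar (experimental; default `FALSE`).
#' @param u Optional explicit uniform draw (testing).
#' @return List with `position` and `fitness`.
#' @export
pes_perturb <- function(best_position, best_fitness, objective,
                        lower = -Inf, upper = Inf, cauchy_scale = 1,
                        per_coordinate = FALSE, u = NULL) {
  if (is.null(u)) {
    u <- stats::runif(if (isTRUE(per_coordinate)) length(best_position) else 1)
  }
  r <- cauchy_scale * tan((u - 0.5) * pi)
  candidate <- clip_box(best_position + r * best_position, lower, upper)
  f <- objective(candidate)
  if (is.finite(f) && f < best_fitness) {
    list(position = candidate, fitness = f)
  } else {
    list(position = best_position, fitness = best_fitness)
  }
}

#' Run the enhanced sparrow search algorithm
#'
#' Identical population machinery to [optimize_ssa()] except that producers
#' use [phfs_update()] when the alarm value is below `ST` and [eeps_update()]
#' otherwise, and the incumbent receives a greedy Cauchy perturbation
#' ([pes_perturb()]) after each iteration's role updates.
#'
#' @param objective Function of a length-`dim` numeric vector returning a
#'   finite scalar.
#' @param config An `egssa_config`.
#' @return A `swarm_result` (see [optimize_ssa()]).
#' @export
optimize_egssa <- function(objective, config) {
  stopifnot(inherits(config, "egssa_config"))
  producer_fn <- function(prod, ranks, state, iter) {
    R2 <- stats::runif(1)
    out <- prod
    for (j in seq_len(nrow(prod))) {
      out[j, ] <- if (R2 < config$ST) {
        phfs_update(prod[j, ], state$best_position, config)
      } else {
        eeps_update(prod[j, ], state$best_position, iter, config)
      }
    }
    out
  }
  run_swarm(objective, config, producer_fn, pes = TRUE,
            cauchy_scale = config$cauchy_scale,
            cauchy_per_coordinate = config$cauchy_per_coordinate)
}

#' Write a run manifest (config, seed, strategy parameters) as JSON
#'
#' @param result A `swarm_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(result, path) {
  cfg <- result$config
  jsonlite::write_json(
    list(optimizer = if (inherits(cfg, "egssa_config")) "egssa" else "ssa",
         pop_size = cfg$pop_size, dim = cfg$dim,
         lower = cfg$lower, upper = cfg$upper, iter_max = cfg$iter_max,
         ST = cfg$ST, PD = cfg$PD, SD = cfg$SD, seed = cfg$seed,
         o = cfg$o, delta = cfg$delta, cauchy_scale = cfg$cauchy_scale,
         best_fitness = result$best_fitness,
         best_position = result$best_position),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
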