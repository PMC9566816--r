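# 23 classical box-constrained benchmark functions (F1-F23): seven unimodal,
# six scalable multimodal, ten fixed-dimension multimodal.  Constants of the
# fixed-dimension functions (Shekel foxholes, Kowalik, Hartman, Shekel) follow
# the canonical benchmark literature tables, which are the only tables
# consistent with the printed optima.

# ---- constant tables -------------------------------------------------------

.foxholes_a <- rbind(
  rep(c(-32, -16, 0, 16, 32), times = 5),
  rep(c(-32, -16, 0, 16, 32), each = 5)
)

.kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
                0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

.hartman3_A <- matrix(c(3, 10, 30,
                        0.1, 10, 35,
                        3, 10, 30,
                        0.1, 10, 35), nrow = 4, byrow = TRUE)
.hartman3_c <- c(1, 1.2, 3, 3.2)
.hartman3_P <- matrix(c(0.3689, 0.1170, 0.2673,
                        0.4699, 0.4387, 0.7470,
                        0.1091, 0.8732, 0.5547,
                        0.03815, 0.5743, 0.8828), nrow = 4, byrow = TRUE)

.hartman6_A <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                        0.05, 10, 17, 0.1, 8, 14,
                        3, 3.5, 1.7, 10, 17, 8,
                        17, 8, 0.05, 10, 0.1, 14), nrow = 4, byrow = TRUE)
.hartman6_c <- c(1, 1.2, 3, 3.2)
.hartman6_P <- matrix(c(0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886,
                        0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991,
                        0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650,
                        0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381),
                      nrow = 4, byrow = TRUE)

.shekel_a <- rbind(c(4, 4, 4, 4), c(1, 1, 1, 1), c(8, 8, 8, 8),
                   c(6, 6, 6, 6), c(3, 7, 3, 7), c(2, 9, 2, 9),
                   c(5, 5, 3, 3), c(8, 1, 8, 1), c(6, 2, 6, 2),
                   c(7, 3.6, 7, 3.6))
.shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

# penalty term of F12/F13: k(x-a)^m above a, k(-x-a)^m below -a, 0 inside
.penalty_u <- function(x, a, k, m) {
  out <- numeric(length(x))
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  sum(out)
}

.shekel_fn <- function(m) {
  a <- .shekel_a[seq_len(m), , drop = FALSE]
  cc <- .shekel_c[seq_len(m)]
  function(x) {
    d2 <- rowSums(sweep(a, 2, x)^2)
    -sum(1 / (d2 + cc))
  }
}

.hartman_fn <- function(A, cvec, P) {
  function(x) {
    e <- rowSums(A * sweep(P, 2, x)^2)
    -sum(cvec * exp(-e))
  }
}

# ---- registry --------------------------------------------------------------

.benchmark_registry <- local({
  row <- function(name, dim, lb, ub, opt, category, fn, stochastic = FALSE,
                  printed_string = NULL) {
    list(name = name, dim = dim, lower_bound = lb, upper_bound = ub,
         printed_optimum = opt, category = category, fn = fn,
         stochastic = stochastic,
         printed_string = if (is.null(printed_string)) format(opt) else printed_string)
  }
  reg <- list(
    F1 = row("F1", 30, -100, 100, 0, "unimodal", function(x) sum(x^2)),
    F2 = row("F2", 30, -10, 10, 0, "unimodal",
             function(x) sum(abs(x)) + prod(abs(x))),
    F3 = row("F3", 30, -100, 100, 0, "unimodal",
             function(x) sum(cumsum(x)^2)),
    F4 = row("F4", 30, -100, 100, 0, "unimodal", function(x) max(abs(x))),
    F5 = row("F5", 30, -30, 30, 0, "unimodal", function(x) {
      n <- length(x)
      sum(100 * (x[-1] - x[-n]^2)^2 + (x[-n] - 1)^2)
    }),
    F6 = row("F6", 30, -100, 100, 0, "unimodal",
             function(x) sum(floor(x + 0.5)^2)),
    F7 = row("F7", 30, -1.28, 1.28, 0, "unimodal",
             function(x) sum(seq_along(x) * x^4) + stats::runif(1),
             stochastic = TRUE),
    F8 = row("F8", 30, -500, 500, -418.9829 * 30, "multimodal",
             function(x) sum(-x * sin(sqrt(abs(x)))),
             printed_string = "-418.9829 x 5"),
    F9 = row("F9", 30, -5.12, 5.12, 0, "multimodal",
             function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)),
    F10 = row("F10", 30, -32, 32, 0, "multimodal", function(x) {
      n <- length(x)
      -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
        20 + exp(1)
    }),
    F11 = row("F11", 30, -600, 600, 0, "multimodal", function(x) {
      sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
    }),
    F12 = row("F12", 30, -50, 50, 0, "multimodal", function(x) {
      n <- length(x)
      y <- 1 + (x + 1) / 4
      (pi / n) * (10 * sin(pi * y[1])^2 +
                    sum((y[-n] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                    (y[n] - 1)^2) +
        .penalty_u(x, 10, 100, 4)
    }),
    F13 = row("F13", 30, -50, 50, 0, "multimodal", function(x) {
      n <- length(x)
      0.1 * (sin(3 * pi * x[1])^2 +
               sum((x[-n] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
               (x[n] - 1)^2 * (1 + sin(2 * pi * x[n])^2)) +
        .penalty_u(x, 5, 100, 4)
    }),
    F14 = row("F14", 2, -65.536, 65.536, 1, "fixed_dimension_multimodal",
              function(x) {
                d6 <- colSums((x - .foxholes_a)^6)
                1 / (1 / 500 + sum(1 / (seq_len(25) + d6)))
              }),
    F15 = row("F15", 4, -5, 5, 0.00030, "fixed_dimension_multimodal",
              function(x) {
                b <- .kowalik_b
                sum((.kowalik_a - x[1] * (b^2 + b * x[2]) /
                       (b^2 + b * x[3] + x[4]))^2)
              }),
    F16 = row("F16", 2, -5, 5, -1.0316, "fixed_dimension_multimodal",
              function(x) {
                4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 + x[1] * x[2] -
                  4 * x[2]^2 + 4 * x[2]^4
              }),
    F17 = row("F17", 2, -5, 5, 0.398, "fixed_dimension_multimodal",
              function(x) {
                (x[2] - 5.1 * x[1]^2 / (4 * pi^2) + 5 * x[1] / pi - 6)^2 +
                  10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10
              }),
    F18 = row("F18", 2, -2, 2, 3, "fixed_dimension_multimodal",
              function(x) {
                (1 + (x[1] + x[2] + 1)^2 *
                   (19 - 14 * x[1] + 3 * x[1]^2 - 14 * x[2] +
                      6 * x[1] * x[2] + 3 * x[2]^2)) *
                  (30 + (2 * x[1] - 3 * x[2])^2 *
                     (18 - 32 * x[1] + 12 * x[1]^2 + 48 * x[2] -
                        36 * x[1] * x[2] + 27 * x[2]^2))
              }),
    F19 = row("F19", 3, 0, 1, -3.86, "fixed_dimension_multimodal",
              .hartman_fn(.hartman3_A, .hartman3_c, .hartman3_P)),
    F20 = row("F20", 6, 0, 1, -3.32, "fixed_dimension_multimodal",
              .hartman_fn(.hartman6_A, .hartman6_c, .hartman6_P)),
    F21 = row("F21", 4, 0, 10, -10.1532, "fixed_dimension_multimodal",
              .shekel_fn(5)),
    F22 = row("F22", 4, 0, 10, -10.4028, "fixed_dimension_multimodal",
              .shekel_fn(7)),
    F23 = row("F23", 4, 0, 10, -10.5363, "fixed_dimension_multimodal",
              .shekel_fn(10))
  )
  reg
})

#' Names of the built-in benchmark functions
#'
#' @return Character vector `c("F1", ..., "F23")`.
#' @export
benchmark_names <- function() names(.benchmark_registry)

#' Construct a benchmark objective
#'
#' Returns one of the 23 classical benchmark functions as a
#' `benchmark_function` object carrying its dimension, box bounds, printed
#' optimum and category.  F1-F13 are 30-dimensional scalable functions;
#' F14-F23 are fixed-dimension multimodal functions whose constant tables
#' (Shekel foxholes, Kowalik, Hartman, Shekel) are built in.
#'
#' Two registry quirks are worth knowing.  The Schwefel function F8 is
#' customarily quoted as "-418.9829 x 5" in suite tables regardless of
#' dimension; the object stores the analytic optimum `-418.9829 * dim` in
#' `printed_optimum` and the customary string in `printed_string`.  The
#' 3-dimensional Hartman function F19 is quoted with range `[1, 3]` in some
#' suite tables, but its printed optimum -3.86 is only attained on the
#' canonical unit box, which is what this registry uses.
#'
#' @param name One of `"F1"` ... `"F23"`.
#' @return A `benchmark_function`: list with `name`, `dim`, `lower_bound`,
#'   `upper_bound`, `printed_optimum`, `category`, `stochastic` and the
#'   evaluator `fn`.
#' @examples
#' f <- make_benchmark("F1")
#' evaluate(f, rep(0, f$dim))
#' @export
make_benchmark <- function(name) {
  if (length(name) != 1L || !name %in% names(.benchmark_registry)) {
    stop("no such benchmark: ", paste(name, collapse = ", "))
  }
  f <- .benchmark_registry[[name]]
  class(f) <- "benchmark_function"
  f
}

#' Evaluate a benchmark function at a point
#'
#' Deterministic for all functions except F7, which adds a uniform draw on
#' `[0, 1)` from the current RNG stream.  Points outside the box are
#' evaluated as-is (optimizers clip before evaluating); a wrong-length `x`
#' is an error.
#'
#' @param func A `benchmark_function` from [make_benchmark()].
#' @param x Numeric vector of length `func$dim`.
#' @return Scalar objective value.
#' @export
evaluate <- function(func, x) {
  stopifnot(inherits(func, "benchmark_function"))
  if (length(x) != func$dim) {
    stop("dimension mismatch: ", func$name, " expects length ", func$dim,
         ", got ", length(x))
  }
  func$fn(as.numeric(x))
}

#' @export
print.benchmark_function <- function(x, ...) {
  cat(sprintf("<benchmark %s: dim %d, box [%g, %g], optimum %s (%s)>\n",
              x$name, x$dim, x$lower_bound, x$upper_bound,
              x$printed_string, x$category))
  invisible(x)
}

#' Benchmark registry as a data frame
#'
#' Machine-readable listing of all 23 functions (name, dimension, bounds,
#' printed optimum, category), matching the TSV shipped under
#' `inst/extdata/benchmarks.tsv`.
#'
#' @return A data frame with one row per function.
#' @export
benchmark_table <- function() {
  do.call(rbind, lapply(.benchmark_registry, function(f) {
    data.frame(name = f$name, dim = f$dim, lower_bound = f$lower_bound,
               upper_bound = f$upper_bound,
               printed_optimum = f$printed_optimum,
               category = f$category, stringsAsFactors = FALSE)
  }))
}
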