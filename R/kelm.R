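# Kernel extreme learning machine (KELM), binary case.  The hidden-layer
# feature map of the ELM is replaced by a Gaussian kernel, so training is the
# closed-form dual solve (K + I/c) w = y with y in {+1, -1}; prediction is the
# kernel expansion sum_i k(x, x_i) w_i with a sign decision.

#' Gaussian kernel matrix
#'
#' Entry (i, j) is `exp(-||A_i - B_j||^2 / (2 * kernel_width^2))`.  The
#' kernel width is read literally as a length scale: larger `kernel_width`
#' means a flatter, wider kernel.
#'
#' @param A,B Numeric matrices with the same number of columns.
#' @param kernel_width Positive length scale.
#' @return An `nrow(A) x nrow(B)` matrix with entries in `(0, 1]`.
#' @export
gaussian_kernel_matrix <- function(A, B, kernel_width) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("column mismatch: A has ", ncol(A), " columns, B has ", ncol(B))
  }
  if (!is.numeric(kernel_width) || length(kernel_width) != 1L ||
      !is.finite(kernel_width) || kernel_width <= 0) {
    stop("kernel_width must be a positive number")
  }
  D2 <- sqdist(A, B)
  exp(-D2 / (2 * kernel_width^2))
}

# pairwise squared Euclidean distances, clamped at 0 against rounding
sqdist <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

# encode arbitrary binary labels as +1/-1; positive_label maps to +1
encode_labels <- function(y, positive_label = NULL) {
  u <- sort(unique(y))
  if (length(u) > 2L) stop("labels must be binary; got ", length(u), " levels")
  if (is.null(positive_label)) {
    positive_label <- if (all(u %in% c(-1, 1))) 1 else u[length(u)]
  }
  ifelse(y == positive_label, 1, -1)
}

#' Train a kernel extreme learning machine
#'
#' Solves the regularized dual system `(K + I/regularization) w = y` where
#' `K` is the Gaussian kernel matrix of the training inputs with themselves
#' and `y` is the `{+1, -1}` label encoding.  The identity is divided by the
#' regularization coefficient, so a larger `regularization` means a weaker
#' ridge and a closer fit.  The solve uses a Cholesky factorization with a
#' least-squares fallback for near-singular systems (tiny kernel widths can
#' make `K` numerically rank deficient).
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Binary label vector (any two values; `positive_label` maps to +1).
#' @param regularization Positive regularization coefficient `c`.
#' @param kernel_width Positive Gaussian kernel width `k`.
#' @param positive_label Value of `y` encoded as +1; defaults to +1 for
#'   numeric `{+1,-1}` labels, else the larger of the two sorted values.
#' @return A `kelm_model`: training inputs, encoded labels, hyperparameters
#'   and the dual weight vector.
#' @export
kelm_train <- function(X, y, regularization, kernel_width,
                       positive_label = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (length(y) != nrow(X)) stop("X and y disagree in length")
  if (!is.finite(regularization) || regularization <= 0) {
    stop("regularization must be positive")
  }
  L <- encode_labels(y, positive_label)
  if (length(unique(L)) < 2L) {
    warning("degenerate training set: a single class present")
  }
  K <- gaussian_kernel_matrix(X, X, kernel_width)
  A <- K + diag(1 / regularization, nrow(K))
  w <- tryCatch(
    {
      R <- chol(A)
      drop(backsolve(R, backsolve(R, L, transpose = TRUE)))
    },
    error = function(e) {
      w <- tryCatch(drop(qr.solve(A, L, tol = 1e-12)),
                    error = function(e2) drop(qr.coef(qr(A, LAPACK = TRUE), L)))
      if (any(!is.finite(w))) {
        stop(sprintf(
          "KELM training failed: singular system at (k = %g, c = %g)",
          kernel_width, regularization))
      }
      w
    })
  structure(
    list(train_inputs = X, train_labels = L, kernel_width = kernel_width,
         regularization = regularization, dual_weights = w),
    class = "kelm_model")
}

#' Predict with a trained KELM
#'
#' Scores are the kernel expansion `sum_i k(x, x_i) * w_i`; labels are the
#' sign of the score with ties (score exactly 0) assigned to the positive
#' class so that runs are reproducible.
#'
#' @param model A `kelm_model`.
#' @param X_new Matrix of query points (columns must match training).
#' @return List with `scores` (numeric) and `labels` (`{+1, -1}`).
#' @export
kelm_predict <- function(model, X_new) {
  stopifnot(inherits(model, "kelm_model"))
  X_new <- as.matrix(X_new)
  if (nrow(X_new) == 0L) {
    return(list(scores = numeric(0), labels = numeric(0)))
  }
  if (ncol(X_new) != ncol(model$train_inputs)) {
    stop("dimension mismatch: model trained on ", ncol(model$train_inputs),
         " features, got ", ncol(X_new))
  }
  Kq <- gaussian_kernel_matrix(X_new, model$train_inputs, model$kernel_width)
  scores <- drop(Kq %*% model$dual_weights)
  labels <- ifelse(scores >= 0, 1, -1)
  list(scores = scores, labels = labels)
}

#' @export
print.kelm_model <- function(x, ...) {
  cat(sprintf("<kelm_model: n = %d, d = %d, kernel width %g, regularization %g>\n",
              nrow(x$train_inputs), ncol(x$train_inputs),
              x$kernel_width, x$regularization))
  invisible(x)
}

#' Serialize / restore a KELM model as flat text
#'
#' Writes inputs, labels, hyperparameters and dual weights to a plain-text
#' file so a fitted model can be archived alongside a report.
#'
#' @param model A `kelm_model`.
#' @param path File path.
#' @return `kelm_save` returns `path` invisibly; `kelm_load` the model.
#' @export
kelm_save <- function(model, path) {
  stopifnot(inherits(model, "kelm_model"))
  obj <- list(kernel_width = model$kernel_width,
              regularization = model$regularization,
              train_labels = model$train_labels,
              dual_weights = model$dual_weights,
              train_inputs = as.data.frame(model$train_inputs))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname kelm_save
#' @export
kelm_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(train_inputs = as.matrix(obj$train_inputs),
         train_labels = as.numeric(obj$train_labels),
         kernel_width = obj$kernel_width,
         regularization = obj$regularization,
         dual_weights = as.numeric(obj$dual_weights)),
    class = "kelm_model")
}
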