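# Dataset loading, preprocessing (missing-row removal, [-1, 1] min-max
# normalization), fold splitting, and a synthetic tabular generator emulating
# small two-class clinical tables (mixed informative/noise features, optional
# missing cells, class imbalance) so every downstream stage is testable
# without the external UCI files.

#' Construct a dataset container
#'
#' @param features Numeric matrix (samples x features); may contain `NA`
#'   for internally marked missing cells.
#' @param labels Vector of `{+1, -1}`.
#' @param feature_names Optional column names.
#' @param positive_label_name Display name of the positive class.
#' @param provenance Character vector of applied transforms.
#' @return A `disease_dataset`.
#' @export
dataset <- function(features, labels, feature_names = NULL,
                    positive_label_name = "positive", provenance = character(0)) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(-1, 1)))
  if (!is.null(feature_names)) colnames(features) <- feature_names
  structure(list(features = features, labels = as.numeric(labels),
                 feature_names = colnames(features),
                 positive_label_name = positive_label_name,
                 provenance = provenance),
            class = "disease_dataset")
}

#' @export
print.disease_dataset <- function(x, ...) {
  cat(sprintf("<disease_dataset: %d samples, %d features, %d positive / %d negative>\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == 1), sum(x$labels == -1)))
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Load a delimited table under a schema
#'
#' The schema names the label column, the label values mapped to the
#' positive class, missing-value markers, and identifier columns to drop.
#' Categorical attributes are mapped to integer codes.  Schemas for the six
#' customary UCI disease tables (breast cancer, heart disease, Parkinson,
#' autism screening for children, Cleveland, Bupa) ship under
#' `system.file("extdata", "schemas", package = "egssa")`; the data files
#' themselves are not redistributed.
#'
#' @param path Delimited text file.
#' @param schema A list (or path to a JSON file) with fields `label_column`
#'   (name or 1-based index), `positive_values` (values mapped to +1),
#'   optional `missing_markers` (default `"?"` and empty string),
#'   `drop_columns`, `sep` (default `","`), `header` (default `FALSE`),
#'   `column_names`.
#' @return A `disease_dataset` with missing cells marked `NA`.
#' @export
load_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  sep <- schema$sep %||% ","
  header <- isTRUE(schema$header)
  missing_markers <- schema$missing_markers %||% c("?", "")
  raw <- utils::read.table(path, sep = sep, header = header,
                           na.strings = missing_markers,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           comment.char = "")
  if (!is.null(schema$column_names)) {
    if (length(schema$column_names) != ncol(raw)) {
      stop("schema names ", length(schema$column_names),
           " columns but file has ", ncol(raw))
    }
    names(raw) <- schema$column_names
  }
  col_id <- function(col) if (is.numeric(col)) names(raw)[col] else col
  label_col <- col_id(schema$label_column)
  if (!label_col %in% names(raw)) stop("label column not found: ", label_col)
  drop <- vapply(schema$drop_columns %||% character(0), col_id, character(1))
  y_raw <- raw[[label_col]]
  if (any(is.na(y_raw))) stop("missing values in label column")
  pos <- schema$positive_values
  known <- unique(y_raw) %in% c(pos, schema$negative_values %||% setdiff(unique(y_raw), pos))
  if (!is.null(schema$negative_values) && !all(known)) {
    stop("unknown label values: ",
         paste(setdiff(unique(y_raw), c(pos, schema$negative_values)), collapse = ", "))
  }
  labels <- ifelse(y_raw %in% pos, 1, -1)
  feats <- raw[, setdiff(names(raw), c(label_col, drop)), drop = FALSE]
  for (j in seq_along(feats)) {
    if (!is.numeric(feats[[j]])) {
      v <- feats[[j]]
      codes <- match(v, sort(unique(stats::na.omit(v)))) - 1L
      feats[[j]] <- as.numeric(codes)
    }
  }
  dataset(as.matrix(feats), labels,
          feature_names = names(feats),
          positive_label_name = paste(pos, collapse = "|"),
          provenance = sprintf("load_table(%s)", basename(path)))
}

#' Remove rows with missing cells
#'
#' @param ds A `disease_dataset`.
#' @return The dataset without rows containing `NA`; provenance records the
#'   number removed.  Idempotent.
#' @export
drop_missing <- function(ds) {
  stopifnot(inherits(ds, "disease_dataset"))
  keep <- stats::complete.cases(ds$features)
  removed <- sum(!keep)
  if (removed == nrow(ds$features)) warning("all rows contained missing values")
  dataset(ds$features[keep, , drop = FALSE], ds$labels[keep],
          feature_names = ds$feature_names,
          positive_label_name = ds$positive_label_name,
          provenance = c(ds$provenance, sprintf("drop_missing(removed=%d)", removed)))
}

#' Column-wise min-max normalization to [-1, 1]
#'
#' `x -> 2 (x - min) / (max - min) - 1` per column.  Constant columns map to
#' 0 with a warning.  When `scaler` (a previously fitted scaler) is given,
#' its ranges are applied instead, so test partitions may fall outside
#' `[-1, 1]`; values are deliberately not clipped.
#'
#' @param ds A `disease_dataset` without missing values.
#' @param scaler Optional scaler from a previous call (attribute `scaler`
#'   of the result).
#' @return Normalized dataset with a `scaler` attribute (`min`, `max`).
#' @export
normalize_minmax <- function(ds, scaler = NULL) {
  stopifnot(inherits(ds, "disease_dataset"))
  X <- ds$features
  if (anyNA(X)) stop("normalize_minmax requires a dataset without missing values")
  if (is.null(scaler)) {
    mins <- apply(X, 2, min)
    maxs <- apply(X, 2, max)
    if (any(maxs == mins)) warning("constant column(s) mapped to 0")
  } else {
    mins <- scaler$min
    maxs <- scaler$max
  }
  rng <- maxs - mins
  Xn <- sweep(X, 2, mins)
  for (j in seq_len(ncol(Xn))) {
    Xn[, j] <- if (rng[j] == 0) 0 else 2 * Xn[, j] / rng[j] - 1
  }
  out <- dataset(Xn, ds$labels, feature_names = ds$feature_names,
                 positive_label_name = ds$positive_label_name,
                 provenance = c(ds$provenance, "normalize_minmax[-1,1]"))
  attr(out, "scaler") <- list(min = mins, max = maxs)
  out
}

#' Seeded k-fold index partition
#'
#' Shuffles `1..n` with the seed, then splits contiguously so fold sizes
#' differ by at most one.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return List of `k` disjoint index vectors whose union is `1..n`.
#' @export
kfold_indices <- function(n, k, seed = NULL) {
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(k), times = sizes))
}

#' Synthetic two-class tabular generator
#'
#' Emulates a small clinical classification table: two multivariate-normal
#' classes with unit within-class standard deviation, separated by
#' `class_separation` (in units of that standard deviation) along the
#' informative coordinates, plus pure-noise N(0,1) coordinates shared by
#' both classes.  Optionally injects uniformly random missing cells.
#'
#' @param n_samples Number of rows (>= 10).
#' @param n_informative Number of informative features.
#' @param n_noise Number of noise features.
#' @param class_separation Mean separation between classes (>= 0); 0 makes
#'   the labels independent of the features.
#' @param positive_fraction Fraction of +1 labels, in (0, 1).
#' @param missing_rate Cell-wise missingness probability in `[0, 1)`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A `disease_dataset` (with `NA` cells when `missing_rate > 0`).
#' @export
synth_generate <- function(n_samples = 300, n_informative = 5, n_noise = 5,
                           class_separation = 2, positive_fraction = 0.5,
                           missing_rate = 0, seed = NULL) {
  stopifnot(n_samples >= 10, n_informative >= 1, n_noise >= 0,
            class_separation >= 0,
            positive_fraction > 0, positive_fraction < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  n_pos <- round(positive_fraction * n_samples)
  labels <- sample(c(rep(1, n_pos), rep(-1, n_samples - n_pos)))
  d <- n_informative + n_noise
  X <- matrix(stats::rnorm(n_samples * d), n_samples, d)
  # symmetric shift: classes at +/- separation/2 on informative coordinates
  shift <- labels * class_separation / 2
  X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + shift
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_samples * d) < missing_rate, n_samples, d)
    X[mask] <- NA
  }
  colnames(X) <- c(paste0("inf", seq_len(n_informative)),
                   if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  dataset(X, labels, feature_names = colnames(X),
          provenance = sprintf(
            "synth_generate(n=%d, inf=%d, noise=%d, sep=%g, pos=%g, miss=%g)",
            n_samples, n_informative, n_noise, class_separation,
            positive_fraction, missing_rate))
}

#' Write a dataset to CSV (round-trips through [load_table()])
#'
#' @param ds A `disease_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$features)
  df$label <- ds$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "?")
  invisible(path)
}
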