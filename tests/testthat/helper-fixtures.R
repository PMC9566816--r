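# fixtures built in code

# literature minimizers of the fixed-dimension functions
literature_minimizers <- list(
  F16 = c(0.08984, -0.7126),
  F17 = c(pi, 2.275),
  F18 = c(0, -1),
  F19 = c(0.114614, 0.555649, 0.852547),
  F20 = c(0.20169, 0.150011, 0.476874, 0.275332, 0.311652, 0.6573),
  F21 = c(4, 4, 4, 4),
  F22 = c(4, 4, 4, 4),
  F23 = c(4, 4, 4, 4)
)

# tiny separable two-class set: one feature, classes at -1 and +1
toy_two_point <- function() {
  list(X = matrix(c(-1, 1), 2, 1), y = c(-1, 1))
}

# small cheap tune config for structural tests
cheap_tune <- function(seed = 1) {
  tune_config(pop_size = 4, iter_max = 5, folds = 5, seed = seed)
}

# write a small delimited file and return its path
write_toy_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

toy_schema <- list(
  sep = ",", header = FALSE,
  column_names = c("a", "b", "lab"),
  label_column = "lab",
  positive_values = "y",
  negative_values = "n",
  drop_columns = list(),
  missing_markers = c("?", "")
)
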