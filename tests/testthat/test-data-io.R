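test_that("load_table applies schema: missing markers, labels, drops", {
  path <- write_toy_csv(c("1,2,y", "3,?,n", "5,6,y", "7,8,n", "9,10,y"))
  ds <- load_table(path, toy_schema)
  expect_s3_class(ds, "disease_dataset")
  expect_equal(dim(ds$features), c(5, 2))
  expect_equal(sum(is.na(ds$features)), 1)
  expect_equal(ds$labels, c(1, -1, 1, -1, 1))

  # schema from a JSON file works identically
  sp <- tempfile(fileext = ".json")
  jsonlite::write_json(toy_schema, sp, auto_unbox = TRUE)
  ds2 <- load_table(path, sp)
  expect_equal(ds2$features, ds$features)

  # unknown label value is an error when negatives are enumerated
  bad <- write_toy_csv(c("1,2,y", "3,4,maybe"))
  expect_error(load_table(bad, toy_schema), "unknown label")
})

test_that("shipped schemas parse and name the six disease tables", {
  dir <- system.file("extdata", "schemas", package = "egssa")
  files <- list.files(dir, full.names = TRUE)
  expect_length(files, 6)
  for (f in files) {
    sch <- jsonlite::read_json(f, simplifyVector = TRUE)
    expect_true(all(c("label_column", "positive_values") %in% names(sch)))
  }
})

test_that("drop_missing removes flagged rows and is idempotent", {
  X <- matrix(1:20, 10, 2)
  X[c(2, 7), 1] <- NA
  ds <- dataset(X, rep(c(1, -1), 5))
  d1 <- drop_missing(ds)
  expect_equal(nrow(d1$features), 8)
  d2 <- drop_missing(d1)
  expect_equal(d1$features, d2$features)
  # no missing cells: identity
  clean <- dataset(matrix(1:6, 3, 2), c(1, -1, 1))
  expect_equal(drop_missing(clean)$features, clean$features)
  # all rows missing: empty with warning
  allna <- dataset(matrix(NA_real_, 2, 2), c(1, -1))
  expect_warning(e <- drop_missing(allna), "all rows")
  expect_equal(nrow(e$features), 0)
})

test_that("min-max normalization maps to [-1,1] and handles fitted scalers", {
  ds <- dataset(matrix(c(2, 4, 6, 5, 5, 5), 3, 2), c(1, -1, 1))
  expect_warning(n <- normalize_minmax(ds), "constant")
  expect_equal(n$features[, 1], c(-1, 0, 1))
  expect_equal(n$features[, 2], c(0, 0, 0))

  # train-fitted scaler applied to an out-of-range test value: 1.4, unclipped
  tr <- dataset(matrix(c(0, 10), 2, 1), c(1, -1))
  trn <- normalize_minmax(tr)
  te <- dataset(matrix(12, 1, 1), 1)
  ten <- normalize_minmax(te, scaler = attr(trn, "scaler"))
  expect_equal(ten$features[1, 1], 1.4)

  # every non-constant column spans exactly [-1, 1]
  set.seed(2)
  big <- dataset(matrix(rnorm(60), 20, 3), rep(c(1, -1), 10))
  bn <- normalize_minmax(big)
  expect_equal(unname(apply(bn$features, 2, range)),
               matrix(c(-1, 1), 2, 3))
})

test_that("kfold indices partition exactly with near-equal sizes", {
  f <- kfold_indices(25, 10, seed = 3)
  sizes <- lengths(f)
  expect_equal(sort(unname(sizes)), c(rep(2, 5), rep(3, 5)))
  expect_equal(sort(unname(unlist(f))), 1:25)
  f2 <- kfold_indices(25, 10, seed = 3)
  expect_identical(f, f2)
  expect_error(kfold_indices(5, 10), "k <= n")
})

test_that("synthetic generator matches its stated world", {
  ds <- synth_generate(n_samples = 200, n_informative = 3, n_noise = 2,
                       class_separation = 6, positive_fraction = 0.3,
                       seed = 12)
  expect_equal(dim(ds$features), c(200, 5))
  expect_equal(sum(ds$labels == 1), 60)
  # informative coordinates separate the classes by ~6 within-class sds
  gap <- colMeans(ds$features[ds$labels == 1, 1:3]) -
    colMeans(ds$features[ds$labels == -1, 1:3])
  expect_true(all(abs(gap - 6) < 1))
  # noise coordinates do not separate
  gap_n <- colMeans(ds$features[ds$labels == 1, 4:5]) -
    colMeans(ds$features[ds$labels == -1, 4:5])
  expect_true(all(abs(gap_n) < 1))

  # missing-cell injection: ~binomial(n*d, rate) cells, removable rows
  dm <- synth_generate(n_samples = 200, n_informative = 3, n_noise = 2,
                       missing_rate = 0.1, seed = 13)
  n_missing <- sum(is.na(dm$features))
  expect_gt(n_missing, 60)   # E = 100, sd ~ 9.5
  expect_lt(n_missing, 140)
  expect_false(anyNA(drop_missing(dm)$features))

  # determinism
  expect_identical(synth_generate(seed = 5)$features,
                   synth_generate(seed = 5)$features)
})

test_that("datasets round-trip through CSV", {
  ds <- synth_generate(n_samples = 20, n_informative = 2, n_noise = 1,
                       seed = 9)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  sch <- list(sep = ",", header = TRUE, label_column = "label",
              positive_values = 1)
  back <- load_table(path, sch)
  expect_equal(unname(back$labels), unname(ds$labels))
  expect_equal(unname(back$features), unname(ds$features), tolerance = 1e-10)
})
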