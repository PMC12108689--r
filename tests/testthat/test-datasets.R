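# Tabular I/O, stratified splitting, scaling and the synthetic generator.

test_that("tabular reader encodes labels by first appearance, any delimiter", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("g1,g2,label", "1.5,2,A", "3,4,B", "5,6.5,A", "7,8,B"), csv)
  ds <- read_tabular(csv, "label")
  expect_identical(ds$y, c(0L, 1L, 0L, 1L))
  expect_identical(ds$label_levels, c("A", "B"))
  expect_identical(ds$feature_names, c("g1", "g2"))
  expect_equal(unname(ds$X[3, 2]), 6.5)
  # same content as TSV reads identically
  tsv <- tempfile(fileext = ".tsv")
  writeLines(gsub(",", "\t", readLines(csv)), tsv)
  ds2 <- read_tabular(tsv, "label")
  expect_identical(ds2$X, ds$X)
  expect_identical(ds2$y, ds$y)
  # label column by index, headerless file
  noh <- tempfile(fileext = ".csv")
  writeLines(c("1,2,0", "3,4,1", "5,6,0", "7,8,1"), noh)
  ds3 <- read_tabular(noh, label_column = 3)
  expect_identical(ds3$y, c(0L, 1L, 0L, 1L))
  expect_identical(ds3$feature_names, c("f1", "f2"))
  # non-numeric feature cell is reported with its location
  bad <- tempfile(fileext = ".csv")
  writeLines(c("g1,g2,label", "1,2,A", "NA,4,B", "5,6,A", "7,8,B"), bad)
  expect_error(read_tabular(bad, "label"), "row 2, column 'g1'")
  # single-class files are rejected
  one <- tempfile(fileext = ".csv")
  writeLines(c("g1,g2,label", "1,2,A", "3,4,A", "5,6,A", "7,8,A"), one)
  expect_error(read_tabular(one, "label"), "2 distinct")
})

test_that("write/read round-trips a dataset exactly", {
  ds <- small_synthetic(seed = 4)
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_tabular(f, "label")
  expect_equal(back$X, ds$X, ignore_attr = FALSE)
  expect_identical(back$y, ds$y)
  expect_identical(back$feature_names, ds$feature_names)
  # truth sidecar holds 0-based informative indices
  truth <- as.integer(readLines(paste0(f, ".truth.txt")))
  expect_identical(truth, which(ds$truth_mask == 1L) - 1L)
})

test_that("stratified holdout keeps class proportions and is seed-stable", {
  set.seed(1)
  ds <- labeled_dataset(matrix(rnorm(10 * 3), 10, 3), rep(c("a", "b"), 5))
  set.seed(2)
  sp <- stratified_holdout(ds, 0.2)
  expect_identical(as.vector(table(sp$test$y)), c(1L, 1L))
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:10)
  # fraction 0.5 on 4 balanced samples: one of each class per side
  ds4 <- labeled_dataset(matrix(rnorm(8), 4, 2), c("a", "b", "a", "b"))
  set.seed(3)
  sp4 <- stratified_holdout(ds4, 0.5)
  expect_identical(as.vector(table(sp4$test$y)), c(1L, 1L))
  expect_identical(as.vector(table(sp4$train$y)), c(1L, 1L))
  # determinism under a fixed seed
  set.seed(9); a <- stratified_holdout(ds, 0.2)
  set.seed(9); b <- stratified_holdout(ds, 0.2)
  expect_identical(a$test_idx, b$test_idx)
  # a singleton class cannot be stratified
  ds_bad <- labeled_dataset(matrix(rnorm(15), 5, 3), c("a", "a", "a", "a", "b"))
  expect_error(stratified_holdout(ds_bad, 0.2), "fewer than 2")
})

test_that("stratified k-fold partitions the samples class-proportionally", {
  set.seed(1)
  ds <- labeled_dataset(matrix(rnorm(20 * 2), 20, 2), rep(c("a", "b"), 10))
  set.seed(2)
  folds <- stratified_kfold(ds, 10)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f$test_idx, 2)
    expect_identical(as.vector(table(f$test$y)), c(1L, 1L))
  }
  all_test <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_identical(all_test, 1:20) # a partition: disjoint and exhaustive
  expect_error(stratified_kfold(ds, 1), "at least 2")
  # fold count shrinks to the smallest class with a warning
  ds_small <- labeled_dataset(matrix(rnorm(12 * 2), 12, 2),
                              c(rep("a", 9), rep("b", 3)))
  set.seed(3)
  expect_warning(f2 <- stratified_kfold(ds_small, 5), "reducing n_folds")
  expect_length(f2, 3)
})

test_that("synthetic generator honors its spec and is reproducible", {
  spec <- synthetic_spec(n = 60, n_classes = 3, n_informative = 10,
                         n_redundant = 20, n_noise = 470)
  ds <- synthesize_dataset(spec, seed = 11)
  expect_identical(dim(ds$X), c(60L, 500L))
  expect_identical(sum(ds$truth_mask), 10L)
  expect_identical(as.vector(table(ds$y)), c(20L, 20L, 20L))
  # bit-identical regeneration from the same spec and seed
  ds2 <- synthesize_dataset(spec, seed = 11)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$y, ds2$y)
  # redundant features track their informative parents
  sm <- synthesize_dataset(synthetic_spec(n = 100, n_classes = 2,
    n_informative = 4, n_redundant = 8, n_noise = 8, delta = 2,
    redundancy_noise = 0.5), seed = 12)
  red_cols <- which(startsWith(sm$feature_names, "red"))
  inf_cols <- which(startsWith(sm$feature_names, "inf"))
  best_cor <- sapply(red_cols, function(j)
    max(abs(cor(sm$X[, j], sm$X[, inf_cols]))))
  expect_true(all(best_cor >= 0.5))
  # too few informative features for distinct class signatures
  expect_error(synthetic_spec(n_classes = 4, n_informative = 1), "distinct")
})

test_that("class separation scales with delta as advertised", {
  # delta = 0: no signal; full-feature KNN is at chance level
  errs0 <- sapply(1:5, function(s) {
    ds <- synthesize_dataset(synthetic_spec(n = 60, n_classes = 3,
      n_informative = 10, n_redundant = 20, n_noise = 170, delta = 0), seed = s)
    set.seed(s)
    sp <- stratified_holdout(ds, 0.2)
    subset_error(sp$train, sp$test, rep(1L, ncol(ds$X)), k = 5)
  })
  expect_lt(abs(mean(errs0) - 2 / 3), 0.07)
  # delta = 3: the truth features alone classify nearly perfectly
  errs3 <- sapply(1:10, function(s) {
    ds <- reference_synthetic(seed = s)
    set.seed(s)
    sp <- stratified_holdout(ds, 0.2)
    subset_error(sp$train, sp$test, ds$truth_mask, k = 5)
  })
  expect_lte(mean(errs3), 0.05)
})

test_that("min-max scaling uses training statistics only", {
  sc <- min_max_scale(matrix(c(2, 4), 2, 1))
  expect_equal(sc$train, matrix(c(0, 1), 2, 1))
  # constant training column maps to 0 everywhere
  sc2 <- min_max_scale(matrix(5, 2, 1), matrix(9, 1, 1))
  expect_equal(sc2$train, matrix(0, 2, 1))
  expect_equal(sc2$apply, matrix(0, 1, 1))
  # applied values outside the training range are not clipped
  sc3 <- min_max_scale(matrix(c(2, 4), 2, 1), matrix(6, 1, 1))
  expect_equal(sc3$apply, matrix(2, 1, 1))
})
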