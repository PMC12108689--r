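# Dataset container, tabular I/O, stratified splitting, min-max scaling and
# the synthetic high-dimensional generator.

#' Labeled dataset container
#'
#' A samples-by-features numeric matrix with integer class codes. Class
#' labels are encoded as consecutive integers `0, 1, 2, ...` in order of
#' first appearance; the original labels are kept in `label_levels`.
#'
#' @param X Numeric matrix (samples in rows, features in columns) with no
#'   missing values.
#' @param y Class labels, one per row of `X` (any atomic type; at least
#'   two distinct values).
#' @param feature_names Optional feature names; defaults to `colnames(X)`
#'   or `f1..fD`.
#' @param truth_mask Optional 0/1 vector of length `ncol(X)` marking the
#'   truly informative features (synthetic data only).
#' @return An object of class `labeled_dataset` with elements `X`, `y`
#'   (integer codes), `label_levels`, `feature_names`, `truth_mask`.
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(20), 4, 5), c("a", "b", "a", "b"))
#' ds$y
#' @export
labeled_dataset <- function(X, y, feature_names = NULL, truth_mask = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values")
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(y)) stop("labels contain missing values")
  lev <- unique(y)
  if (length(lev) < 2L) stop("need at least 2 distinct class labels")
  code <- match(y, lev) - 1L
  feature_names <- feature_names %||% colnames(X) %||%
    paste0("f", seq_len(ncol(X)))
  if (length(feature_names) != ncol(X))
    stop("feature_names must have one entry per column")
  colnames(X) <- feature_names
  if (!is.null(truth_mask)) {
    truth_mask <- as.integer(truth_mask)
    if (length(truth_mask) != ncol(X) || !all(truth_mask %in% c(0L, 1L)))
      stop("truth_mask must be a 0/1 vector of length ncol(X)")
  }
  structure(list(X = X, y = code, label_levels = as.character(lev),
                 feature_names = feature_names, truth_mask = truth_mask),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset: %d samples x %d features, %d classes (%s)\n",
              nrow(x$X), ncol(x$X), length(x$label_levels),
              paste(x$label_levels, collapse = ", ")))
  if (!is.null(x$truth_mask))
    cat(sprintf("  ground truth: %d informative features\n", sum(x$truth_mask)))
  invisible(x)
}

# Row subset that preserves the label encoding of the parent dataset.
ds_subset <- function(dataset, idx) {
  out <- dataset
  out$X <- dataset$X[idx, , drop = FALSE]
  out$y <- dataset$y[idx]
  out
}

n_classes <- function(dataset) length(dataset$label_levels)

#' Read a samples-by-features table with a label column
#'
#' Reads a CSV or TSV file whose rows are samples and whose columns are
#' numeric features plus one label column. The delimiter is auto-detected
#' (comma vs tab) and a header row is auto-detected by checking whether
#' the first line parses as numbers. Labels are encoded as integers by
#' first appearance.
#'
#' @param path File path.
#' @param label_column Label column, by name (requires a header) or by
#'   1-based index. Default `"label"`.
#' @param delimiter `"auto"` (default), `","` or `"\t"`.
#' @return A [labeled_dataset()].
#' @export
read_tabular <- function(path, label_column = "label",
                         delimiter = c("auto", ",", "\t")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- delimiter
  if (sep == "auto") {
    n_tab <- nchar(first) - nchar(gsub("\t", "", first, fixed = TRUE))
    n_com <- nchar(first) - nchar(gsub(",", "", first, fixed = TRUE))
    if (n_tab == 0L && n_com == 0L)
      stop("could not detect a comma or tab delimiter in ", path)
    sep <- if (n_tab >= n_com) "\t" else ","
  }
  fields1 <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (is.character(label_column) &&
      suppressWarnings(is.na(as.numeric(label_column)))) {
    header <- TRUE
  } else {
    li0 <- as.integer(label_column)
    cand <- if (li0 >= 1L && li0 <= length(fields1)) fields1[-li0] else fields1
    header <- any(is.na(suppressWarnings(as.numeric(cand))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (is.character(label_column) &&
      suppressWarnings(is.na(as.numeric(label_column)))) {
    li <- match(label_column, names(df))
    if (is.na(li)) stop("label column '", label_column, "' not found")
  } else {
    li <- as.integer(label_column)
    if (li < 1L || li > ncol(df)) stop("label column index out of range")
  }
  y_raw <- df[[li]]
  if (any(is.na(y_raw)) || any(y_raw == ""))
    stop("missing labels in ", path)
  feat <- df[-li]
  D <- length(feat)
  if (D < 1L) stop("no feature columns in ", path)
  X <- matrix(NA_real_, nrow(df), D)
  for (j in seq_len(D)) {
    col <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(is.na(col))
    if (length(bad))
      stop(sprintf("non-numeric feature value '%s' at row %d, column '%s'",
                   feat[[j]][bad[1]], bad[1], names(feat)[j]))
    X[, j] <- col
  }
  fnames <- if (header) names(feat) else paste0("f", seq_len(D))
  labeled_dataset(X, y_raw, feature_names = fnames)
}

#' Write a dataset to CSV/TSV with an optional ground-truth sidecar
#'
#' Writes the dataset with a header row (feature names plus a final
#' `label` column carrying the original labels). Numbers are printed with
#' 17 significant digits so a write/read cycle is lossless. If the
#' dataset carries a `truth_mask`, the 0-based indices of the informative
#' features are written to `<path>.truth.txt`.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output file path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  df <- as.data.frame(lapply(seq_len(ncol(dataset$X)), function(j)
    sprintf("%.17g", dataset$X[, j])), stringsAsFactors = FALSE)
  names(df) <- dataset$feature_names
  df$label <- dataset$label_levels[dataset$y + 1L]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$truth_mask))
    writeLines(as.character(which(dataset$truth_mask == 1L) - 1L),
               paste0(path, ".truth.txt"))
  invisible(path)
}

#' Stratified holdout split
#'
#' Splits the samples of every class in the given proportion, keeping at
#' least one sample of each class on both sides. Uses the current RNG
#' stream; seed with [set.seed()] for a reproducible split.
#'
#' @param dataset A [labeled_dataset()]; every class needs >= 2 samples.
#' @param test_fraction Fraction of each class put in the test part.
#' @return List with elements `train`, `test` (datasets) and `train_idx`,
#'   `test_idx` (row indices into the input).
#' @export
stratified_holdout <- function(dataset, test_fraction = 0.2) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  y <- dataset$y
  test_idx <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < 2L)
      stop("class '", dataset$label_levels[cl + 1L],
           "' has fewer than 2 samples; cannot stratify")
    nt <- round(test_fraction * length(idx))
    nt <- max(1L, min(length(idx) - 1L, nt))
    test_idx <- c(test_idx, sample(idx, nt))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(y), test_idx)
  list(train = ds_subset(dataset, train_idx),
       test = ds_subset(dataset, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Stratified k-fold partition
#'
#' Assigns the samples of every class round-robin to folds after a random
#' shuffle, so the folds partition the sample set and each fold is close
#' to class-proportional. If the smallest class has fewer samples than
#' `n_folds`, the fold count is reduced to that size with a warning.
#'
#' @param dataset A [labeled_dataset()].
#' @param n_folds Number of folds, at least 2.
#' @return List of `n_folds` elements, each a list with `train`, `test`,
#'   `train_idx`, `test_idx`.
#' @export
stratified_kfold <- function(dataset, n_folds = 10) {
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2L) stop("n_folds must be at least 2")
  y <- dataset$y
  min_class <- min(table(y))
  if (min_class < 2L)
    stop("smallest class has fewer than 2 samples; cannot stratify")
  if (min_class < n_folds) {
    warning(sprintf("reducing n_folds from %d to %d (smallest class size)",
                    n_folds, min_class))
    n_folds <- as.integer(min_class)
  }
  fold_of <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  lapply(seq_len(n_folds), function(f) {
    te <- which(fold_of == f)
    tr <- which(fold_of != f)
    list(train = ds_subset(dataset, tr), test = ds_subset(dataset, te),
         train_idx = tr, test_idx = te)
  })
}

#' Specification of a synthetic high-dimensional dataset
#'
#' Describes a small-sample, high-dimensional multi-class dataset with a
#' known informative block, the regime of gene-expression tumor data:
#' `n_informative` class-separating features, `n_redundant` noisy copies
#' of informative features, and `n_noise` class-independent features. The
#' defaults (60 samples, 3 balanced classes, 10 informative + 20
#' redundant + 470 noise features, class separation `delta = 3` noise
#' SDs) are the package's reference recovery benchmark.
#'
#' @param n Number of samples.
#' @param n_classes Number of classes (>= 2).
#' @param n_informative Number of truly informative features (>= 1).
#' @param n_redundant Number of redundant features, each a random
#'   informative feature plus Gaussian noise.
#' @param n_noise Number of pure-noise features.
#' @param delta Class-mean separation in units of the noise SD (>= 0).
#' @param redundancy_noise SD of the noise added to redundant copies.
#' @param label_balance Optional class proportions (length `n_classes`,
#'   normalized internally); `NULL` means balanced.
#' @param seed Default RNG seed used by [synthesize_dataset()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 60L, n_classes = 3L, n_informative = 10L,
                           n_redundant = 20L, n_noise = 470L, delta = 3,
                           redundancy_noise = 0.5, label_balance = NULL,
                           seed = 1L) {
  n <- as.integer(n); n_classes <- as.integer(n_classes)
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  n_noise <- as.integer(n_noise)
  if (n_classes < 2L) stop("need at least 2 classes")
  if (n_informative < 1L) stop("need at least 1 informative feature")
  if (n_redundant < 0L || n_noise < 0L) stop("feature counts must be >= 0")
  if (delta < 0) stop("delta must be >= 0")
  if (redundancy_noise < 0) stop("redundancy_noise must be >= 0")
  if (3^n_informative < n_classes)
    stop("n_informative too small to give every class a distinct signature")
  if (!is.null(label_balance)) {
    if (length(label_balance) != n_classes || any(label_balance <= 0))
      stop("label_balance needs one positive weight per class")
    label_balance <- label_balance / sum(label_balance)
  }
  if (n < 2L * n_classes) stop("need at least 2 samples per class")
  structure(list(n = n, n_classes = n_classes,
                 n_informative = n_informative, n_redundant = n_redundant,
                 n_noise = n_noise, delta = delta,
                 redundancy_noise = redundancy_noise,
                 label_balance = label_balance, seed = seed),
            class = "synthetic_spec")
}

# Distinct class signatures over {-1, 0, +1}^m, rejection-sampled so that
# every pair of classes differs in at least one informative feature.
class_signatures <- function(K, m) {
  for (attempt in 1:1000) {
    sig <- matrix(sample(c(-1, 0, 1), K * m, replace = TRUE), K, m)
    if (nrow(unique(sig)) == K) return(sig)
  }
  stop("could not draw distinct class signatures; increase n_informative")
}

#' Generate a synthetic labeled dataset
#'
#' Draws a dataset from a [synthetic_spec()]: informative feature `j` of
#' a class-`c` sample is `Normal(delta * m[c, j], 1)` where `m` is a
#' class-signature matrix with entries in `{-1, 0, +1}` and distinct rows
#' per class; each redundant feature is a randomly chosen informative
#' feature plus `Normal(0, redundancy_noise)` noise; noise features are
#' standard normal. The returned dataset carries a `truth_mask` marking
#' the informative block.
#'
#' @param spec A [synthetic_spec()].
#' @param seed RNG seed (defaults to `spec$seed`); pass `NULL` to use the
#'   current RNG stream.
#' @return A [labeled_dataset()] with ground truth.
#' @examples
#' ds <- synthesize_dataset(synthetic_spec(n = 24, n_classes = 2,
#'   n_informative = 2, n_redundant = 2, n_noise = 16))
#' sum(ds$truth_mask)
#' @export
synthesize_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  K <- spec$n_classes
  props <- spec$label_balance %||% rep(1 / K, K)
  counts <- floor(props * spec$n)
  rem <- spec$n - sum(counts)
  if (rem > 0) {
    frac <- props * spec$n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  if (any(counts < 2L)) stop("label_balance leaves a class with < 2 samples")
  y <- rep.int(seq_len(K) - 1L, counts)
  n <- spec$n
  m <- spec$n_informative
  sig <- class_signatures(K, m)
  X_inf <- spec$delta * sig[y + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * m), n, m)
  X_red <- NULL
  if (spec$n_redundant > 0L) {
    parents <- sample.int(m, spec$n_redundant, replace = TRUE)
    X_red <- X_inf[, parents, drop = FALSE] +
      matrix(stats::rnorm(n * spec$n_redundant, 0, spec$redundancy_noise),
             n, spec$n_redundant)
  }
  X_noise <- NULL
  if (spec$n_noise > 0L)
    X_noise <- matrix(stats::rnorm(n * spec$n_noise), n, spec$n_noise)
  X <- cbind(X_inf, X_red, X_noise)
  fnames <- c(paste0("inf", seq_len(m)),
              if (spec$n_redundant > 0L) paste0("red", seq_len(spec$n_redundant)),
              if (spec$n_noise > 0L) paste0("noise", seq_len(spec$n_noise)))
  truth <- c(rep(1L, m), rep(0L, spec$n_redundant + spec$n_noise))
  labeled_dataset(X, paste0("class", y + 1L), feature_names = fnames,
                  truth_mask = truth)
}

#' Min-max scaling with training-set statistics
#'
#' Maps every column to `(x - min) / (max - min)` using minima and maxima
#' computed on the training matrix only. Columns that are constant in the
#' training data map to 0 everywhere; values of `apply_X` outside the
#' training range are not clipped.
#'
#' @param train_X Training matrix whose column statistics define the map.
#' @param apply_X Optional second matrix scaled with the same statistics.
#' @return List with `train` and (if given) `apply`.
#' @export
min_max_scale <- function(train_X, apply_X = NULL) {
  train_X <- as.matrix(train_X)
  mins <- apply(train_X, 2, min)
  maxs <- apply(train_X, 2, max)
  rng <- maxs - mins
  const <- rng == 0
  div <- ifelse(const, 1, rng)
  rescale <- function(M) {
    Z <- sweep(sweep(as.matrix(M), 2, mins), 2, div, "/")
    Z[, const] <- 0
    Z
  }
  out <- list(train = rescale(train_X))
  if (!is.null(apply_X)) out$apply <- rescale(apply_X)
  out
}
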