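# Wrapper objective: KNN classification error on a masked feature subset
# combined with a subset-size penalty.

#' Wrapper fitness value
#'
#' The scalarized feature-selection objective
#' \deqn{fitness = \omega E + (1 - \omega) d / D}
#' where `E` is the classification error rate of the wrapper classifier,
#' `d` the number of selected features, `D` the total feature count and
#' `omega` the trade-off weight (0.99 by default, so accuracy dominates
#' and the size term breaks ties among equally accurate subsets).
#'
#' @param E Classification error rate in `[0, 1]`.
#' @param d Number of selected features (`1 <= d <= D`).
#' @param D Total number of features.
#' @param omega Trade-off weight in `[0, 1]`.
#' @return The fitness value; lower is better.
#' @examples
#' fitness_value(0.2, 10, 100) # 0.199
#' @export
fitness_value <- function(E, d, D, omega = 0.99) {
  if (is.na(E) || E < 0 || E > 1) stop("E must lie in [0, 1]")
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (d < 1 || d > D) stop("subset size d must satisfy 1 <= d <= D")
  omega * E + (1 - omega) * d / D
}

# Record of one evaluated mask.
fitness_record <- function(fitness, error, subset_size, D) {
  structure(list(fitness = fitness, error = error,
                 subset_size = as.integer(subset_size), D = as.integer(D)),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("fitness %.6f (error %s, %d/%d features)\n", x$fitness,
              if (is.na(x$error)) "NA" else sprintf("%.4f", x$error),
              x$subset_size, x$D))
  invisible(x)
}

#' K-nearest-neighbor classification
#'
#' Euclidean KNN with deterministic tie handling: distance ties are broken
#' by the lower training-row index, vote ties by the smallest label value.
#' If fewer than `k` training rows are available, `k` is reduced with a
#' warning.
#'
#' @param train_X Training matrix (rows are samples).
#' @param train_y Integer labels, one per training row.
#' @param query Query vector, or a matrix of query rows.
#' @param k Neighbor count.
#' @return Predicted label(s), one per query row.
#' @export
knn_classify <- function(train_X, train_y, query, k = 5) {
  train_X <- as.matrix(train_X)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- as.matrix(query)
  if (ncol(query) != ncol(train_X))
    stop("query and training data must share the feature dimension")
  n <- nrow(train_X)
  if (length(train_y) != n) stop("one training label per training row needed")
  if (k > n) {
    warning(sprintf("only %d training rows; reducing k from %d", n, k))
    k <- n
  }
  labs <- sort(unique(train_y))
  d2 <- outer(rowSums(query^2), rowSums(train_X^2), `+`) -
    2 * tcrossprod(query, train_X)
  pred <- vector(mode = typeof(train_y), length = nrow(query))
  for (q in seq_len(nrow(query))) {
    ord <- order(d2[q, ])               # stable: ties keep the lower index
    votes <- train_y[ord[seq_len(k)]]
    counts <- tabulate(match(votes, labs), nbins = length(labs))
    pred[q] <- labs[which.max(counts)]  # first max = smallest tied label
  }
  pred
}

# Error rate of masked-feature KNN on pre-extracted matrices.
knn_error <- function(train_X, train_y, test_X, test_y, idx, k) {
  pred <- knn_classify(train_X[, idx, drop = FALSE], train_y,
                       test_X[, idx, drop = FALSE], k)
  mean(pred != test_y)
}

#' Classification error of a feature subset
#'
#' Fraction of evaluation samples misclassified by [knn_classify()] using
#' only the features selected by `mask`.
#'
#' @param train,eval [labeled_dataset()]s sharing the feature dimension.
#' @param mask 0/1 vector with at least one set bit.
#' @param k Neighbor count.
#' @return Error rate in `[0, 1]`.
#' @export
subset_error <- function(train, eval, mask, k = 5) {
  mask <- as.integer(mask)
  if (length(mask) != ncol(train$X) || length(mask) != ncol(eval$X))
    stop("mask length must equal the feature count")
  idx <- which(mask == 1L)
  if (length(idx) == 0L) stop("mask selects no features")
  knn_error(train$X, train$y, eval$X, eval$y, idx, k)
}

#' Build the wrapper fitness evaluator for one optimization run
#'
#' Freezes everything stochastic about the objective once per run: a
#' stratified holdout split of the given data (80/20 by default) and,
#' optionally, min-max scaling computed from the training part. The
#' returned evaluator is then a pure function of the bitmask, so personal
#' and global best comparisons are meaningful. The empty mask gets the
#' sentinel fitness 1.0 (worse than any valid subset) with no classifier
#' call.
#'
#' @param dataset A [labeled_dataset()].
#' @param control An [fs_control()].
#' @param seed Optional seed; `NULL` (default) uses the current RNG
#'   stream, which is how the optimizers call it.
#' @return An object of class `fitness_evaluator`: a list with `fn`
#'   (mask -> `fitness_record`), `D`, and the split indices.
#' @export
make_fitness <- function(dataset, control = fs_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- stratified_holdout(dataset, control$test_fraction)
  X_tr <- sp$train$X
  X_te <- sp$test$X
  if (control$scale == "minmax") {
    sc <- min_max_scale(X_tr, X_te)
    X_tr <- sc$train
    X_te <- sc$apply
  }
  y_tr <- sp$train$y
  y_te <- sp$test$y
  D <- ncol(X_tr)
  omega <- control$omega
  k <- control$k
  fn <- function(mask) {
    mask <- as.integer(mask)
    if (length(mask) != D) stop("mask length must equal the feature count")
    d <- sum(mask)
    if (d == 0L) return(fitness_record(1, NA_real_, 0L, D))
    idx <- which(mask == 1L)
    E <- knn_error(X_tr, y_tr, X_te, y_te, idx, k)
    fitness_record(fitness_value(E, d, D, omega), E, d, D)
  }
  structure(list(fn = fn, D = D, train_idx = sp$train_idx,
                 test_idx = sp$test_idx, control = control),
            class = "fitness_evaluator")
}

#' Evaluate one feature mask
#'
#' Convenience wrapper that builds a [make_fitness()] evaluator with the
#' given seed and applies it to one mask. With the same dataset, control
#' and seed the result is identical across calls.
#'
#' @param dataset A [labeled_dataset()].
#' @param mask 0/1 vector of length `ncol(dataset$X)`.
#' @param control An [fs_control()].
#' @param seed Seed fixing the internal holdout split.
#' @return A `fitness_record` with elements `fitness`, `error`,
#'   `subset_size`, `D`.
#' @export
evaluate_mask <- function(dataset, mask, control = fs_control(), seed = 1L) {
  make_fitness(dataset, control, seed = seed)$fn(mask)
}
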