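# Repeated-run benchmarking with an unseen outer test split, plus rank
# statistics (Friedman average ranks, Wilcoxon signed-rank) and trace export.

alg_runner <- function(alg) {
  switch(alg,
         mrfl = function(ds, control, seed) run_bpso_mrfl(ds, control, seed),
         sbpso = function(ds, control, seed) run_bpso(ds, "sshape", control, seed),
         vbpso = function(ds, control, seed) run_bpso(ds, "vshape", control, seed),
         stop("unknown algorithm '", alg, "' (use mrfl, sbpso or vbpso)"))
}

# Accuracy of a selected subset on data unseen during feature selection.
outer_accuracy <- function(fs_data, unseen, mask, control) {
  X_tr <- fs_data$X
  X_te <- unseen$X
  if (control$scale == "minmax") {
    sc <- min_max_scale(X_tr, X_te)
    X_tr <- sc$train
    X_te <- sc$apply
  }
  idx <- which(as.integer(mask) == 1L)
  if (length(idx) == 0L) return(NA_real_)
  1 - knn_error(X_tr, fs_data$y, X_te, unseen$y, idx, control$k)
}

#' Repeated-run benchmark of feature-selection algorithms
#'
#' For every run, an outer split reserves unseen test data that plays no
#' part in feature selection; the algorithms are then run on the
#' remainder with the *same* seed and the *same* split (paired design, so
#' per-run differences isolate the algorithms), and the accuracy of each
#' selected subset is measured on the unseen part with the same KNN
#' configuration. Per-run seeds are `seed + run`.
#'
#' With `outer = "holdout"` the outer split is re-randomized per run;
#' with `outer = "kfold"` a stratified k-fold partition is drawn once and
#' run `r` holds out fold `1 + (r - 1) mod n_folds`.
#'
#' @param dataset A [labeled_dataset()].
#' @param algorithms Subset of `c("mrfl", "sbpso", "vbpso")`.
#' @param runs Number of repeated runs `R >= 1`.
#' @param control An [fs_control()] shared by all algorithms.
#' @param outer `"holdout"` or `"kfold"`.
#' @param n_folds Folds for the k-fold outer protocol.
#' @param outer_fraction Test fraction for the holdout outer protocol.
#' @param seed Base seed.
#' @return An object of class `fs_benchmark`: `runs` (one row per
#'   algorithm x run with accuracy, n_features, fitness, inner error,
#'   truth recall where ground truth exists, seed), `summary` (mean, sd
#'   and a `mean ± sd` cell per algorithm and metric), `traces` (named
#'   list of global-best fitness traces).
#' @export
run_benchmark <- function(dataset, algorithms = c("mrfl", "sbpso"),
                          runs = 20L, control = fs_control(),
                          outer = c("holdout", "kfold"), n_folds = 10L,
                          outer_fraction = 0.2, seed = 1L) {
  outer <- match.arg(outer)
  check_fs_dataset(dataset)
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop("runs must be a positive integer")
  runners <- lapply(algorithms, alg_runner)
  names(runners) <- algorithms
  folds <- NULL
  if (outer == "kfold") {
    set.seed(seed)
    folds <- stratified_kfold(dataset, n_folds)
  }
  truth <- dataset$truth_mask
  rows <- vector("list", runs * length(algorithms))
  traces <- list()
  ri <- 0L
  for (r in seq_len(runs)) {
    run_seed <- seed + r
    if (outer == "holdout") {
      set.seed(run_seed)
      sp <- stratified_holdout(dataset, outer_fraction)
    } else {
      sp <- folds[[1L + (r - 1L) %% length(folds)]]
    }
    for (alg in algorithms) {
      res <- runners[[alg]](sp$train, control, run_seed)
      acc <- outer_accuracy(sp$train, sp$test, res$best_mask, control)
      recall <- if (is.null(truth)) NA_real_ else
        sum(res$best_mask == 1L & truth == 1L) / sum(truth)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(algorithm = alg, run = r, seed = run_seed,
                               accuracy = acc,
                               n_features = res$subset_size,
                               fitness = res$best_fitness,
                               inner_error = res$best_error,
                               truth_recall = recall,
                               stringsAsFactors = FALSE)
      traces[[sprintf("%s_run%d", alg, r)]] <- res$fitness_trace
    }
  }
  runs_df <- do.call(rbind, rows)
  summary_df <- benchmark_summary(runs_df)
  structure(list(runs = runs_df, summary = summary_df, traces = traces,
                 algorithms = algorithms, n_runs = runs, outer = outer,
                 seed = seed, control = control),
            class = "fs_benchmark")
}

benchmark_summary <- function(runs_df) {
  metrics <- c("accuracy", "n_features", "fitness")
  out <- list()
  for (alg in unique(runs_df$algorithm)) {
    sub <- runs_df[runs_df$algorithm == alg, ]
    for (m in metrics) {
      v <- sub[[m]]
      s <- if (length(v) > 1L) stats::sd(v) else 0
      out[[length(out) + 1L]] <- data.frame(
        algorithm = alg, metric = m, mean = mean(v), sd = s,
        cell = sprintf("%.4f ± %.2f", mean(v), s),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.fs_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark: %d run(s) of %s (%s outer protocol, base seed %d)\n",
              x$n_runs, paste(x$algorithms, collapse = ", "), x$outer, x$seed))
  wide <- stats::reshape(x$summary[, c("algorithm", "metric", "cell")],
                         idvar = "algorithm", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Friedman average ranks across datasets
#'
#' Ranks the algorithms within every dataset (rank 1 = best, ties get
#' average ranks) and averages the ranks over datasets, the standard way
#' multi-dataset metaheuristic comparisons are summarized. The companion
#' Friedman chi-square p-value is computed with [stats::friedman.test()]
#' when at least two datasets are available.
#'
#' @param metrics Numeric matrix, datasets in rows, algorithms in
#'   columns; all entries finite.
#' @param lower_better `TRUE` (default) if smaller metric values are
#'   better (fitness, subset size); use `FALSE` for accuracy.
#' @return An object of class `rank_summary`: per-dataset `ranks`,
#'   `average_rank`, the algorithm `order` (best first) and `p_value`.
#' @export
friedman_average_ranks <- function(metrics, lower_better = TRUE) {
  M <- as.matrix(metrics)
  if (!all(is.finite(M))) stop("metric table contains non-finite values")
  if (ncol(M) < 2L) stop("need at least 2 algorithms")
  if (nrow(M) < 1L) stop("need at least 1 dataset")
  if (is.null(colnames(M))) colnames(M) <- paste0("alg", seq_len(ncol(M)))
  S <- if (lower_better) M else -M
  ranks <- t(apply(S, 1, rank))
  if (nrow(M) == 1L) ranks <- matrix(ranks, 1L, ncol(M),
                                     dimnames = list(rownames(M), colnames(M)))
  avg <- colMeans(ranks)
  ord <- colnames(M)[order(avg)]
  p <- if (nrow(M) >= 2L)
    suppressWarnings(stats::friedman.test(S)$p.value)
  else NA_real_
  structure(list(ranks = ranks, average_rank = avg, order = ord,
                 p_value = p),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("Friedman average ranks (1 = best):\n")
  print(round(x$average_rank, 3))
  cat("order:", paste(x$order, collapse = " > "), "\n")
  if (!is.na(x$p_value))
    cat(sprintf("Friedman chi-square p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' Two-sided Wilcoxon signed-rank test for paired results
#'
#' Drops zero differences first. If every difference is zero the result
#' is undefined and `NaN` is returned (the convention used when two
#' algorithms produce identical paired results). P-values above the
#' chosen level (conventionally 0.05) indicate similar performance.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return Two-sided p-value, or `NaN` if all differences are zero.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  keep <- d != 0
  if (!any(keep)) return(NaN)
  if (sum(keep) < 5L)
    warning("fewer than 5 non-zero differences; p-value is unreliable")
  suppressWarnings(stats::wilcox.test(a[keep], b[keep], paired = TRUE)$p.value)
}

#' Export convergence traces and result tables
#'
#' Writes one CSV per (algorithm, run) with columns `iteration` (0 is the
#' initialized swarm) and `gbest_fitness`, plus `runs.csv` (per-run
#' results) and `summary.csv` (aggregates). Re-exporting the same
#' benchmark produces byte-identical files.
#'
#' @param benchmark An `fs_benchmark`.
#' @param path Output directory, created if needed.
#' @return Character vector of written file paths, invisibly.
#' @export
export_traces <- function(benchmark, path) {
  if (!inherits(benchmark, "fs_benchmark")) stop("not an fs_benchmark")
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory ", path)
  files <- character(0)
  for (key in names(benchmark$traces)) {
    tr <- benchmark$traces[[key]]
    f <- file.path(path, sprintf("trace_%s.csv", key))
    utils::write.csv(data.frame(iteration = seq_along(tr) - 1L,
                                gbest_fitness = sprintf("%.17g", tr)),
                     f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f_runs <- file.path(path, "runs.csv")
  utils::write.csv(benchmark$runs, f_runs, row.names = FALSE)
  f_sum <- file.path(path, "summary.csv")
  utils::write.csv(benchmark$summary, f_sum, row.names = FALSE)
  invisible(c(files, f_runs, f_sum))
}
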