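#' Algorithm settings for swarm-based feature selection
#'
#' Bundles every tunable of the optimizer and of the wrapper fitness into a
#' single validated object. The defaults are the configuration used
#' throughout the package's evaluation protocol: a swarm of `N = 20`
#' particles run for `T = 100` iterations, inertia weight decreasing
#' linearly from 0.9 to 0.4, cyclone random-reference constants
#' `c5 = c6 = 2`, fitness weight `omega = 0.99` and a 5-nearest-neighbor
#' wrapper classifier.
#'
#' @param N Population (swarm) size, at least 2.
#' @param T Maximum number of iterations (non-negative; `T = 0` evaluates
#'   only the initial swarm).
#' @param w_max,w_min Upper and lower bound of the linearly decreasing
#'   inertia weight.
#' @param c5,c6 Constant learning factors of the random-reference cyclone
#'   branch (both 2).
#' @param omega Fitness weight \eqn{\omega \in [0, 1]} balancing
#'   classification error against subset size (see [fitness_value()]).
#' @param k Neighbor count of the KNN wrapper classifier.
#' @param v_clamp Symmetric velocity bound; velocities are clipped to
#'   `[-v_clamp, v_clamp]` after every update. `tanh(6)` is within 1e-5 of
#'   1, so the default 6 only removes numerically irrelevant magnitudes.
#' @param branch_threshold Probability of entering the cyclone phase
#'   instead of chain learning on a given particle update (0.5).
#' @param test_fraction Fraction of the data held out inside the fitness
#'   evaluator as the error-measuring split (0.2 gives the 80/20 protocol).
#' @param scale `"minmax"` to min-max scale features using training-split
#'   statistics before computing distances, or `"none"`.
#' @param per_dimension_r If `TRUE` (default) the stochastic factors r1, r2
#'   of every velocity/somersault update are drawn per dimension; if
#'   `FALSE` they are scalar per particle.
#' @param memoize If `TRUE`, fitness values are cached by bitmask so
#'   duplicate masks are evaluated once.
#'
#' @return An object of class `fs_control`.
#' @examples
#' ctrl <- fs_control(T = 10)
#' ctrl$N
#' @export
fs_control <- function(N = 20L, T = 100L, w_max = 0.9, w_min = 0.4,
                       c5 = 2, c6 = 2, omega = 0.99, k = 5L,
                       v_clamp = 6, branch_threshold = 0.5,
                       test_fraction = 0.2, scale = c("minmax", "none"),
                       per_dimension_r = TRUE, memoize = FALSE) {
  scale <- match.arg(scale)
  N <- as.integer(N)
  T <- as.integer(T)
  k <- as.integer(k)
  if (is.na(N) || N < 2L) stop("population size N must be an integer >= 2")
  if (is.na(T) || T < 0L) stop("iteration budget T must be a non-negative integer")
  if (w_min < 0 || w_min > w_max) stop("need 0 <= w_min <= w_max")
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  if (v_clamp <= 0) stop("v_clamp must be positive")
  if (branch_threshold < 0 || branch_threshold > 1)
    stop("branch_threshold must lie in [0, 1]")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  structure(list(N = N, T = T, w_max = w_max, w_min = w_min,
                 c5 = c5, c6 = c6, omega = omega, k = k,
                 v_clamp = v_clamp, branch_threshold = branch_threshold,
                 test_fraction = test_fraction, scale = scale,
                 per_dimension_r = isTRUE(per_dimension_r),
                 memoize = isTRUE(memoize)),
            class = "fs_control")
}

#' @export
print.fs_control <- function(x, ...) {
  cat("Feature-selection control settings\n")
  cat(sprintf("  swarm: N = %d, T = %d, inertia %.2f -> %.2f, v_clamp = %g\n",
              x$N, x$T, x$w_max, x$w_min, x$v_clamp))
  cat(sprintf("  fitness: omega = %g, k = %d, %s split %.0f/%.0f, scaling = %s\n",
              x$omega, x$k, "holdout",
              100 * (1 - x$test_fraction), 100 * x$test_fraction, x$scale))
  cat(sprintf("  cyclone constants c5 = %g, c6 = %g; branch threshold = %g\n",
              x$c5, x$c6, x$branch_threshold))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
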