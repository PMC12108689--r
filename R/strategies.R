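# Velocity/position update rules: chain, cyclone (gbest- and random-reference
# branches), somersault, their coefficient schedules and the two transfer
# functions that map real velocities back to bits.

# Gauss error function via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Linearly decreasing inertia weight
#'
#' @param t Current iteration (0..T).
#' @param T Maximum number of iterations.
#' @param w_max,w_min Inertia bounds (defaults 0.9 and 0.4).
#' @return `w_max - (w_max - w_min) * t / T`; `w_max` when `T = 0`.
#' @examples
#' inertia_weight(50, 100) # 0.65
#' @export
inertia_weight <- function(t, T, w_max = 0.9, w_min = 0.4) {
  if (T == 0) return(w_max)
  if (T < 0 || t < 0 || t > T) stop("need 0 <= t <= T")
  w_max - (w_max - w_min) * t / T
}

#' Chain-learning factors c1 and c2
#'
#' Time-varying learning factors of the chain phase,
#' `c1 = 2 erf(0.5 - t/T)` and `c2 = 3 erf(1.7 - t/T)`. Both decrease
#' strictly with `t`; `c1` changes sign at `t/T = 0.5`, shifting the swarm
#' from exploitation of the chain attractor toward exploration.
#'
#' @inheritParams inertia_weight
#' @return Named numeric vector `c(c1, c2)`.
#' @export
chain_coefficients <- function(t, T) {
  if (T < 1) stop("T must be at least 1")
  c(c1 = 2 * erf(0.5 - t / T), c2 = 3 * erf(1.7 - t / T))
}

#' Cyclone-learning factors c3 and c4
#'
#' The cyclone (gbest-reference) branch swaps the roles of the two chain
#' schedules: `c3 = 3 erf(1.7 - t/T)` weights the chain attractor and
#' `c4 = 2 erf(0.5 - t/T)` weights the global best, so `c3(t) == c2(t)`
#' and `c4(t) == c1(t)` for every `t`.
#'
#' @inheritParams inertia_weight
#' @return Named numeric vector `c(c3, c4)`.
#' @export
cyclone_coefficients <- function(t, T) {
  ch <- chain_coefficients(t, T)
  c(c3 = unname(ch["c2"]), c4 = unname(ch["c1"]))
}

#' One velocity update
#'
#' Shared form of the chain, cyclone and baseline velocity rules:
#' `v' = w v + a r1 (attractor - x) + b r2 (reference - x)`, clipped to
#' `[-v_clamp, v_clamp]`. The caller chooses the coefficient pair
#' `(a, b)`: `(c1, c2)` for chain learning, `(c3, c4)` for the
#' gbest-reference cyclone branch, `(c5, c6) = (2, 2)` for the
#' random-reference cyclone branch, and constant `(2, 2)` with
#' `attractor = pbest_i`, `reference = gbest` for classic binary PSO.
#' In the chain phases the attractor is the personal best of the particle
#' directly in front (the particle's own for the head of the chain).
#'
#' @param x Current position (0/1 vector of length D).
#' @param v Current velocity (length D).
#' @param attractor Cognitive attractor position (length D).
#' @param reference Social reference: the global best mask or a continuous
#'   random reference in `[0, 1]^D`.
#' @param w Inertia weight.
#' @param a,b Learning factors for the attractor and reference terms.
#' @param v_clamp Symmetric velocity bound.
#' @param r1,r2 Stochastic factors in `[0, 1]`, by default fresh
#'   per-dimension uniforms from the current RNG stream.
#' @return The clamped new velocity.
#' @export
velocity_update <- function(x, v, attractor, reference, w, a, b,
                            v_clamp = 6,
                            r1 = stats::runif(length(x)),
                            r2 = stats::runif(length(x))) {
  D <- length(x)
  if (length(v) != D || length(attractor) != D || length(reference) != D)
    stop("position, velocity, attractor and reference must share one length")
  v_new <- w * v + a * r1 * (attractor - x) + b * r2 * (reference - x)
  pmin(pmax(v_new, -v_clamp), v_clamp)
}

#' Random reference position for the exploratory cyclone branch
#'
#' A fresh continuous position drawn uniformly in the search-space box,
#' `lower + u * (upper - lower)` per dimension. For bitmask search the
#' box is the unit hypercube, so the entries are plain uniforms; they are
#' deliberately not rounded to bits because they only enter a velocity
#' difference.
#'
#' @param D Dimension (number of features).
#' @param lower,upper Search-space bounds (defaults 0 and 1).
#' @return Numeric vector of length `D`.
#' @export
random_reference <- function(D, lower = 0, upper = 1) {
  if (D < 1) stop("D must be at least 1")
  lower + stats::runif(D) * (upper - lower)
}

#' V-shaped binarization (bit-flip transfer)
#'
#' Maps a velocity to a flip probability `Tf = tanh(|v|)` and flips the
#' corresponding bit of the current position when a fresh uniform falls
#' below it; otherwise the bit is kept. A zero velocity therefore leaves
#' the position unchanged, which preserves good positions near
#' convergence (unlike the S-shaped rule).
#'
#' @param x Current 0/1 position.
#' @param v New velocity (same length).
#' @param u Uniform draws in `[0, 1]`, one per bit.
#' @return Integer 0/1 vector.
#' @export
binarize_vshape <- function(x, v, u = stats::runif(length(v))) {
  if (length(x) != length(v)) stop("position and velocity lengths differ")
  flip <- u < tanh(abs(v))
  out <- as.integer(x)
  out[flip] <- 1L - out[flip]
  out
}

#' S-shaped binarization (sigmoid transfer)
#'
#' Classic binary-PSO rule: `Tf = 1 / (1 + exp(-v))`; the new bit is 1
#' when a fresh uniform falls below `Tf` and 0 otherwise, independent of
#' the previous position.
#'
#' @param v New velocity.
#' @param u Uniform draws in `[0, 1]`, one per bit.
#' @return Integer 0/1 vector.
#' @export
binarize_sshape <- function(v, u = stats::runif(length(v))) {
  as.integer(u < 1 / (1 + exp(-v)))
}

#' Somersault update around the global best
#'
#' Treats the global best as a pivot: per dimension,
#' `x_new = pbest + 2 r1 (gbest - r2 pbest)` with fresh uniforms r1, r2,
#' thresholded at 0.5 (`> 0.5` maps to 1, otherwise 0; the measure-zero
#' tie at exactly 0.5 maps to 0, biasing toward smaller subsets). When
#' `pbest == gbest` the update is an exact fixed point for any draws.
#'
#' @param pbest Personal best position (0/1 vector).
#' @param gbest Global best position (0/1 vector, same length).
#' @param r1,r2 Uniform draws in `[0, 1]`, one per dimension.
#' @return Integer 0/1 vector, the replacement position.
#' @export
somersault_update <- function(pbest, gbest,
                              r1 = stats::runif(length(pbest)),
                              r2 = stats::runif(length(pbest))) {
  if (length(pbest) != length(gbest)) stop("pbest and gbest lengths differ")
  x_new <- pbest + 2 * r1 * (gbest - r2 * pbest)
  as.integer(x_new > 0.5)
}
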