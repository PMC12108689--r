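# Swarm state, best bookkeeping and the full optimization loop for
# BPSO-MRFL and the classic binary-PSO baselines.

#' Initialize a swarm
#'
#' Positions are iid Bernoulli(0.5) per bit (a bit is 1 iff a uniform
#' draw is below 0.5), velocities are uniform in `[-1, 1]`, personal
#' bests start at the initial positions with fitness `Inf` (undefined
#' until the first evaluation), and the global best is undefined. Draws
#' come from the current RNG stream, particle by particle: first the D
#' position uniforms, then the D velocity uniforms.
#'
#' @param control An [fs_control()].
#' @param D Number of features (dimension), at least 1.
#' @return An object of class `fs_swarm`: position/velocity matrices
#'   (`N x D`), personal bests and global-best slots.
#' @export
init_swarm <- function(control, D) {
  D <- as.integer(D)
  if (is.na(D) || D < 1L) stop("dimension D must be a positive integer")
  N <- control$N
  pos <- matrix(0L, N, D)
  vel <- matrix(0, N, D)
  for (i in seq_len(N)) {
    pos[i, ] <- as.integer(stats::runif(D) < 0.5)
    vel[i, ] <- stats::runif(D, -1, 1)
  }
  structure(list(pos = pos, vel = vel, pbest_pos = pos,
                 pbest_fit = rep(Inf, N), pbest_rec = vector("list", N),
                 gbest_pos = NULL, gbest_fit = Inf, gbest_rec = NULL,
                 t = 0L),
            class = "fs_swarm")
}

#' Update personal and global bests
#'
#' Replaces a particle's personal best only on strict fitness improvement
#' (ties keep the incumbent), then sets the global best to the minimum
#' personal-best fitness over the swarm, ties broken by the lowest
#' particle index. The particle order is fixed at initialization and
#' never re-sorted; it defines the foraging chain.
#'
#' @param swarm An `fs_swarm`.
#' @param records One fitness record per particle for its current
#'   position: a list of `fitness_record`s or a bare numeric vector.
#' @return The updated swarm.
#' @export
update_bests <- function(swarm, records) {
  N <- nrow(swarm$pos)
  D <- ncol(swarm$pos)
  if (is.numeric(records))
    records <- lapply(seq_along(records), function(i)
      fitness_record(records[i], NA_real_, sum(swarm$pos[i, ]), D))
  if (length(records) != N || any(vapply(records, is.null, logical(1))))
    stop("need one fitness record per particle")
  fit <- vapply(records, function(r) r$fitness, numeric(1))
  if (anyNA(fit)) stop("fitness records contain missing values")
  better <- fit < swarm$pbest_fit
  if (any(better)) {
    swarm$pbest_pos[better, ] <- swarm$pos[better, , drop = FALSE]
    swarm$pbest_fit[better] <- fit[better]
    swarm$pbest_rec[better] <- records[better]
  }
  b <- which.min(swarm$pbest_fit)   # ties -> lowest particle index
  swarm$gbest_pos <- swarm$pbest_pos[b, ]
  swarm$gbest_fit <- swarm$pbest_fit[b]
  swarm$gbest_rec <- swarm$pbest_rec[[b]]
  swarm
}

# Coerce a user fitness function's return value to a fitness_record.
as_fitness_record <- function(x, mask, D) {
  if (inherits(x, "fitness_record")) return(x)
  fitness_record(as.numeric(x), NA_real_, sum(mask), D)
}

#' Run a binary swarm optimizer on an arbitrary fitness function
#'
#' The engine behind [run_bpso_mrfl()] and [run_bpso()], exposed so that
#' custom (for example exhaustively enumerable) objectives can be
#' optimized directly. `fitness` maps a 0/1 vector of length `D` to a
#' `fitness_record` or a bare number; lower is better.
#'
#' For `algorithm = "mrfl"` each iteration runs the manta-ray schedule:
#' per particle, a uniform `u1` chooses cyclone learning (`u1 < 0.5`)
#' versus chain learning; inside the cyclone phase a second uniform `u2`
#' selects the exploratory random-reference branch when `t/T < u2` and
#' the gbest-reference branch otherwise; velocities are binarized with
#' the V-shaped rule; after evaluating and updating the bests, every
#' particle somersaults around the global best and the swarm is evaluated
#' again. That costs `2N` evaluations per iteration (`N` at
#' initialization). The baselines (`"sbpso"`, `"vbpso"`) use the classic
#' global-best velocity rule with constant learning factors 2 and the
#' S- or V-shaped transfer function, `N` evaluations per iteration, and
#' no somersault phase.
#'
#' @param fitness Function of one 0/1 vector.
#' @param D Dimension.
#' @param control An [fs_control()].
#' @param algorithm `"mrfl"`, `"sbpso"` or `"vbpso"`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return An object of class `fs_result` (see [run_bpso_mrfl()]).
#' @export
optimize_swarm <- function(fitness, D, control = fs_control(),
                           algorithm = c("mrfl", "sbpso", "vbpso"),
                           seed = NULL) {
  algorithm <- match.arg(algorithm)
  if (!is.null(seed)) set.seed(seed)
  D <- as.integer(D)
  N <- control$N
  T_max <- control$T
  evals <- 0L
  memo <- if (control$memoize) new.env(parent = emptyenv()) else NULL
  eval_mask <- function(mask) {
    if (!is.null(memo)) {
      key <- paste(mask, collapse = "")
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
    }
    evals <<- evals + 1L
    rec <- as_fitness_record(fitness(mask), mask, D)
    if (!is.null(memo)) memo[[key]] <- rec
    rec
  }
  eval_all <- function(sw)
    lapply(seq_len(N), function(i) eval_mask(sw$pos[i, ]))

  rpair <- function() {
    if (control$per_dimension_r)
      list(stats::runif(D), stats::runif(D))
    else {
      s <- stats::runif(2)
      list(rep(s[1], D), rep(s[2], D))
    }
  }

  sw <- init_swarm(control, D)
  sw <- update_bests(sw, eval_all(sw))
  trace <- numeric(T_max + 1L)
  trace[1L] <- sw$gbest_fit

  for (t in seq_len(T_max)) {
    w <- inertia_weight(t, T_max, control$w_max, control$w_min)
    ch <- chain_coefficients(t, T_max)
    cy <- cyclone_coefficients(t, T_max)
    for (i in seq_len(N)) {
      if (algorithm == "mrfl") {
        attractor <- if (i == 1L) sw$pbest_pos[1L, ] else sw$pbest_pos[i - 1L, ]
        u1 <- stats::runif(1)
        if (u1 < control$branch_threshold) {      # cyclone phase
          u2 <- stats::runif(1)
          if (t / T_max < u2) {                   # exploratory branch
            a <- control$c5; b <- control$c6
            ref <- random_reference(D)
          } else {                                # gbest-reference branch
            a <- cy[["c3"]]; b <- cy[["c4"]]
            ref <- sw$gbest_pos
          }
        } else {                                  # chain learning
          a <- ch[["c1"]]; b <- ch[["c2"]]
          ref <- sw$gbest_pos
        }
      } else {                                    # classic global-best BPSO
        attractor <- sw$pbest_pos[i, ]
        a <- 2; b <- 2
        ref <- sw$gbest_pos
      }
      r <- rpair()
      v <- velocity_update(sw$pos[i, ], sw$vel[i, ], attractor, ref,
                           w, a, b, control$v_clamp, r[[1]], r[[2]])
      sw$vel[i, ] <- v
      sw$pos[i, ] <- if (algorithm == "sbpso") binarize_sshape(v)
                     else binarize_vshape(sw$pos[i, ], v)
    }
    sw <- update_bests(sw, eval_all(sw))
    if (algorithm == "mrfl") {
      for (i in seq_len(N)) {
        r <- rpair()
        sw$pos[i, ] <- somersault_update(sw$pbest_pos[i, ], sw$gbest_pos,
                                         r[[1]], r[[2]])
      }
      sw <- update_bests(sw, eval_all(sw))
    }
    trace[t + 1L] <- sw$gbest_fit
    sw$t <- t
  }

  rec <- sw$gbest_rec
  structure(list(best_mask = sw$gbest_pos,
                 selected = which(sw$gbest_pos == 1L),
                 best_fitness = sw$gbest_fit,
                 best_error = rec$error,
                 subset_size = rec$subset_size,
                 fitness_trace = trace,
                 evaluations_used = evals,
                 algorithm = algorithm,
                 seed = seed,
                 control = control),
            class = "fs_result")
}

check_fs_dataset <- function(dataset) {
  if (!inherits(dataset, "labeled_dataset"))
    stop("dataset must be a labeled_dataset")
  if (ncol(dataset$X) < 1L) stop("dataset has no features")
  tab <- table(dataset$y)
  if (length(tab) < 2L) stop("dataset has a single class")
  if (any(tab < 2L)) stop("every class needs at least 2 samples")
  invisible(dataset)
}

#' Feature selection with BPSO-MRFL
#'
#' Runs binary particle swarm optimization with the three manta-ray
#' foraging learning strategies (chain, cyclone, somersault) on the given
#' dataset, minimizing the wrapper fitness
#' `omega * E + (1 - omega) * d / D` where `E` is the KNN error on a
#' stratified holdout split frozen at the start of the run.
#'
#' All randomness (the fitness split, swarm initialization, every branch
#' and update draw) comes from one stream seeded with `seed`, so a run is
#' exactly reproducible.
#'
#' @param dataset A [labeled_dataset()] with at least 2 classes and 2
#'   samples per class.
#' @param control An [fs_control()].
#' @param seed Integer RNG seed.
#' @return An object of class `fs_result` with elements `best_mask`
#'   (0/1), `selected` (1-based indices), `best_fitness`, `best_error`,
#'   `subset_size`, `fitness_trace` (global-best fitness after
#'   initialization and after each iteration, length `T + 1`, always
#'   non-increasing), `evaluations_used` (`N + 2NT` without memoization),
#'   `algorithm`, `seed`, `control`.
#' @examples
#' ds <- synthesize_dataset(synthetic_spec(n = 40, n_classes = 2,
#'   n_informative = 3, n_redundant = 2, n_noise = 15))
#' res <- run_bpso_mrfl(ds, fs_control(N = 5, T = 5), seed = 1)
#' res$subset_size
#' @export
run_bpso_mrfl <- function(dataset, control = fs_control(), seed = 1L) {
  check_fs_dataset(dataset)
  set.seed(seed)
  fe <- make_fitness(dataset, control)
  res <- optimize_swarm(fe$fn, fe$D, control, algorithm = "mrfl")
  res$seed <- seed
  res
}

#' Baseline binary PSO (S-shaped or V-shaped transfer)
#'
#' Classic global-best binary PSO with constant learning factors
#' `c1 = c2 = 2` and the same linearly decreasing inertia weight as
#' [run_bpso_mrfl()], binarizing velocities with either the sigmoid
#' (`"sshape"`) or the tanh bit-flip (`"vshape"`) transfer function.
#' Costs `N` fitness evaluations per iteration.
#'
#' @inheritParams run_bpso_mrfl
#' @param variant `"sshape"` or `"vshape"`.
#' @return An `fs_result`, as for [run_bpso_mrfl()] but with
#'   `evaluations_used = N + NT`.
#' @export
run_bpso <- function(dataset, variant = c("sshape", "vshape"),
                     control = fs_control(), seed = 1L) {
  variant <- match.arg(variant)
  check_fs_dataset(dataset)
  set.seed(seed)
  fe <- make_fitness(dataset, control)
  res <- optimize_swarm(fe$fn, fe$D, control,
                        algorithm = if (variant == "sshape") "sbpso" else "vbpso")
  res$seed <- seed
  res
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("%s run (seed %s): fitness %.6f, error %s, %d features selected\n",
              x$algorithm, format(x$seed), x$best_fitness,
              if (is.na(x$best_error)) "NA" else sprintf("%.4f", x$best_error),
              x$subset_size))
  cat(sprintf("  %d fitness evaluations over %d iterations\n",
              x$evaluations_used, length(x$fitness_trace) - 1L))
  invisible(x)
}
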