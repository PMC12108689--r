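# Swarm state, best bookkeeping and the optimization loop.

test_that("initialization follows the documented draw rules", {
  ctrl <- fs_control(N = 3)
  # replay the stream by hand: bit = 1 iff u < 0.5, then velocity in [-1, 1]
  set.seed(21)
  manual_pos <- matrix(0L, 3, 4)
  manual_vel <- matrix(0, 3, 4)
  for (i in 1:3) {
    manual_pos[i, ] <- as.integer(runif(4) < 0.5)
    manual_vel[i, ] <- runif(4, -1, 1)
  }
  set.seed(21)
  sw <- init_swarm(ctrl, 4)
  expect_identical(sw$pos, manual_pos)
  expect_equal(sw$vel, manual_vel)
  expect_true(all(sw$vel >= -1 & sw$vel <= 1))
  expect_identical(sw$pbest_pos, sw$pos)
  expect_identical(sw$gbest_fit, Inf) # undefined until first evaluation
  expect_error(init_swarm(ctrl, 0), "positive")
  expect_error(fs_control(N = 1), ">= 2")
})

test_that("personal bests improve strictly; global best takes the lowest index", {
  set.seed(22)
  sw <- init_swarm(fs_control(N = 3), 5)
  sw <- update_bests(sw, c(0.5, 0.4, 0.9))
  expect_equal(sw$pbest_fit, c(0.5, 0.4, 0.9))
  expect_equal(sw$gbest_fit, 0.4)
  # strict improvement replaces; an equal fitness does not
  sw$pos[1, ] <- 1L - sw$pos[1, ]
  old_p2 <- sw$pbest_pos[2, ]
  sw <- update_bests(sw, c(0.3, 0.4, 0.9))
  expect_equal(sw$pbest_fit[1], 0.3)
  expect_identical(sw$pbest_pos[1, ], sw$pos[1, ])
  expect_identical(sw$pbest_pos[2, ], old_p2)
  # gbest is the minimum pbest, ties broken by the lowest particle index
  sw2 <- init_swarm(fs_control(N = 3), 5)
  sw2 <- update_bests(sw2, c(0.4, 0.2, 0.9))
  expect_equal(sw2$gbest_fit, 0.2)
  expect_identical(sw2$gbest_pos, sw2$pbest_pos[2, ])
  sw3 <- init_swarm(fs_control(N = 3), 5)
  sw3 <- update_bests(sw3, c(0.2, 0.2, 0.9))
  expect_identical(sw3$gbest_pos, sw3$pbest_pos[1, ])
  expect_error(update_bests(sw3, c(0.1, 0.2)), "one fitness record per")
})

test_that("a zero-iteration budget returns the best of the initial swarm", {
  ds <- small_synthetic()
  ctrl <- fs_control(N = 5, T = 0)
  res <- run_bpso_mrfl(ds, ctrl, seed = 1)
  expect_length(res$fitness_trace, 1)
  expect_identical(res$evaluations_used, 5L)
  # reproduce by hand: evaluate the same 5 initial masks
  set.seed(1)
  fe <- make_fitness(ds, ctrl)
  sw <- init_swarm(ctrl, fe$D)
  fits <- sapply(1:5, function(i) fe$fn(sw$pos[i, ])$fitness)
  expect_equal(res$best_fitness, min(fits))
})

test_that("traces are non-increasing and evaluation counts are exact", {
  ds <- small_synthetic()
  ctrl <- fs_control(N = 6, T = 15)
  for (s in 1:5) {
    res <- run_bpso_mrfl(ds, ctrl, seed = s)
    expect_true(all(diff(res$fitness_trace) <= 0))
    expect_length(res$fitness_trace, 16)
    expect_identical(res$evaluations_used, 6L + 2L * 6L * 15L)
    expect_identical(res$subset_size, sum(res$best_mask))
    expect_identical(res$selected, which(res$best_mask == 1L))
  }
  for (variant in c("sshape", "vshape")) {
    res <- run_bpso(ds, variant, ctrl, seed = 1)
    expect_true(all(diff(res$fitness_trace) <= 0))
    expect_identical(res$evaluations_used, 6L + 6L * 15L) # no somersault phase
  }
})

test_that("runs are exactly reproducible for a given seed", {
  ds <- small_synthetic()
  ctrl <- fs_control(N = 5, T = 10)
  a <- run_bpso_mrfl(ds, ctrl, seed = 77)
  b <- run_bpso_mrfl(ds, ctrl, seed = 77)
  expect_identical(a$best_mask, b$best_mask)
  expect_identical(a$fitness_trace, b$fitness_trace)
})

test_that("memoization never changes the result, only the evaluation count", {
  ds <- small_synthetic()
  plain <- run_bpso_mrfl(ds, fs_control(N = 5, T = 10), seed = 3)
  memo <- run_bpso_mrfl(ds, fs_control(N = 5, T = 10, memoize = TRUE), seed = 3)
  expect_identical(memo$best_mask, plain$best_mask)
  expect_identical(memo$fitness_trace, plain$fitness_trace)
  expect_lte(memo$evaluations_used, plain$evaluations_used)
})

test_that("the swarm finds the enumerated optimum on a tiny problem", {
  # 5 features, one of which separates the classes perfectly
  ds <- perfect_feature_dataset(n = 40, D = 5, seed = 30)
  ctrl <- fs_control()
  fe <- make_fitness(ds, ctrl, seed = 30)
  masks <- as.matrix(expand.grid(rep(list(0:1), 5)))[-1, ]
  f_all <- apply(masks, 1, function(m) fe$fn(as.integer(m))$fitness)
  f_opt <- min(f_all)
  res <- optimize_swarm(fe$fn, 5, fs_control(N = 20, T = 50), "mrfl", seed = 1)
  expect_equal(res$best_fitness, f_opt, tolerance = 1e-12)
  # the optimizer can never beat exhaustive enumeration
  expect_gte(res$best_fitness, f_opt - 1e-12)
})

test_that("degenerate datasets are rejected", {
  X <- matrix(rnorm(20), 4, 5)
  expect_error(labeled_dataset(X, rep("a", 4)), "2 distinct")
  ds_bad <- labeled_dataset(rbind(X, X[1, , drop = FALSE]),
                            c("a", "a", "a", "a", "b"))
  expect_error(run_bpso_mrfl(ds_bad), "at least 2 samples")
})
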