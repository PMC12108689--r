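# Fixtures are generated in code; nothing is stored on disk.

# Two well-separated classes carried entirely by feature 1; the remaining
# D-1 columns are standard-normal noise.
perfect_feature_dataset <- function(n = 50, D = 100, seed = 42) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * D), n, D)
  X[, 1] <- ifelse(y == "a", 0, 10) + rnorm(n, 0, 0.1)
  labeled_dataset(X, y)
}

# Small synthetic dataset for fast optimizer tests.
small_synthetic <- function(seed = 1, n_noise = 15)
  synthesize_dataset(synthetic_spec(n = 40, n_classes = 2, n_informative = 3,
                                    n_redundant = 2, n_noise = n_noise,
                                    delta = 3),
                     seed = seed)

# The package's reference recovery benchmark conditions.
reference_synthetic <- function(seed = 1)
  synthesize_dataset(synthetic_spec(), seed = seed)

mask_of <- function(idx, D) {
  m <- integer(D)
  m[idx] <- 1L
  m
}
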