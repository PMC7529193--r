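# Independent oracles and small utilities shared across tests.

# Exhaustive 2^n enumeration of the success-count pmf: the brute-force
# counterpart to the dynamic-programming convolution.
brute_force_count_pmf <- function(thetas) {
  n <- length(thetas)
  pmf <- numeric(n + 1)
  grid <- expand.grid(rep(list(0:1), n))
  for (r in seq_len(nrow(grid))) {
    z <- as.numeric(grid[r, ])
    w <- prod(ifelse(z == 1, thetas, 1 - thetas))
    k <- sum(z)
    pmf[k + 1] <- pmf[k + 1] + w
  }
  pmf
}

# Batch-means Monte-Carlo standard error for correlated MCMC draws.
batch_se <- function(x, n_batch = 30) {
  b <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch), function(i)
    mean(x[((i - 1) * b + 1):(i * b)]), 0)
  stats::sd(means) / sqrt(n_batch)
}

# Per-record confidences of the rho3 protocol in the fixed bird example:
# 23 definitive females, 19 definitive males, 8 partial assessments.
bird_rho3_thetas <- function() {
  c(rep(1, 23), rep(0, 19), 0.9, 0.9, 0.8, 0.8, 0.7, 0.4, 0.3, 0.2)
}
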