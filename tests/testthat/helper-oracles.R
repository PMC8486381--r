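# Independent oracles and small constructors shared across tests.

# Brute-force Yen threshold: evaluates the maximum-correlation criterion at
# every histogram level directly from its definition, with plain loops and
# sums. Independent of the package's vectorized implementation.
yen_bruteforce <- function(x, n_bins = 256L) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / n_bins
  b <- pmin(n_bins - 1L, floor((x - lo) / w))
  h <- tabulate(b + 1L, nbins = n_bins)
  p <- h / sum(h)
  vals <- numeric(n_bins)
  for (t in seq_len(n_bins)) {
    P1 <- sum(p[1:t])
    P2 <- sum(p[1:t]^2)
    P2c <- sum(p[-(1:t)]^2)
    val <- 0
    if (P2 * P2c > 0) val <- val - log(P2 * P2c)
    if (P1 * (1 - P1) > 0) val <- val + 2 * log(P1 * (1 - P1))
    vals[t] <- val
  }
  # same documented tie rule: within tolerance, the lower level wins
  best_t <- which(vals >= max(vals) - 1e-10)[1L]
  lo + best_t * w
}

# rasterized filled disk mask
disk_mask <- function(n, centre, radius) {
  outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2, "+") <= radius^2
}

# place k well-separated small squares in an n x n mask
squares_mask <- function(n, k, size = 3L, step = 12L, offset = 3L) {
  m <- matrix(FALSE, n, n)
  per_row <- max(1L, (n - offset) %/% step)
  for (i in seq_len(k)) {
    r <- offset + step * ((i - 1L) %/% per_row)
    c <- offset + step * ((i - 1L) %% per_row)
    m[r:(r + size - 1L), c:(c + size - 1L)] <- TRUE
  }
  m
}

# random two-mode test image (intensities in 0..255), deterministic per seed
two_mode_image <- function(seed, n = 48L) {
  set.seed(seed)
  lvl <- sample(0:255, 2)
  x <- matrix(sample(lvl, n * n, replace = TRUE, prob = c(0.6, 0.4)), n, n)
  x + matrix(sample(0:20, n * n, replace = TRUE), n, n)
}
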