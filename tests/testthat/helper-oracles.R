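# Independent oracles, deliberately written as naive scalar loops so they
# share no code path with the implementation they check.

# Penalty as an explicit ordered-pair sum: 1/2 sum_ij W_ij (z_i - z_j)^2 per
# sample, averaged over samples.
pairwise_penalty_oracle <- function(z, w) {
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  n <- ncol(z)
  total <- 0
  for (s in seq_len(nrow(z))) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) acc <- acc + w[i, j] * (z[s, i] - z[s, j])^2
      }
    }
    total <- total + acc / 2
  }
  total / nrow(z)
}

# Adaptive Gaussian kernel entry by entry, scalar arithmetic only.
kernel_oracle <- function(x, k, floor_ = 1e-8) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    others <- sort(d[i, setdiff(seq_len(n), i)])
    sigma[i] <- max(others[k], floor_)
  }
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        w[i, j] <- 0.5 * exp(-d[i, j]^2 / (2 * sigma[i]^2)) +
          0.5 * exp(-d[i, j]^2 / (2 * sigma[j]^2))
      }
    }
  }
  w
}

# Connected components by union-find over thresholded edges.
union_find_components <- function(w, threshold) {
  n <- nrow(w)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && w[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # relabel contiguously in order of first appearance
  as.integer(factor(roots, levels = unique(roots))) - 1L
}

random_symmetric_weights <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- sample(up, size = max(1L, round(density * length(up))))
  w[on] <- runif(length(on))
  w + t(w)
}
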