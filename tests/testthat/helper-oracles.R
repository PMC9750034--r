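# Independent oracles used to cross-check the package implementations.
# Deliberately written as plain loops with no shared code paths.

# Textbook two-class ReliefF: exhaustive pairwise Manhattan distances on
# range-normalised features, k nearest hits/misses per instance.
brute_force_relieff <- function(x, y, k) {
  rng <- apply(x, 2, function(col) max(col) - min(col))
  m <- nrow(x)
  p <- ncol(x)
  norm_diff <- function(f, a, b) {
    if (rng[f] == 0) return(0)
    abs(x[a, f] - x[b, f]) / rng[f]
  }
  manhattan <- function(a, b) {
    s <- 0
    for (f in seq_len(p)) s <- s + norm_diff(f, a, b)
    s
  }
  w <- rep(0, p)
  for (i in seq_len(m)) {
    d <- rep(Inf, m)
    for (j in seq_len(m)) if (j != i) d[j] <- manhattan(i, j)
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d[same], same)][1:k]
    misses <- other[order(d[other], other)][1:k]
    for (f in seq_len(p)) {
      for (h in hits) w[f] <- w[f] - norm_diff(f, i, h) / (m * k)
      for (mi in misses) w[f] <- w[f] + norm_diff(f, i, mi) / (m * k)
    }
  }
  names(w) <- colnames(x)
  w
}

# Two-class toy dataset: feature 1 separates "smiling" from "rest" by `sep`,
# the rest are pure noise.
make_dv_matrix <- function(n_per_class, p = 3, sep = 1, noise = 0.3,
                           seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n_per_class * p, sd = noise),
              nrow = 2 * n_per_class)
  colnames(x) <- paste0("f", seq_len(p))
  y <- rep(c("smiling", "rest"), each = n_per_class)
  x[y == "smiling", 1] <- x[y == "smiling", 1] + sep
  list(x = x, label = y)
}
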