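# Independent brute-force oracles used across the suite. These deliberately
# use scalar loops / power iteration so they share no code path with the
# package implementations they check.

# Pearson correlation by direct summation of the defining formula.
pearson_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- m[i, ]; xj <- m[j, ]
      num <- sum((xi - mean(xi)) * (xj - mean(xj)))
      den <- sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      out[i, j] <- num / den
    }
  }
  out
}

# Node strength by scalar loop.
strength_oracle <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) if (j != i) out[i] <- out[i] + W[i, j]
  }
  out
}

# Weighted clustering coefficient by triple loop over ordered pairs.
clustering_oracle <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        num <- num + W[i, j] * W[j, k] * W[k, i]
      }
    }
    l <- sum(W[i, -i])
    out[i] <- if (l * (l - 1) > 0) num / (l * (l - 1)) else 0
  }
  out
}

# Leading eigenpair by power iteration (nonnegative W).
power_iteration_oracle <- function(W, iters = 50000, tol = 1e-14) {
  v <- rep(1, nrow(W)) / sqrt(nrow(W))
  lam <- 0
  for (k in seq_len(iters)) {
    w <- W %*% v
    lam_new <- sqrt(sum(w^2))
    w <- w / lam_new
    if (max(abs(w - v)) < tol) { v <- w; lam <- lam_new; break }
    v <- w; lam <- lam_new
  }
  if (sum(v) < 0) v <- -v
  list(theta = as.numeric(v), lambda = lam)
}

# Two-sample pooled-variance t by the textbook formula.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Two-sample KS D by brute-force ECDF sweep over all pooled points.
ks_d_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Random symmetric nonnegative weight matrix with zero diagonal.
random_weight_matrix <- function(n, max_w = 1) {
  W <- matrix(runif(n * n, 0, max_w), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# Random symmetric "connectivity-like" matrix: unit diagonal, entries in
# (-1, 1), built from a random data cloud so it is a true correlation.
random_connectivity <- function(n, n_obs = 4 * n, id = "subject") {
  X <- matrix(rnorm(n_obs * n), n_obs, n)
  connectivity_matrix(stats::cor(X), subject_id = id)
}

# Small toy cohorts of connectivity-like matrices with a per-subject edge
# table Y so edge-level effects can be planted exactly.
toy_matrices_from_edges <- function(Y, n_nodes) {
  # Y: subjects x n_nodes(n_nodes-1)/2 rows of edge values in (i<j) order
  pairs <- rsfcnet:::upper_pairs(n_nodes)
  lapply(seq_len(nrow(Y)), function(s) {
    m <- diag(n_nodes)
    m[cbind(pairs[, 1], pairs[, 2])] <- Y[s, ]
    m[cbind(pairs[, 2], pairs[, 1])] <- Y[s, ]
    connectivity_matrix(m, subject_id = sprintf("s%02d", s))
  })
}

small_cohort_spec <- function(seed = 11, delta = 0.5, jitter_df = 500) {
  cohort_spec(
    n_regions = 24, n_timepoints = 80, n_control = 10, n_patient = 9,
    effect_blocks = list(
      list(nodes = 4:8, direction = "hypo", delta = delta),
      list(nodes = 15:18, direction = "hyper", delta = delta)
    ),
    jitter_df = jitter_df, seed = seed
  )
}
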