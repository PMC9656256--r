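#' Turn a connectivity matrix into a nonnegative weight matrix
#'
#' The diagonal is always zeroed. Modes: `"absolute"` takes `|r_ij|`
#' (default; the triangle products in the clustering coefficient and the
#' Perron-Frobenius argument behind eigenvector centrality presuppose
#' nonnegative weights), `"positive_only"` zeroes negative correlations,
#' `"raw"` leaves off-diagonal entries untouched (for sensitivity
#' analyses only).
#'
#' @param R a [connectivity_matrix()] or plain symmetric matrix.
#' @param policy weight policy mode.
#' @return numeric weight matrix with zero diagonal and a `weight_policy`
#'   attribute.
#' @export
apply_weight_policy <- function(R, policy = c("absolute", "positive_only", "raw")) {
  policy <- match.arg(policy)
  W <- unclass(R)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  W <- switch(policy,
    absolute = abs(W),
    positive_only = pmax(W, 0),
    raw = W
  )
  diag(W) <- 0
  attr(W, "weight_policy") <- policy
  attr(W, "subject_id") <- attr(R, "subject_id")
  W
}

#' Node strength
#'
#' Strength of node i is the sum of its edge weights,
#' Ns_i = sum_j w_ij (the zeroed diagonal excludes the self-correlation).
#'
#' @param W square symmetric weight matrix (zero diagonal).
#' @return numeric vector of strengths, one per node.
#' @export
node_strength <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  rowSums(W) - diag(W)  # robust even if a caller passes a nonzero diagonal
}

#' Eigenvector centrality of a weighted undirected graph
#'
#' The centrality vector is the unit-norm eigenvector v of the weight
#' matrix associated with its largest eigenvalue lambda, so that
#' theta_i = (1 / lambda) * sum_j w_ij v_j. The global sign is fixed so
#' that the entries sum to a nonnegative value; for nonnegative W the
#' Perron-Frobenius theorem then makes every entry nonnegative. A leading
#' eigenvalue that is (numerically) degenerate, or an all-zero matrix,
#' raises an error rather than silently picking a direction.
#'
#' @param W square symmetric weight matrix.
#' @param tol relative tolerance for declaring the leading eigenvalue
#'   degenerate.
#' @return list with `theta` (unit-norm vector) and `lambda`.
#' @export
eigenvector_centrality <- function(W, tol = 1e-10) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W)) == 0) stop("eigenvector centrality undefined for the zero matrix",
                             call. = FALSE)
  e <- eigen(W, symmetric = TRUE)
  vals <- e$values
  lead <- which.max(vals)
  scale <- max(abs(vals))
  if (sum(vals > vals[lead] - tol * scale) > 1L) {
    stop("leading eigenvalue is degenerate (multiplicity > 1 within tolerance)",
         call. = FALSE)
  }
  theta <- e$vectors[, lead]
  if (sum(theta) < 0) theta <- -theta
  theta <- theta / sqrt(sum(theta^2))
  list(theta = theta, lambda = vals[lead])
}

#' Weighted clustering coefficient
#'
#' For node i with total connection weight l_i = sum_j w_ij, the local
#' clustering coefficient is
#'   C_i = [ sum over ordered pairs (j, k), j != k, both != i,
#'           of w_ij * w_jk * w_ki ] / ( l_i * (l_i - 1) ).
#' The numerator is the weighted count of closed triples through i (equal
#' to the i-th diagonal entry of W^3 when the diagonal of W is zero).
#' Nodes whose denominator is non-positive (l_i <= 1) get C_i = 0.
#' Negative weights make the triple products meaningless, so they raise an
#' error; use [apply_weight_policy()] first.
#'
#' @param W square symmetric nonnegative weight matrix (zero diagonal).
#' @return numeric vector of clustering coefficients.
#' @export
clustering_coefficient <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (min(W) < 0) {
    stop("clustering coefficient requires nonnegative weights; apply a weight policy",
         call. = FALSE)
  }
  Wd <- W
  diag(Wd) <- 0
  num <- diag(Wd %*% Wd %*% Wd)
  l <- rowSums(Wd)
  den <- l * (l - 1)
  out <- ifelse(den > 0, num / den, 0)
  as.numeric(out)
}

#' Network mean of a node measure
#'
#' Arithmetic mean over nodes; the network-wide summary reported for each
#' of the three node measures.
#'
#' @param values numeric vector of per-node values.
#' @return scalar mean.
#' @export
network_mean <- function(values) {
  if (length(values) == 0L) stop("empty measure vector", call. = FALSE)
  mean(values)
}

#' All three node measures for one subject
#'
#' Convenience wrapper: applies the weight policy, then computes clustering
#' coefficient, eigenvector centrality and node strength, plus their
#' network means.
#'
#' @param R a [connectivity_matrix()].
#' @param policy weight policy (see [apply_weight_policy()]).
#' @return object of class `node_measures`: list with `clustering`,
#'   `centrality`, `lambda`, `strength`, `means` (named vector), `policy`,
#'   `subject_id`.
#' @export
node_measures <- function(R, policy = "absolute") {
  W <- apply_weight_policy(R, policy)
  cc <- clustering_coefficient(W)
  ec <- eigenvector_centrality(W)
  ns <- node_strength(W)
  structure(list(
    subject_id = attr(R, "subject_id") %||% "subject",
    clustering = cc,
    centrality = ec$theta,
    lambda = ec$lambda,
    strength = ns,
    means = c(clustering = network_mean(cc),
              centrality = network_mean(ec$theta),
              strength = network_mean(ns)),
    policy = policy
  ), class = "node_measures")
}

#' Per-subject measure matrix for a cohort
#'
#' Stacks one node measure across subjects into a subjects x nodes matrix,
#' aligned to atlas order -- the input format of the cluster permutation
#' test and of the node-measure feature variants.
#'
#' @param measure_sets list of [node_measures()] objects.
#' @param which one of `"clustering"`, `"centrality"`, `"strength"`.
#' @return numeric matrix, subjects x nodes, rownames = subject ids.
#' @export
measure_matrix <- function(measure_sets, which = c("clustering", "centrality", "strength")) {
  which <- match.arg(which)
  out <- do.call(rbind, lapply(measure_sets, `[[`, which))
  rownames(out) <- vapply(measure_sets, `[[`, "", "subject_id")
  out
}
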