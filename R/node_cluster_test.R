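# Per-node two-sample pooled t for a subjects x nodes measure matrix.
# Positive t = higher in controls.
node_t_stats <- function(M, is_control) {
  n1 <- sum(is_control); n0 <- sum(!is_control); n <- n1 + n0
  m1 <- colMeans(M[is_control, , drop = FALSE])
  m0 <- colMeans(M[!is_control, , drop = FALSE])
  ssw <- colSums(M * M) - n1 * m1^2 - n0 * m0^2
  se <- sqrt(pmax(ssw, 0) / (n - 2) * (1 / n1 + 1 / n0))
  tt <- (m1 - m0) / se
  tt[se == 0] <- 0
  tt
}

# Segment supra-threshold nodes into maximal sign-homogeneous contiguous
# runs under the atlas ordering; returns list of integer index vectors with
# attached sign and mass.
segment_clusters <- function(t_vec, t_crit) {
  state <- integer(length(t_vec))                # -1, 0, +1
  state[t_vec > t_crit] <- 1L
  state[t_vec < -t_crit] <- -1L
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    structure(idx, sign = r$values[k], mass = sum(t_vec[idx]))
  })
}

# Max |cluster mass| for one t vector (0 when nothing is supra-threshold).
max_cluster_mass <- function(t_vec, t_crit) {
  cl <- segment_clusters(t_vec, t_crit)
  if (length(cl) == 0L) return(0)
  max(vapply(cl, function(x) abs(attr(x, "mass")), 0))
}

#' Cluster-based permutation test over anatomically ordered nodes
#'
#' Tests group differences in the spatial distribution of a node measure.
#' Procedure: (1) a per-node two-sample pooled t (positive = higher in
#' controls); (2) nodes with `|t|` above the two-sided critical value at
#' `forming_alpha` are segmented into maximal sign-homogeneous contiguous
#' runs under the atlas-index ordering -- "anatomical neighborhood" means
#' adjacency of consecutive atlas indices; (3) each run's mass is the sum
#' of its member t-statistics; (4) the null distribution is the maximum
#' `|mass|` over `n_perm` seeded group-label permutations (pooled over
#' both signs, so family-wise error is controlled jointly); (5) each
#' observed cluster gets `p = (1 + #, null >= |mass|) / (1 + n_perm)`.
#'
#' @param measures numeric matrix, subjects x nodes, columns in atlas
#'   order (see [measure_matrix()]).
#' @param groups character vector of `"control"`/`"depression"` labels.
#' @param forming_alpha two-sided cluster-forming threshold (default 0.05).
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param region_labels optional node labels (atlas order).
#' @param measure_name recorded in the result.
#' @return object of class `node_cluster_result`: `clusters` data.frame
#'   (cluster, sign, start, end, size, mass, p), `members` data.frame
#'   (cluster, node, label, t), per-node `t`, and parameters.
#' @export
cluster_permutation_test <- function(measures, groups, forming_alpha = 0.05,
                                     n_perm = 10000L, seed = 1L,
                                     region_labels = NULL,
                                     measure_name = "measure") {
  stopifnot(is.matrix(measures))
  groups <- as.character(groups)
  if (nrow(measures) != length(groups)) {
    stop("measure matrix rows must align with group labels", call. = FALSE)
  }
  if (length(unique(groups)) < 2L || min(table(groups)) < 2L) {
    stop("need at least 2 subjects in each of two groups", call. = FALSE)
  }
  check_scalar(forming_alpha, "forming_alpha", lo = 1e-12, hi = 1 - 1e-12)
  check_scalar(n_perm, "n_perm", lo = 1, integerish = TRUE)
  region_labels <- region_labels %||% colnames(measures) %||%
    default_region_labels(ncol(measures))

  is_control <- groups == "control"
  n <- length(groups); n1 <- sum(is_control)
  t_crit <- stats::qt(1 - forming_alpha / 2, df = n - 2)
  t_obs <- node_t_stats(measures, is_control)
  obs_clusters <- segment_clusters(t_obs, t_crit)

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm_control <- logical(n)
      perm_control[sample.int(n, n1)] <- TRUE
      max_cluster_mass(node_t_stats(measures, perm_control), t_crit)
    }, 0)
  })

  if (length(obs_clusters) == 0L) {
    clusters <- data.frame(cluster = integer(0), sign = character(0),
                           start = integer(0), end = integer(0),
                           size = integer(0), mass = numeric(0), p = numeric(0),
                           stringsAsFactors = FALSE)
    members <- data.frame(cluster = integer(0), node = integer(0),
                          label = character(0), t = numeric(0),
                          stringsAsFactors = FALSE)
  } else {
    mass <- vapply(obs_clusters, function(x) attr(x, "mass"), 0)
    sgn <- vapply(obs_clusters, function(x) attr(x, "sign"), 0L)
    pvals <- vapply(abs(mass), function(m) (1 + sum(null_max >= m)) / (1 + n_perm), 0)
    ord <- order(pvals, -abs(mass))
    clusters <- data.frame(
      cluster = seq_along(ord),
      sign = ifelse(sgn[ord] > 0, "positive", "negative"),
      start = vapply(obs_clusters[ord], min, 0L),
      end = vapply(obs_clusters[ord], max, 0L),
      size = vapply(obs_clusters[ord], length, 0L),
      mass = mass[ord], p = pvals[ord], stringsAsFactors = FALSE
    )
    members <- do.call(rbind, lapply(seq_along(ord), function(ci) {
      idx <- as.integer(obs_clusters[[ord[ci]]])
      data.frame(cluster = ci, node = idx, label = region_labels[idx],
                 t = t_obs[idx], stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    clusters = clusters, members = members, t = t_obs,
    t_crit = t_crit, forming_alpha = forming_alpha,
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    measure_name = measure_name, region_labels = region_labels
  ), class = "node_cluster_result")
}

#' @export
print.node_cluster_result <- function(x, ...) {
  cat(sprintf("node_cluster_result (%s): %d cluster(s), forming |t| > %.3f, %d permutations\n",
              x$measure_name, nrow(x$clusters), x$t_crit, x$n_perm))
  if (nrow(x$clusters) > 0) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Significant clusters from a cluster test
#'
#' @param result a `node_cluster_result`.
#' @param alpha significance level on the cluster p-values.
#' @return the `clusters` data.frame restricted to `p <= alpha`.
#' @export
significant_clusters <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "node_cluster_result"))
  result$clusters[result$clusters$p <= alpha, , drop = FALSE]
}
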