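#' Specify a synthetic two-group BOLD cohort
#'
#' Defines the design of a seeded synthetic resting-state cohort: two groups
#' of subjects whose parcel-averaged BOLD series are drawn from group-level
#' correlation structures that differ only inside planted, contiguous
#' "effect blocks" of atlas-ordered nodes. The defaults mirror a 166-region
#' parcellation scanned for 192 volumes at TR = 2 s, with 49 controls and 41
#' patients, and three planted blocks: two hypo-connected blocks (occipital-
#' and vermis-like positions) and one hyper-connected block (orbitofrontal-
#' like position).
#'
#' @param n_regions number of parcellated regions (nodes).
#' @param n_timepoints number of volumes per subject.
#' @param n_control,n_patient group sizes.
#' @param base_loading_rank number of latent factors generating the shared
#'   baseline correlation structure.
#' @param effect_blocks list of blocks, each a list with elements `nodes`
#'   (contiguous 1-based node indices), `direction` (`"hypo"` or `"hyper"`)
#'   and `delta` (effect magnitude in `[0, 1)`). Blocks must be disjoint.
#' @param ar_coefficient lag-1 autocorrelation of the simulated series,
#'   in `[0, 1)`.
#' @param noise_sd standard deviation of the factor-model's region-specific
#'   noise (controls how far baseline correlations sit below 1).
#' @param jitter_df degrees of freedom of the per-subject Wishart covariance
#'   perturbation; larger means subjects hew closer to their group matrix.
#'   `Inf` disables the jitter.
#' @param seed integer seed; every downstream draw derives from it.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()], [build_group_covariances()]
#' @export
cohort_spec <- function(n_regions = 166L,
                        n_timepoints = 192L,
                        n_control = 49L,
                        n_patient = 41L,
                        base_loading_rank = 8L,
                        effect_blocks = default_effect_blocks(),
                        ar_coefficient = 0.3,
                        noise_sd = 1,
                        jitter_df = 500,
                        seed = 1L) {
  check_scalar(n_regions, "n_regions", lo = 2, integerish = TRUE)
  check_scalar(n_timepoints, "n_timepoints", lo = 3, integerish = TRUE)
  check_scalar(n_control, "n_control", lo = 0, integerish = TRUE)
  check_scalar(n_patient, "n_patient", lo = 0, integerish = TRUE)
  check_scalar(base_loading_rank, "base_loading_rank", lo = 1, integerish = TRUE)
  check_scalar(ar_coefficient, "ar_coefficient", lo = 0, hi = 1 - 1e-12)
  check_scalar(noise_sd, "noise_sd", lo = 1e-12)
  if (!identical(jitter_df, Inf)) check_scalar(jitter_df, "jitter_df", lo = 2)
  check_scalar(seed, "seed", integerish = TRUE)

  seen <- integer(0)
  for (b in effect_blocks) {
    stopifnot(is.list(b), all(c("nodes", "direction", "delta") %in% names(b)))
    if (!b$direction %in% c("hypo", "hyper")) {
      stop("effect block direction must be 'hypo' or 'hyper'", call. = FALSE)
    }
    check_scalar(b$delta, "delta", lo = 0, hi = 1 - 1e-12)
    nodes <- as.integer(b$nodes)
    if (any(nodes < 1L) || any(nodes > n_regions)) {
      stop("effect block nodes must lie within [1, n_regions]", call. = FALSE)
    }
    if (!identical(nodes, seq(min(nodes), max(nodes)))) {
      stop("effect block nodes must be contiguous", call. = FALSE)
    }
    if (any(nodes %in% seen)) stop("effect blocks must be disjoint", call. = FALSE)
    seen <- c(seen, nodes)
  }

  structure(list(
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    n_control = as.integer(n_control),
    n_patient = as.integer(n_patient),
    base_loading_rank = as.integer(base_loading_rank),
    effect_blocks = effect_blocks,
    ar_coefficient = ar_coefficient,
    noise_sd = noise_sd,
    jitter_df = jitter_df,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default planted effect blocks
#'
#' Three contiguous blocks in atlas positions chosen to resemble the spatial
#' layout typically reported for depression: two blocks where patients are
#' hypo-connected (occipital-like nodes 47--54 and vermis-like nodes
#' 109--113) and one where they are hyper-connected (orbitofrontal-like
#' nodes 21--28), each with effect magnitude delta = 0.5.
#'
#' @return a list of effect-block descriptors.
#' @export
default_effect_blocks <- function() {
  list(
    list(nodes = 47:54,   direction = "hypo",  delta = 0.5),
    list(nodes = 109:113, direction = "hypo",  delta = 0.5),
    list(nodes = 21:28,   direction = "hyper", delta = 0.5)
  )
}

# Shared baseline correlation: low-rank factor model with a positive-dominant
# leading factor plus region-specific noise, rescaled to a correlation matrix.
baseline_correlation <- function(spec) {
  with_seed(derive_seed(spec$seed, "baseline"), {
    n <- spec$n_regions
    r <- spec$base_loading_rank
    L <- matrix(rnorm(n * r, sd = 0.6), n, r)
    L[, 1L] <- 0.7 + 0.3 * abs(rnorm(n))  # global positive factor
    S <- tcrossprod(L) + diag(spec$noise_sd^2, n)
    cov2cor(S)
  })
}

# Clip negative eigenvalues to zero and rescale the diagonal back to 1.
project_psd_correlation <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  d <- sqrt(pmax(diag(out), 1e-12))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out
}

#' Plant block-wise connectivity effects into a correlation matrix
#'
#' Applies the patient-group transformation to a baseline correlation
#' matrix: within every effect block, off-diagonal entries are attenuated
#' by `(1 - delta)` (hypo) or moved to `min(1, r * (1 + delta))` (hyper),
#' then the whole matrix is projected back to the nearest positive
#' semi-definite correlation matrix by eigenvalue clipping and diagonal
#' rescaling.
#'
#' @param corr baseline correlation matrix (symmetric PSD, unit diagonal).
#' @param effect_blocks list of blocks as in [cohort_spec()].
#' @return the altered correlation matrix.
#' @export
plant_effect_blocks <- function(corr, effect_blocks) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  out <- corr
  for (b in effect_blocks) {
    check_scalar(b$delta, "delta", lo = 0, hi = 1 - 1e-12)
    idx <- as.integer(b$nodes)
    if (any(idx < 1L) || any(idx > nrow(corr))) {
      stop("effect block nodes must lie within the matrix", call. = FALSE)
    }
    blk <- out[idx, idx, drop = FALSE]
    off <- row(blk) != col(blk)
    if (b$direction == "hypo") {
      blk[off] <- blk[off] * (1 - b$delta)
    } else {
      blk[off] <- pmax(-1, pmin(1, blk[off] * (1 + b$delta)))
    }
    out[idx, idx] <- blk
  }
  project_psd_correlation(out)
}

#' Build the control and patient group correlation matrices
#'
#' The control matrix is the shared baseline; the patient matrix is the
#' baseline with every within-block off-diagonal entry attenuated by
#' `(1 - delta)` for hypo blocks or moved to `min(1, r * (1 + delta))` for
#' hyper blocks, followed by projection to the nearest positive
#' semi-definite correlation matrix (eigenvalue clipping + diagonal
#' rescaling).
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `control` and `patient`, both symmetric PSD
#'   correlation matrices of size `n_regions`.
#' @export
build_group_covariances <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ctrl <- baseline_correlation(spec)
  pat <- plant_effect_blocks(ctrl, spec$effect_blocks)
  list(control = ctrl, patient = pat)
}

#' Simulate one subject's parcellated BOLD time series
#'
#' Draws Gaussian innovations with the requested cross-sectional covariance
#' and smooths them with a lag-1 autoregression. The same AR coefficient is
#' applied to every region, so the stationary cross-correlation of the
#' output equals that of the innovations; innovations are scaled by
#' `sqrt(1 - ar^2)` to keep unit marginal variance, and the series is
#' initialized from its stationary distribution.
#'
#' @param cov positive semi-definite covariance (regions x regions).
#' @param n_timepoints number of volumes to simulate.
#' @param ar lag-1 autoregression coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @param subject_id optional id attached to the result.
#' @return a `parcel_ts` object: matrix regions x timepoints with a
#'   `subject_id` attribute.
#' @export
simulate_subject <- function(cov, n_timepoints, ar = 0, seed = 1L,
                             subject_id = "subject") {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov))
  check_scalar(ar, "ar", lo = 0, hi = 1 - 1e-12)
  check_scalar(n_timepoints, "n_timepoints", lo = 2, integerish = TRUE)
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values))) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(cov))
  n <- nrow(cov)
  x <- with_seed(seed, {
    innov <- A %*% matrix(rnorm(n * n_timepoints), n, n_timepoints)
    out <- matrix(0, n, n_timepoints)
    out[, 1L] <- innov[, 1L]                       # stationary start
    sc <- sqrt(1 - ar^2)
    for (t in seq_len(n_timepoints - 1L) + 1L) {
      out[, t] <- ar * out[, t - 1L] + sc * innov[, t]
    }
    out
  })
  parcel_ts(x, subject_id = subject_id,
            region_labels = rownames(cov) %||% default_region_labels(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_region_labels <- function(n) sprintf("R%03d", seq_len(n))

#' Generate a full synthetic cohort
#'
#' Draws `n_control + n_patient` subjects. Each subject gets a covariance
#' equal to the group matrix, optionally perturbed by a Wishart draw with
#' `jitter_df` degrees of freedom (rescaled to a correlation matrix) so that
#' between-subject variability exists, then a seeded AR(1) series via
#' [simulate_subject()]. Per-subject seeds derive deterministically from
#' `spec$seed`, so the same spec regenerates the identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `synthetic_cohort`: list with `subjects`
#'   (each: `id`, `group`, `ts`), `subject_table` (data.frame), and
#'   `ground_truth` (effect blocks, planted edges, seed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  covs <- build_group_covariances(spec)
  groups <- c(rep("control", spec$n_control), rep("depression", spec$n_patient))
  ids <- sprintf("sub-%03d", seq_along(groups))
  subjects <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    gcov <- if (groups[k] == "control") covs$control else covs$patient
    scov <- if (is.finite(spec$jitter_df)) {
      with_seed(derive_seed(spec$seed, paste0("jitter-", k)), {
        # slight identity shrinkage keeps the Wishart scale strictly PD even
        # when PSD projection left zero eigenvalues
        sig <- 0.999 * gcov + 0.001 * diag(nrow(gcov))
        w <- stats::rWishart(1L, df = spec$jitter_df, Sigma = sig / spec$jitter_df)[, , 1L]
        cov2cor(w)
      })
    } else gcov
    subjects[[k]] <- list(
      id = ids[k], group = groups[k],
      ts = simulate_subject(scov, spec$n_timepoints, ar = spec$ar_coefficient,
                            seed = derive_seed(spec$seed, paste0("subject-", k)),
                            subject_id = ids[k])
    )
  }
  planted <- do.call(rbind, lapply(spec$effect_blocks, function(b) {
    idx <- as.integer(b$nodes)
    if (length(idx) < 2L) return(NULL)
    p <- upper_pairs(length(idx))
    data.frame(i = idx[p[, 1L]], j = idx[p[, 2L]],
               direction = b$direction, delta = b$delta)
  }))
  structure(list(
    subjects = subjects,
    subject_table = data.frame(subject_id = ids, group = groups,
                               stringsAsFactors = FALSE),
    ground_truth = list(effect_blocks = spec$effect_blocks,
                        planted_edges = planted, seed = spec$seed),
    spec = spec
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%d control, %d depression), %d regions x %d timepoints\n",
              length(x$subjects), x$spec$n_control, x$spec$n_patient,
              x$spec$n_regions, x$spec$n_timepoints))
  invisible(x)
}
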