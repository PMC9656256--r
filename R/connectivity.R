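#' Parcellated BOLD time series
#'
#' Light container for one subject's regions x timepoints matrix of
#' parcel-averaged BOLD signal. Row `i` holds the average series of region
#' `i` in ascending atlas order.
#'
#' @param data numeric matrix, regions x timepoints, no missing values.
#' @param subject_id subject identifier.
#' @param region_labels character vector, one label per region.
#' @return a `parcel_ts` object (a matrix with attributes).
#' @export
parcel_ts <- function(data, subject_id = "subject", region_labels = NULL) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (anyNA(data) || any(!is.finite(data))) {
    stop("parcel time series must be finite with no missing values", call. = FALSE)
  }
  if (ncol(data) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  region_labels <- region_labels %||% rownames(data) %||%
    default_region_labels(nrow(data))
  if (length(region_labels) != nrow(data)) {
    stop("region_labels length must match region count", call. = FALSE)
  }
  rownames(data) <- region_labels
  structure(data, subject_id = subject_id, class = c("parcel_ts", "matrix", "array"))
}

#' Average voxel time series into parcels
#'
#' Reduces a voxels x timepoints matrix to a regions x timepoints matrix by
#' taking the unweighted mean over the voxels assigned to each parcel.
#' Parcels are ordered by ascending parcel id.
#'
#' @param voxel_data numeric matrix, voxels x timepoints.
#' @param labels integer vector of parcel ids, one per voxel.
#' @param subject_id subject identifier carried into the result.
#' @return a [parcel_ts()] with one row per distinct parcel id.
#' @export
parcel_average <- function(voxel_data, labels, subject_id = "subject") {
  stopifnot(is.matrix(voxel_data))
  if (length(labels) != nrow(voxel_data)) {
    stop("'labels' must have one entry per voxel (row)", call. = FALSE)
  }
  ids <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts == 0)) {
    stop(sprintf("empty parcel(s): %s",
                 paste(names(counts)[counts == 0], collapse = ", ")), call. = FALSE)
  }
  out <- rowsum(voxel_data, group = labels, reorder = TRUE) /
    as.vector(counts[as.character(ids)])
  parcel_ts(unname(out), subject_id = subject_id,
            region_labels = sprintf("P%s", ids))
}

#' Pearson functional connectivity matrix
#'
#' Computes the region x region matrix of Pearson correlation coefficients
#' between parcel-averaged BOLD series: for regions i and j with series
#' x_i(t), x_j(t) over n timepoints,
#' r_ij = sum_t (x_i - mean x_i)(x_j - mean x_j) /
#'        sqrt(sum_t (x_i - mean x_i)^2  sum_t (x_j - mean x_j)^2).
#' A region with zero temporal variance makes the coefficient undefined and
#' raises an error naming the region.
#'
#' @param ts a [parcel_ts()] or plain regions x timepoints matrix.
#' @param subject_id identifier; defaults to the one carried by `ts`.
#' @return a `connectivity_matrix`: symmetric matrix with unit diagonal and
#'   entries in `[-1, 1]`, with `subject_id` attribute.
#' @export
pearson_connectivity <- function(ts, subject_id = NULL) {
  subject_id <- subject_id %||% attr(ts, "subject_id") %||% "subject"
  m <- unclass(ts)
  stopifnot(is.matrix(m), is.numeric(m))
  if (ncol(m) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(m)[v == 0] %||% which(v == 0)
    stop(sprintf("constant time series in region(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  R <- stats::cor(t(m))
  R <- (R + t(R)) / 2
  diag(R) <- 1
  connectivity_matrix(R, subject_id = subject_id,
                      region_labels = rownames(m))
}

#' Connectivity matrix container with invariant checks
#'
#' Validates and wraps a symmetric correlation matrix: square, symmetric to
#' 1e-12, diagonal exactly 1, all entries in `[-1, 1]`.
#'
#' @param R numeric square matrix.
#' @param subject_id subject identifier.
#' @param region_labels labels for rows/columns.
#' @return a `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(R, subject_id = "subject", region_labels = NULL) {
  stopifnot(is.matrix(R), is.numeric(R))
  if (nrow(R) != ncol(R)) stop("connectivity matrix must be square", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-12) {
    stop("connectivity matrix must be symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(abs(diag(R) - 1) > 0)) {
    stop("connectivity matrix diagonal must be exactly 1", call. = FALSE)
  }
  if (min(R) < -1 - 1e-12 || max(R) > 1 + 1e-12) {
    stop("connectivity entries must lie in [-1, 1]", call. = FALSE)
  }
  region_labels <- region_labels %||% rownames(R) %||%
    default_region_labels(nrow(R))
  dimnames(R) <- list(region_labels, region_labels)
  structure(R, subject_id = subject_id,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Synthetic region metadata table
#'
#' Produces a stand-in region table with the structure of an anatomical
#' atlas: 1-based atlas index (whose ascending order defines the anatomical
#' neighborhood used by the cluster test), a label, and MNI-like centroid
#' coordinates laid out on a regular grid. The labels and coordinates are
#' synthetic -- they carry the format, not real anatomy.
#'
#' @param n_regions number of regions.
#' @return data.frame with columns `index`, `label`, `x`, `y`, `z`.
#' @export
synthetic_region_table <- function(n_regions = 166L) {
  check_scalar(n_regions, "n_regions", lo = 1, integerish = TRUE)
  idx <- seq_len(n_regions)
  # grid layout spanning a brain-sized bounding box, purely synthetic
  nx <- ceiling(n_regions^(1 / 3))
  gx <- ((idx - 1L) %% nx)
  gy <- ((idx - 1L) %/% nx) %% nx
  gz <- (idx - 1L) %/% (nx * nx)
  data.frame(
    index = idx,
    label = default_region_labels(n_regions),
    x = round(-70 + 140 * gx / max(nx - 1L, 1L), 1),
    y = round(-100 + 170 * gy / max(nx - 1L, 1L), 1),
    z = round(-60 + 140 * gz / max(nx - 1L, 1L), 1),
    stringsAsFactors = FALSE
  )
}

validate_region_table <- function(regions) {
  stopifnot(is.data.frame(regions))
  need <- c("index", "label", "x", "y", "z")
  if (!all(need %in% names(regions))) {
    stop(sprintf("region table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(regions$index)) stop("region indices must be unique", call. = FALSE)
  if (is.unsorted(regions$index, strictly = TRUE)) {
    stop("region indices must be sorted ascending", call. = FALSE)
  }
  invisible(regions)
}
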