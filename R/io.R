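#' Write a dense numeric matrix as labeled TSV
#'
#' Tab-separated grid with one header row of column labels and a leading
#' label column of row names; the format used for time series,
#' connectivity matrices and significance masks.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  rn <- rownames(m) %||% default_region_labels(nrow(m))
  cn <- colnames(m) %||% sprintf("c%d", seq_len(ncol(m)))
  # %.17g preserves doubles exactly across the round trip
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rn[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(paste(c("label", cn), collapse = "\t"), body), path)
  invisible(path)
}

#' Read a dense numeric matrix written by [write_matrix()]
#'
#' @param path input path.
#' @param symmetric if `TRUE`, validate symmetry to `tol` and average the
#'   two triangles.
#' @param tol symmetry tolerance.
#' @return numeric matrix with row/column names restored.
#' @export
read_matrix <- function(path, symmetric = FALSE, tol = 1e-8) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop(sprintf("'%s': no data rows", path), call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncols <- length(header)
  rows <- vector("list", length(lines) - 1L)
  rn <- character(length(lines) - 1L)
  for (k in seq_along(rows)) {
    parts <- strsplit(lines[k + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != ncols) {
      stop(sprintf("'%s' line %d: expected %d fields, found %d",
                   path, k + 1L, ncols, length(parts)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) {
      stop(sprintf("'%s' line %d: non-numeric cell", path, k + 1L), call. = FALSE)
    }
    rn[k] <- parts[1L]
    rows[[k]] <- vals
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(rn, header[-1L])
  if (symmetric) {
    if (nrow(m) != ncol(m)) stop(sprintf("'%s': not square", path), call. = FALSE)
    if (max(abs(m - t(m))) > tol) {
      stop(sprintf("'%s': asymmetric beyond tolerance %g", path, tol), call. = FALSE)
    }
    m <- (m + t(m)) / 2
  }
  m
}

#' Read and validate a subject table
#'
#' CSV with columns `subject_id`, `group` (values `control` /
#' `depression`) and optionally `diagnosis` (free labels on depression
#' rows, e.g. MDD / BAD). Duplicate ids and unknown group values are
#' errors. When a diagnosis column is present, one dummy column
#' `diag_<level>` per diagnosis level is appended; the dummies sum to the
#' depression indicator (pass a full-rank subset of them, e.g. all but
#' one level, to [build_design()]).
#'
#' @param path CSV path.
#' @return data.frame, in file order.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("subject table needs columns 'subject_id' and 'group'", call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in subject table", call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("control", "depression"))
  if (length(bad) > 0) {
    stop(sprintf("unknown group value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if ("diagnosis" %in% names(df)) {
    lev <- sort(unique(df$diagnosis[df$group == "depression" & !is.na(df$diagnosis) &
                                      df$diagnosis != ""]))
    for (lv in lev) {
      df[[paste0("diag_", lv)]] <-
        as.integer(df$group == "depression" & !is.na(df$diagnosis) &
                     df$diagnosis == lv)
    }
  }
  df
}

#' Write a synthetic cohort to disk
#'
#' One TSV per subject (regions x timepoints, region labels as row
#' labels), a subject table CSV, and a ground-truth JSON recording the
#' planted blocks, planted edges and seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_matrix(unclass(s$ts), file.path(dir, paste0(s$id, "_ts.tsv")))
  }
  utils::write.csv(cohort$subject_table, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(seed = gt$seed,
         effect_blocks = lapply(gt$effect_blocks, function(b)
           list(nodes = as.integer(b$nodes), direction = b$direction,
                delta = b$delta)),
         planted_edges = gt$planted_edges),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
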