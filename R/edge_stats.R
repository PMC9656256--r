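#' Build a design matrix for the edge-wise group test
#'
#' Columns: intercept, optional covariates, then the group contrast column
#' coded 1 for `"control"` and 0 for `"depression"`, so a positive t means
#' stronger connectivity in controls. The design must be full column rank;
#' a covariate collinear with the group indicator (e.g. diagnosis dummies
#' that jointly sum to the patient indicator) is rejected.
#'
#' @param groups character vector of `"control"` / `"depression"` labels.
#' @param covariates optional numeric matrix or data.frame of covariate
#'   columns (dummy-coded), rows aligned with `groups`.
#' @return list with `X` (design matrix), `contrast_col` (index of the
#'   group column), `groups`.
#' @export
build_design <- function(groups, covariates = NULL) {
  groups <- as.character(groups)
  if (!all(groups %in% c("control", "depression"))) {
    stop("groups must be 'control' or 'depression'", call. = FALSE)
  }
  if (length(unique(groups)) < 2L) stop("both groups must be present", call. = FALSE)
  g <- as.numeric(groups == "control")
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != length(groups)) {
      stop("covariates must have one row per subject", call. = FALSE)
    }
    if (is.null(colnames(cv))) colnames(cv) <- sprintf("cov%d", seq_len(ncol(cv)))
  }
  X <- cbind(intercept = rep(1, length(groups)), cv, group = g)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient: a covariate is confounded with the group indicator",
         call. = FALSE)
  }
  list(X = X, contrast_col = ncol(X), groups = groups)
}

# GLM contrast t-statistics for every column of Y given design X.
glm_contrast_t <- function(X, Y, contrast_col) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  M <- XtXinv %*% t(X)                      # p x n
  beta <- M %*% Y                           # p x E
  XtY <- crossprod(X, Y)
  rss <- colSums(Y * Y) - colSums(XtY * beta)
  sigma2 <- pmax(rss, 0) / (n - p)
  se <- sqrt(sigma2 * XtXinv[contrast_col, contrast_col])
  tt <- beta[contrast_col, ] / se
  tt[se == 0] <- 0
  tt
}

# Two-sample pooled t for many permuted control indicators at once.
# G: B x n matrix of 0/1 control indicators; Y: n x E edge matrix.
perm_two_sample_t <- function(G, Y, n1, n0) {
  S <- colSums(Y); SS <- colSums(Y * Y); n <- n1 + n0
  S1 <- G %*% Y                             # B x E
  m1 <- S1 / n1
  m0 <- sweep(-S1, 2L, S, `+`) / n0
  ssw <- sweep(-(n1 * m1^2 + n0 * m0^2), 2L, SS, `+`)
  se <- sqrt(pmax(ssw, 0) / (n - 2) * (1 / n1 + 1 / n0))
  tt <- (m1 - m0) / se
  tt[se == 0] <- 0
  tt
}

#' Edge-wise group comparison with permutation p-values and FDR control
#'
#' For every upper-triangle edge, fits the linear model
#' `edge ~ intercept + covariates + group` and computes the group-contrast
#' t-statistic (positive = stronger in controls). Permutation p-values use
#' Freedman-Lane residual permutation: residuals of the covariates-only
#' model are permuted, refitted under the full model, and the contrast t
#' recomputed, `n_perm` times from a seeded stream. With no covariates
#' this reduces exactly to permuting group labels, and that equivalent
#' fast path is used. P-values use the add-one estimator
#' `(1 + #{|t*| >= |t|}) / (1 + n_perm)`; Benjamini-Hochberg correction is
#' applied across all edges and the mask thresholds the adjusted q-values
#' at `alpha`.
#'
#' @param matrices list of [connectivity_matrix()] objects (or plain
#'   symmetric matrices) sharing one region order.
#' @param groups character vector of `"control"`/`"depression"`, one per
#'   matrix.
#' @param covariates optional dummy-coded covariate columns.
#' @param alpha FDR significance level (the study default is 1e-4).
#' @param n_perm number of permutations (the study default is 100000).
#' @param seed integer seed for the permutation stream.
#' @param alternative `"two.sided"` (default) or `"greater"`
#'   (control > depression).
#' @param use_fast_path use the vectorized label-permutation path when no
#'   covariates are present (identical results; set `FALSE` to force the
#'   general Freedman-Lane loop, mainly for cross-validation of the two
#'   implementations).
#' @return object of class `edge_test_result`: `edges` data.frame
#'   (i, j, t, p_perm, q_fdr, significant), `mask` (0/1 matrix),
#'   `n_significant_edges`, `n_involved_nodes`, and the parameters used.
#' @export
edgewise_group_test <- function(matrices, groups, covariates = NULL,
                                alpha = 1e-4, n_perm = 100000L, seed = 1L,
                                alternative = c("two.sided", "greater"),
                                use_fast_path = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(length(matrices) == length(groups))
  if (min(table(groups)) < 2L) stop("need at least 2 subjects per group", call. = FALSE)
  check_scalar(alpha, "alpha", lo = 0, hi = 1)
  check_scalar(n_perm, "n_perm", lo = 1, integerish = TRUE)

  nreg <- nrow(matrices[[1L]])
  labels <- rownames(matrices[[1L]]) %||% default_region_labels(nreg)
  for (m in matrices) {
    if (nrow(m) != nreg) stop("all matrices must share one region order", call. = FALSE)
  }
  pairs <- upper_pairs(nreg)
  Y <- do.call(rbind, lapply(matrices, upper_vec))   # subjects x edges
  des <- build_design(groups, covariates)
  X <- des$X
  n <- nrow(X)
  t_obs <- glm_contrast_t(X, Y, des$contrast_col)

  exceed <- numeric(ncol(Y))
  cmp <- function(tp, to) {
    if (alternative == "two.sided") abs(tp) >= abs(to) - 1e-12 else tp >= to - 1e-12
  }
  with_seed(seed, {
    if (ncol(X) == 2L && use_fast_path) {
      # no covariates: Freedman-Lane == label permutation; vectorized
      n1 <- sum(des$groups == "control"); n0 <- n - n1
      chunk <- max(1L, min(n_perm, floor(5e6 / ncol(Y))))
      done <- 0L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        G <- matrix(0, b, n)
        for (r in seq_len(b)) G[r, sample.int(n, n1)] <- 1
        tp <- perm_two_sample_t(G, Y, n1, n0)
        To <- matrix(t_obs, b, ncol(Y), byrow = TRUE)
        exceed <- exceed + colSums(cmp(tp, To))
        done <- done + b
      }
    } else {
      # Freedman-Lane: permute reduced-model residuals, refit full model
      Z <- X[, -des$contrast_col, drop = FALSE]
      Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
      fitted_z <- Hz %*% Y
      resid_z <- Y - fitted_z
      for (b in seq_len(n_perm)) {
        Ystar <- fitted_z + resid_z[sample.int(n), , drop = FALSE]
        tp <- glm_contrast_t(X, Ystar, des$contrast_col)
        exceed <- exceed + cmp(tp, t_obs)
      }
    }
  })
  p_perm <- (1 + exceed) / (1 + n_perm)
  q_fdr <- stats::p.adjust(p_perm, method = "BH")
  sig <- q_fdr <= alpha

  edges <- data.frame(
    i = pairs[, 1L], j = pairs[, 2L],
    region_i = labels[pairs[, 1L]], region_j = labels[pairs[, 2L]],
    t = t_obs, p_perm = p_perm, q_fdr = q_fdr, significant = sig,
    stringsAsFactors = FALSE
  )
  mask <- matrix(0L, nreg, nreg, dimnames = list(labels, labels))
  mask[cbind(pairs[sig, 1L], pairs[sig, 2L])] <- 1L
  mask[cbind(pairs[sig, 2L], pairs[sig, 1L])] <- 1L
  structure(list(
    edges = edges, mask = mask,
    n_significant_edges = sum(sig),
    n_involved_nodes = length(unique(c(pairs[sig, 1L], pairs[sig, 2L]))),
    alpha = alpha, n_perm = as.integer(n_perm), seed = as.integer(seed),
    alternative = alternative
  ), class = "edge_test_result")
}

#' @export
print.edge_test_result <- function(x, ...) {
  cat(sprintf("edge_test_result: %d/%d edges significant (q <= %g), touching %d nodes; %d permutations\n",
              x$n_significant_edges, nrow(x$edges), x$alpha,
              x$n_involved_nodes, x$n_perm))
  invisible(x)
}

#' Two-sample pooled-variance t-test on network means
#'
#' Compares the network-mean values of one measure between groups with the
#' classical independent-samples t-test (equal variances, two-sided).
#'
#' @param means_control,means_patient numeric vectors of per-subject
#'   network means.
#' @return list with `t`, `p`, `df`.
#' @export
global_measure_test <- function(means_control, means_patient) {
  if (length(means_control) < 2L || length(means_patient) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  n1 <- length(means_control); n2 <- length(means_patient)
  sp2 <- ((n1 - 1) * stats::var(means_control) +
          (n2 - 1) * stats::var(means_patient)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance: groups are constant", call. = FALSE)
  tt <- (mean(means_control) - mean(means_patient)) /
    sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square without continuity correction (df = 1), the form
#' that reproduces the demographic comparisons of sex and education.
#'
#' @param table 2x2 matrix of counts.
#' @return list with `statistic`, `p`.
#' @export
chi_square_test <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("all expected counts must be positive", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum ECDF gap D with the asymptotic p-value; the nonparametric group
#' comparison used for continuous demographics (age, symptom scores).
#'
#' @param a,b numeric samples.
#' @return list with `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests a sample against a normal distribution with plug-in sample mean
#' and standard deviation. Using estimated parameters makes the test
#' conservative about rejecting normality (the classical Lilliefors
#' caveat), which is documented rather than corrected.
#'
#' @param x numeric sample, length >= 5.
#' @return list with `D`, `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5L) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance: normality test undefined", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x),
                                         exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}
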