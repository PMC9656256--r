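#' Build a subject x feature table for one feature-vector variant
#'
#' Variants: `"full_fc"` flattens each connectivity matrix's upper
#' triangle (i < j, row-major; N(N-1)/2 features); `"significant_fc"`
#' restricts that flattening to the edges flagged in `mask`;
#' `"clustering"`, `"strength"`, `"centrality"` use the per-node measure
#' vectors.
#'
#' @param variant feature variant name.
#' @param matrices list of [connectivity_matrix()] (FC variants).
#' @param measure_sets list of [node_measures()] (node variants).
#' @param mask symmetric 0/1 matrix (required for `significant_fc`).
#' @return numeric matrix, subjects x features, with feature names
#'   `"i_j"` (edges) or region labels (nodes).
#' @export
build_features <- function(variant = c("full_fc", "significant_fc",
                                       "clustering", "strength", "centrality"),
                           matrices = NULL, measure_sets = NULL, mask = NULL) {
  variant <- match.arg(variant)
  if (variant %in% c("full_fc", "significant_fc")) {
    if (is.null(matrices)) stop("FC variants need 'matrices'", call. = FALSE)
    nreg <- nrow(matrices[[1L]])
    pairs <- upper_pairs(nreg)
    X <- do.call(rbind, lapply(matrices, upper_vec))
    colnames(X) <- sprintf("%d_%d", pairs[, 1L], pairs[, 2L])
    rownames(X) <- vapply(matrices, function(m) attr(m, "subject_id") %||% "", "")
    if (variant == "significant_fc") {
      if (is.null(mask)) stop("significant_fc requires an edge mask", call. = FALSE)
      keep <- mask[cbind(pairs[, 1L], pairs[, 2L])] != 0
      X <- X[, keep, drop = FALSE]
    }
    return(X)
  }
  if (is.null(measure_sets)) stop("node variants need 'measure_sets'", call. = FALSE)
  measure_matrix(measure_sets, variant)
}

#' Fit a pseudo-inverse ("pseudolinear") linear discriminant model
#'
#' Classical two-class LDA with the pooled within-class covariance
#' inverted by Moore-Penrose pseudo-inverse, so rank-deficient feature
#' sets (more features than subjects, duplicated columns) are tolerated:
#' the discriminant acts in the span of the within-class variation. The
#' pseudo-inverse is computed from the economy SVD of the class-centered
#' data matrix, never forming the p x p covariance. Discriminant scores
#' are delta_k(x) = x' S^+ m_k - m_k' S^+ m_k / 2 + log(prior_k);
#' posteriors are softmax of the scores.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels vector with exactly two classes, each with >= 2 members.
#' @param priors `"empirical"` (class proportions, the default) or
#'   `"uniform"`.
#' @param positive the class treated as positive for scores (default
#'   `"depression"` when present, else the second level).
#' @return object of class `lda_pseudo`.
#' @export
lda_fit <- function(features, labels, priors = c("empirical", "uniform"),
                    positive = NULL) {
  priors <- match.arg(priors)
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("one label per subject required", call. = FALSE)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  cnt <- table(factor(labels, levels = lev))
  if (min(cnt) < 2L) stop("each class needs at least 2 members", call. = FALSE)
  positive <- positive %||% if ("depression" %in% lev) "depression" else lev[2L]
  if (!positive %in% lev) stop("'positive' must be one of the class labels", call. = FALSE)

  n <- nrow(X); p <- ncol(X)
  pri <- if (priors == "empirical") as.numeric(cnt) / n else c(0.5, 0.5)
  names(pri) <- lev
  if (p == 0L) {
    return(structure(list(levels = lev, positive = positive, priors = pri,
                          means = matrix(0, 2, 0), V = matrix(0, 0, 0),
                          w = numeric(0)), class = "lda_pseudo"))
  }
  means <- rbind(colMeans(X[labels == lev[1L], , drop = FALSE]),
                 colMeans(X[labels == lev[2L], , drop = FALSE]))
  rownames(means) <- lev
  Xc <- X - means[match(labels, lev), , drop = FALSE]
  s <- svd(Xc, nu = 0)
  keep <- s$d > max(s$d[1L], 0) * 1e-8
  V <- s$v[, keep, drop = FALSE]                 # p x r
  w <- (n - 2) / s$d[keep]^2                     # eigenvalues of S^+
  structure(list(levels = lev, positive = positive, priors = pri,
                 means = means, V = V, w = w),
            class = "lda_pseudo")
}

#' Predict from a pseudo-inverse LDA model
#'
#' @param object an [lda_fit()] model.
#' @param newdata numeric matrix, subjects x features (same columns as at
#'   fit time).
#' @param ... unused.
#' @return list with `class` (predicted labels), `posterior` (n x 2
#'   matrix), `score` (discriminant of the positive class minus the
#'   negative one).
#' @export
predict.lda_pseudo <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  n <- nrow(X)
  if (ncol(object$means) == 0L) {
    cls <- names(object$priors)[which.max(object$priors)]
    post <- matrix(object$priors, n, 2, byrow = TRUE,
                   dimnames = list(NULL, object$levels))
    score <- rep(log(object$priors[object$positive]) -
                   log(object$priors[setdiff(object$levels, object$positive)]), n)
    return(list(class = rep(cls, n), posterior = post, score = unname(score)))
  }
  # a_k = S^+ m_k computed in the retained singular subspace
  PM <- object$means %*% object$V                # 2 x r
  PX <- X %*% object$V                           # n x r
  delta <- matrix(0, n, 2, dimnames = list(NULL, object$levels))
  for (k in 1:2) {
    a <- PM[k, ] * object$w
    delta[, k] <- PX %*% a - 0.5 * sum(PM[k, ] * a) + log(object$priors[k])
  }
  shift <- apply(delta, 1L, max)
  post <- exp(delta - shift)
  post <- post / rowSums(post)
  pos <- object$positive
  neg <- setdiff(object$levels, pos)
  list(class = object$levels[max.col(delta, ties.method = "first")],
       posterior = post,
       score = delta[, pos] - delta[, neg])
}

# Stratified fold assignment: within each class, fold ids 1..k as evenly
# as possible, shuffled. Consumes the current RNG stream.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# ROC curve from scores (higher = more positive) with trapezoidal AUC;
# tied scores collapse to single ROC points.
roc_points <- function(score, is_pos) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- is_pos[ord]
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- c(s[-1L] != s[-length(s)], TRUE)     # last index of each tie group
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (head_vec(tpr) + tail_vec(tpr)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
head_vec <- function(x) x[-length(x)]
tail_vec <- function(x) x[-1L]

#' Repeated stratified k-fold cross-validation of the LDA classifier
#'
#' Each repeat draws fresh stratified folds from the seeded stream, fits
#' the pseudo-inverse LDA on each training fold and predicts the held-out
#' fold. Accuracy is aggregated as mean +/- SD over repeats; sensitivity,
#' specificity and precision come from the confusion matrix pooled over
#' all out-of-fold predictions with the positive class (default
#' `"depression"`); the ROC/AUC is computed from the pooled out-of-fold
#' discriminant scores.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels two-class label vector.
#' @param k number of folds (default 10).
#' @param repeats number of independent repetitions (the study protocol
#'   uses 1000; suites use fewer).
#' @param seed integer seed.
#' @param priors passed to [lda_fit()].
#' @param positive positive class for sensitivity/precision/ROC.
#' @param selector optional function(train_idx) -> integer column subset,
#'   re-evaluated inside every training fold (e.g. recomputing the
#'   significant-edge mask without test-set leakage). `NULL` uses all
#'   columns.
#' @return object of class `classification_report`.
#' @export
cross_validate <- function(features, labels, k = 10L, repeats = 100L,
                           seed = 1L, priors = "empirical",
                           positive = NULL, selector = NULL) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("exactly two classes required", call. = FALSE)
  positive <- positive %||% if ("depression" %in% lev) "depression" else lev[2L]
  check_scalar(k, "k", lo = 2, integerish = TRUE)
  check_scalar(repeats, "repeats", lo = 1, integerish = TRUE)
  n <- nrow(X)

  acc <- numeric(repeats)
  pooled_pred <- character(0)
  pooled_true <- character(0)
  pooled_score <- numeric(0)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      folds <- stratified_folds(labels, k)
      pred <- character(n); scor <- numeric(n)
      for (f in sort(unique(folds))) {
        test_idx <- which(folds == f)
        train_idx <- setdiff(seq_len(n), test_idx)
        if (length(unique(labels[train_idx])) < 2L) {
          stop("a training fold lost a class; reduce k", call. = FALSE)
        }
        cols <- if (is.null(selector)) seq_len(ncol(X)) else selector(train_idx)
        fit <- lda_fit(X[train_idx, cols, drop = FALSE], labels[train_idx],
                       priors = priors, positive = positive)
        pr <- predict(fit, X[test_idx, cols, drop = FALSE])
        pred[test_idx] <- pr$class
        scor[test_idx] <- pr$score
      }
      acc[r] <- mean(pred == labels)
      pooled_pred <- c(pooled_pred, pred)
      pooled_true <- c(pooled_true, labels)
      pooled_score <- c(pooled_score, scor)
    }
  })
  neg <- setdiff(lev, positive)
  tp <- sum(pooled_pred == positive & pooled_true == positive)
  tn <- sum(pooled_pred == neg & pooled_true == neg)
  fp <- sum(pooled_pred == positive & pooled_true == neg)
  fn <- sum(pooled_pred == neg & pooled_true == positive)
  rc <- roc_points(pooled_score, pooled_true == positive)
  structure(list(
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc), accuracy = acc,
    sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                       dimnames = list(truth = c(positive, neg),
                                       predicted = c(positive, neg))),
    roc = rc$roc, auc = rc$auc,
    k = as.integer(k), repeats = as.integer(repeats),
    seed = as.integer(seed), positive = positive
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report: accuracy %.4f +/- %.4f (k = %d, %d repeats)\n  sensitivity %.3f  specificity %.3f  precision %.3f  AUC %.3f\n",
    x$accuracy_mean, x$accuracy_sd, x$k, x$repeats,
    x$sensitivity, x$specificity, x$precision, x$auc))
  invisible(x)
}

#' Training-fold edge-mask selector for the significant-FC variant
#'
#' Returns a closure for [cross_validate()]'s `selector` argument: given
#' training-row indices, it reruns the edge-wise FDR analysis on those
#' subjects only and returns the column indices (in full-FC upper-triangle
#' order) of the significant edges -- so feature selection never sees the
#' held-out fold.
#'
#' With `method = "parametric"` (default) the fold-internal p-values come
#' from the analytic t distribution of the group contrast: feature
#' selection does not need permutation exactness, and the permutation
#' estimator's floor of `1/(n_perm + 1)` would otherwise make every
#' fold-internal BH threshold unreachable unless `n_perm` exceeds the
#' edge count divided by `alpha`. `method = "permutation"` runs the full
#' seeded permutation test per fold.
#'
#' @param matrices list of connectivity matrices (all subjects, original
#'   order).
#' @param groups group labels aligned with `matrices`.
#' @param alpha FDR level for the fold-internal selection.
#' @param method `"parametric"` or `"permutation"`.
#' @param n_perm,seed permutation parameters (only for
#'   `method = "permutation"`).
#' @return function(train_idx) -> integer vector of feature columns.
#' @export
fc_mask_selector <- function(matrices, groups, alpha = 0.05,
                             method = c("parametric", "permutation"),
                             n_perm = 500L, seed = 1L) {
  method <- match.arg(method)
  force(matrices); force(groups)
  if (method == "permutation") {
    return(function(train_idx) {
      res <- edgewise_group_test(matrices[train_idx], groups[train_idx],
                                 alpha = alpha, n_perm = n_perm, seed = seed)
      which(res$edges$significant)
    })
  }
  Y_all <- do.call(rbind, lapply(matrices, upper_vec))
  function(train_idx) {
    des <- build_design(groups[train_idx])
    tt <- glm_contrast_t(des$X, Y_all[train_idx, , drop = FALSE],
                         des$contrast_col)
    p <- 2 * stats::pt(-abs(tt), df = length(train_idx) - 2)
    which(stats::p.adjust(p, method = "BH") <= alpha)
  }
}
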