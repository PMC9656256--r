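# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministically derive a child seed from (seed, key). Keeps the result in
# [1, 2^31 - 2] so it is always a valid 32-bit integer seed.
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

#' @importFrom stats cor cov2cor qt pt p.adjust rnorm rWishart sd setNames
#' @importFrom stats chisq.test ks.test t.test
NULL

# Upper-triangle (i < j) index pairs in row-major order: (1,2), (1,3), ...
upper_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

# Flatten the upper triangle of a symmetric matrix in row-major (i < j) order.
upper_vec <- function(m) {
  p <- upper_pairs(nrow(m))
  m[cbind(p[, 1L], p[, 2L])]
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integerish = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lo || x > hi) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x),
         call. = FALSE)
  }
  if (integerish && x != round(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(x)
}
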