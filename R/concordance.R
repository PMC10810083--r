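# Lin's concordance between vectorized co-fluctuation patterns.

#' Lin's concordance between two vectors
#'
#' C_xy = 2 Cov(x, y) / (Var(x) + Var(y) + (mu_x - mu_y)^2), with sample
#' (n-1) moments. Unlike the Pearson correlation, concordance is penalized
#' when the means or variances of the two patterns differ; when means and
#' variances match the two are identical, and in general |C| <= |r|.
#'
#' @param x,y numeric vectors of equal length >= 2 (upper-triangle
#'   vectorizations of patterns, diagonal excluded)
#' @return scalar concordance in [-1, 1]
#' @export
lin_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 elements")
  vx <- stats::var(x)
  vy <- stats::var(y)
  d2 <- (mean(x) - mean(y))^2
  denom <- vx + vy + d2
  if (denom == 0) {
    stop("concordance undefined: both vectors constant with equal means")
  }
  2 * stats::cov(x, y) / denom
}

#' Pattern ensemble container
#'
#' @param patterns non-empty list of [cofluct_pattern()] matrices sharing N
#' @param subject_ids optional per-pattern labels (defaults to each pattern's
#'   `subject_id` attribute)
#' @return object of class `pattern_ensemble` with `patterns`, `subject_ids`,
#'   `N`, `M`
#' @export
pattern_ensemble <- function(patterns, subject_ids = NULL) {
  if (!length(patterns)) stop("pattern list must be non-empty")
  n <- nrow(patterns[[1]])
  for (p in patterns) {
    if (!is.matrix(p) || nrow(p) != n || ncol(p) != n) {
      stop("all patterns must be square matrices sharing N = ", n)
    }
  }
  if (is.null(subject_ids)) {
    subject_ids <- vapply(patterns, function(p) {
      as.character(attr(p, "subject_id") %||% NA_character_)
    }, character(1))
  }
  stopifnot(length(subject_ids) == length(patterns))
  structure(list(patterns = patterns, subject_ids = as.character(subject_ids),
                 N = n, M = length(patterns)),
            class = "pattern_ensemble")
}

#' @export
print.pattern_ensemble <- function(x, ...) {
  cat(sprintf("<pattern_ensemble> %d patterns, N = %d nodes\n", x$M, x$N))
  invisible(x)
}

#' Pairwise Lin's concordance between all patterns of an ensemble
#'
#' Patterns are vectorized over the upper triangle (diagonal excluded) and all
#' pairwise concordances computed. Diagonal set to exactly 1.
#'
#' @param ensemble a [pattern_ensemble()] with >= 2 patterns
#' @return M x M symmetric matrix of class `concordance_matrix`
#' @export
concordance_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "pattern_ensemble"))
  if (ensemble$M < 2) stop("need at least 2 patterns")
  v <- vapply(ensemble$patterns, upper_vec,
              numeric(ensemble$N * (ensemble$N - 1) / 2))
  mu <- colMeans(v)
  cv <- stats::cov(v)
  vr <- diag(cv)
  denom <- outer(vr, vr, "+") + outer(mu, mu, "-")^2
  if (any(denom == 0 & row(denom) != col(denom))) {
    bad <- which(denom == 0 & row(denom) != col(denom), arr.ind = TRUE)[1, ]
    stop("concordance undefined for patterns ", bad[1], " and ", bad[2],
         ": both constant with equal means")
  }
  cm <- 2 * cv / denom
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  class(cm) <- c("concordance_matrix", class(cm))
  cm
}
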