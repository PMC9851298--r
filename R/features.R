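#' Select top features by variance
#'
#' Ranks the rows of a feature matrix (genes-by-cells or edges-by-cells)
#' by sample variance across cells, descending, and keeps the top `k`.
#' Ties are broken by original row order, so the selection is
#' deterministic. On a delta rank matrix this is the standard
#' dimension-reduction step before clustering; the conventional default
#' is `k = 500` features.
#'
#' @param x Numeric matrix with row names, or a `delta_rank_matrix`
#'   (its normalized layer is used).
#' @param k Number of features to keep (default 500); capped at the
#'   number of rows.
#' @return A `feature_selection`: data.frame with columns `feature_id`
#'   and `score` (nonincreasing), and attributes `k` and `criterion`.
#' @export
top_variance_features <- function(x, k = 500) {
  if (inherits(x, "delta_rank_matrix")) x <- drm_layer(x, "normalized")
  if (!is.matrix(x) || nrow(x) < 1L) stop_validation("need a matrix with >= 1 row")
  if (k < 1L) stop_validation("k must be >= 1")
  v <- row_vars(x)
  ord <- order(-v)              # stable: equal variances keep row order
  ord <- ord[seq_len(min(k, nrow(x)))]
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  structure(
    data.frame(feature_id = ids[ord], score = v[ord], stringsAsFactors = FALSE),
    class = c("feature_selection", "data.frame"),
    k = k, criterion = "variance"
  )
}

#' Per-row coefficient of variation
#'
#' CV = sample standard deviation / |mean|, per row. Rows whose mean is
#' numerically zero (|mean| < 1e-12) have no meaningful CV; they are
#' assigned `Inf` and flagged, and should be excluded from rankings.
#' The absolute mean is used because rows of a z-scored delta rank
#' matrix can have negative means.
#'
#' @param x Numeric matrix with at least 2 columns.
#' @return Named numeric vector of CVs with logical attribute
#'   `degenerate` marking near-zero-mean rows.
#' @export
coefficient_of_variation <- function(x) {
  if (inherits(x, "delta_rank_matrix")) x <- drm_layer(x, "normalized")
  if (ncol(x) < 2L)
    stop_degenerate("coefficient of variation needs at least 2 columns")
  mu <- rowMeans(x)
  s <- sqrt(row_vars(x))
  deg <- abs(mu) < 1e-12
  cv <- s / abs(mu)
  cv[deg] <- Inf
  names(cv) <- rownames(x)
  attr(cv, "degenerate") <- deg
  cv
}

#' Select top features by coefficient of variation
#'
#' As [top_variance_features()], with CV as the score; degenerate
#' (zero-mean) rows are excluded before ranking.
#'
#' @inheritParams top_variance_features
#' @return A `feature_selection` with `criterion = "cv"`.
#' @export
top_cv_features <- function(x, k = 500) {
  if (inherits(x, "delta_rank_matrix")) x <- drm_layer(x, "normalized")
  if (k < 1L) stop_validation("k must be >= 1")
  cv <- coefficient_of_variation(x)
  ok <- which(!attr(cv, "degenerate"))
  ord <- ok[order(-cv[ok])]
  ord <- ord[seq_len(min(k, length(ord)))]
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  structure(
    data.frame(feature_id = ids[ord], score = unname(cv[ord]),
               stringsAsFactors = FALSE),
    class = c("feature_selection", "data.frame"),
    k = k, criterion = "cv"
  )
}
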