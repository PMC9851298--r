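#' One-vs-rest Welch test per edge
#'
#' For each edge, compares its delta rank values in cells of type `type`
#' against all other cells with a two-sided unequal-variance (Welch)
#' t-test, the standard significant-difference analysis for marker
#' selection, applied here at the edge level. Degrees of freedom follow
#' Welch-Satterthwaite. Edges with zero variance in both groups get
#' t = 0, p = 1 when the group means agree (no information), and p = 0
#' when two constant groups differ (complete separation).
#'
#' @param drm A `delta_rank_matrix` or edges-by-cells matrix.
#' @param labels Per-cell type assignments (same order as the DRM
#'   columns, or named by cell ID).
#' @param type The cell type to contrast against the rest.
#' @param layer DRM layer to test, default `"normalized"`.
#' @return data.frame with columns `edge_id`, `t_statistic`, `df`,
#'   `p_value`, in edge order.
#' @export
marker_edge_test <- function(drm, labels, type, layer = c("normalized", "raw")) {
  x <- drm_layer(drm, match.arg(layer))
  labels <- align_labels(labels, colnames(x))
  in_t <- labels == type
  if (sum(in_t) < 2L || sum(!in_t) < 2L)
    abort_drm(sprintf(
      "type '%s' needs >= 2 cells on each side (has %d vs %d)",
      type, sum(in_t), sum(!in_t)
    ), "drm_insufficient_cells_error")
  w <- welch_rows(x[, in_t, drop = FALSE], x[, !in_t, drop = FALSE])
  data.frame(edge_id = rownames(x), t_statistic = w$t, df = w$df,
             p_value = w$p, stringsAsFactors = FALSE)
}

# Vectorized Welch t-test across rows: group 1 vs group 2.
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & diff == 0
    t[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    ne <- zero & diff != 0
    t[ne] <- sign(diff[ne]) * Inf; p[ne] <- 0; df[ne] <- NA_real_
  }
  list(t = t, df = df, p = p)
}

align_labels <- function(labels, cell_ids) {
  labels <- as_label_vector(labels)
  if (!is.null(names(labels)) && !is.null(cell_ids)) {
    if (!all(cell_ids %in% names(labels)))
      stop_validation("labels are missing some cell IDs")
    labels <- labels[cell_ids]
  } else if (!is.null(cell_ids) && length(labels) != length(cell_ids)) {
    stop_validation(sprintf("got %d labels for %d cells",
                            length(labels), length(cell_ids)))
  }
  unname(labels)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, monotone-enforced and
#' clipped to \[0, 1\], preserving input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_validation("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fold difference of mean delta ranks
#'
#' The marker-edge effect size: FD = |mean delta rank in type t - mean
#' delta rank outside t|, on the same layer as the test. Used to order
#' FDR-significant edges, largest first.
#'
#' @inheritParams marker_edge_test
#' @return Named numeric vector of FD values, named by edge ID.
#' @export
fold_change_fd <- function(drm, labels, type, layer = c("normalized", "raw")) {
  x <- drm_layer(drm, match.arg(layer))
  labels <- align_labels(labels, colnames(x))
  in_t <- labels == type
  if (!any(in_t)) stop_validation(sprintf("unknown cell type '%s'", type))
  fd <- abs(rowMeans(x[, in_t, drop = FALSE]) -
            rowMeans(x[, !in_t, drop = FALSE]))
  names(fd) <- rownames(x)
  fd
}

#' Select cell-type marker edges
#'
#' For every cell type: one-vs-rest Welch tests on all edges, BH-FDR
#' across edges, keep q < `q_threshold`, order by FD descending (ties by
#' edge order), take the top `k_per_type`. Per-type rows are all kept in
#' the table; an edge significant for several types appears once per
#' type but counts once in the combined unique edge set.
#'
#' @inheritParams marker_edge_test
#' @param k_per_type Edges kept per type (default 7).
#' @param q_threshold FDR threshold (default 0.01).
#' @return A `marker_edge_table`: data.frame with columns `edge_id`,
#'   `cell_type`, `t_statistic`, `p_value`, `q_value`, `fd`,
#'   `rank_within_type`; attribute `n_unique_edges` holds the combined
#'   count and `unique_edges` the IDs.
#' @export
select_marker_edges <- function(drm, labels, k_per_type = 7, q_threshold = 0.01,
                                layer = c("normalized", "raw")) {
  layer <- match.arg(layer)
  x <- drm_layer(drm, layer)
  labels <- align_labels(labels, colnames(x))
  types <- unique(labels)
  rows <- lapply(types, function(t) {
    tst <- marker_edge_test(x, labels, t, layer)
    q <- bh_fdr(tst$p_value)
    fd <- fold_change_fd(x, labels, t, layer)
    sig <- which(q < q_threshold)
    if (length(sig) == 0L) {
      warning(sprintf("no significant edges for type '%s' at FDR < %g",
                      t, q_threshold), call. = FALSE)
      return(NULL)
    }
    sig <- sig[order(-fd[sig])]     # stable: FD ties keep edge order
    sig <- sig[seq_len(min(k_per_type, length(sig)))]
    data.frame(
      edge_id = tst$edge_id[sig],
      cell_type = t,
      t_statistic = tst$t_statistic[sig],
      p_value = tst$p_value[sig],
      q_value = q[sig],
      fd = unname(fd[sig]),
      rank_within_type = seq_along(sig),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(edge_id = character(), cell_type = character(),
                      t_statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), fd = numeric(),
                      rank_within_type = integer(), stringsAsFactors = FALSE)
  uniq <- unique(out$edge_id)
  structure(out,
    class = c("marker_edge_table", "data.frame"),
    n_unique_edges = length(uniq),
    unique_edges = uniq
  )
}

#' @export
print.marker_edge_table <- function(x, ...) {
  cat(sprintf("marker edge table: %d rows over %d types; %d unique edges combined\n",
              nrow(x), length(unique(x$cell_type)), attr(x, "n_unique_edges")))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two sets drawn from a common universe -- e.g. marker
#' genes found via edges vs an independently published marker-gene list.
#'
#' @param set_a,set_b Character vectors (duplicates removed).
#' @param universe_size Size of the common universe.
#' @return P(X >= |intersection|), a single p-value.
#' @export
overlap_enrichment <- function(set_a, set_b, universe_size) {
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  if (length(a) > universe_size || length(b) > universe_size)
    stop_validation("set sizes exceed the universe size")
  k <- length(intersect(a, b))
  phyper(k - 1L, length(a), universe_size - length(a), length(b),
         lower.tail = FALSE)
}

#' Genes spanned by a set of marker edges
#'
#' @param edge_ids Character vector of `"GENEA|GENEB"` edge IDs.
#' @return Unique gene IDs appearing as an endpoint.
#' @export
marker_edge_genes <- function(edge_ids) {
  unique(unlist(strsplit(edge_ids, "|", fixed = TRUE), use.names = FALSE))
}
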