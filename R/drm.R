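#' Within-cell rank transform
#'
#' Converts an expression matrix into a rank matrix: within each cell
#' (column), genes are ranked by expression, smallest value = lowest
#' rank. All `m` genes are ranked, including undetected (zero) genes,
#' which share tied bottom ranks. With the default average ("fractional")
#' tie method, every column sums to `m(m+1)/2` exactly and any two
#' co-zero genes get identical ranks -- so a pair carrying no ordering
#' information contributes a delta rank of exactly 0.
#'
#' @param gem Numeric genes-by-cells matrix (gene IDs as row names).
#' @param ties_method Tie handling, as in [rank()]: `"average"`
#'   (default), `"min"`, `"max"` or `"first"`.
#' @return Numeric matrix of the same shape and dimnames, with attribute
#'   `tie_method`.
#' @examples
#' gem <- matrix(c(5, 1, 0, 3), 4, 1, dimnames = list(paste0("g", 1:4), "c1"))
#' rank_transform(gem)
#' @export
rank_transform <- function(gem, ties_method = c("average", "min", "max", "first")) {
  ties_method <- match.arg(ties_method)
  gem <- validate_gem(gem)
  r <- apply(gem, 2L, rank, ties.method = ties_method)
  storage.mode(r) <- "double"
  dimnames(r) <- dimnames(gem)
  attr(r, "tie_method") <- ties_method
  r
}

#' Per-edge delta ranks
#'
#' For every edge e = (g_i, g_j) of the background network, in its stored
#' orientation, computes the raw delta rank in each cell c:
#' Delta_{e,c} = r_{i,c} - r_{j,c}. The sign encodes which gene is more
#' highly expressed; the magnitude, how far apart they sit in the
#' within-cell ordering. Values lie in \[-(m-1), m-1\].
#'
#' @param ranks Rank matrix from [rank_transform()].
#' @param net A `background_network`; every endpoint must be present in
#'   `rownames(ranks)` (use [restrict_to_genes()] first).
#' @return Numeric edges-by-cells matrix; row names are `"GENEA|GENEB"`
#'   edge IDs in network order.
#' @export
delta_rank <- function(ranks, net) {
  net <- as_background_network(net)
  ia <- match(net$gene_a, rownames(ranks))
  ib <- match(net$gene_b, rownames(ranks))
  missing <- unique(c(net$gene_a[is.na(ia)], net$gene_b[is.na(ib)]))
  if (length(missing))
    abort_drm(sprintf(
      "network genes absent from the rank matrix (restrict_to_genes first): %s",
      paste(head(missing, 5L), collapse = ", ")
    ), "drm_missing_gene_error")
  raw <- ranks[ia, , drop = FALSE] - ranks[ib, , drop = FALSE]
  rownames(raw) <- edge_id_of(net$gene_a, net$gene_b)
  raw
}

#' Column-wise z-score normalization
#'
#' Standardizes each column (cell) of an edges-by-cells matrix:
#' `(X - mean(X)) / sd(X)` over the column's edges, with the sample
#' standard deviation (divisor `l - 1`). A zero-variance column maps to
#' all zeros.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return Matrix of the same shape; every non-constant column has mean 0
#'   and unit sample standard deviation.
#' @export
zscore_columns <- function(x) {
  if (nrow(x) < 2L)
    stop_degenerate("z-scoring needs at least 2 rows (edges) per column")
  mu <- colMeans(x)
  sdv <- col_sds(x)
  z <- sweep(x, 2L, mu)
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2L, sdv[nz], "/")
  z[, !nz] <- 0
  z
}

#' Build the delta rank matrix (DRM)
#'
#' The full transform: restrict the background network to the genes of
#' the expression matrix, rank genes within each cell, take per-edge rank
#' differences, and (by default) z-score each cell over its edges. The
#' raw layer is exactly invariant to any strictly increasing per-cell
#' transformation of the expression values, because only within-cell
#' orderings enter it.
#'
#' @param gem Numeric genes-by-cells expression matrix.
#' @param net Background network (cleaned with [clean_network()], or any
#'   two-column edge list, which is cleaned on the fly).
#' @param normalize Keep the per-cell z-scored layer (default `TRUE`).
#' @param ties_method Passed to [rank_transform()].
#' @return A `delta_rank_matrix` object: a list with elements `raw` and
#'   `normalized` (edges-by-cells matrices; `normalized` is `NULL` when
#'   `normalize = FALSE`), `edges` (the restricted `background_network`),
#'   `edge_ids`, `cell_ids`, `m` (genes ranked), `n` (cells), `l_before`
#'   and `l_after` (edge counts before/after restriction), `tie_method`,
#'   and `sd_divisor` (`"sample"`; the z-score uses `l - 1`).
#' @examples
#' gem <- matrix(rpois(40, 5), 4, 10,
#'               dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
#' net <- clean_network(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' build_drm(gem, net)
#' @export
build_drm <- function(gem, net, normalize = TRUE,
                      ties_method = c("average", "min", "max", "first")) {
  ties_method <- match.arg(ties_method)
  gem <- validate_gem(gem)
  net <- as_background_network(net)
  l_before <- nrow(net)
  net <- restrict_to_genes(net, rownames(gem))
  ranks <- rank_transform(gem, ties_method)
  raw <- delta_rank(ranks, net)
  normalized <- if (normalize) zscore_columns(raw) else NULL
  structure(list(
    raw = raw,
    normalized = normalized,
    edges = net,
    edge_ids = rownames(raw),
    cell_ids = colnames(raw),
    m = nrow(gem),
    n = ncol(gem),
    l_before = l_before,
    l_after = nrow(net),
    tie_method = ties_method,
    sd_divisor = "sample"
  ), class = "delta_rank_matrix")
}

#' Extract a layer from a delta rank matrix
#'
#' @param drm A `delta_rank_matrix`, or a plain edges-by-cells matrix
#'   (returned unchanged, so downstream functions also accept matrices
#'   read back from disk).
#' @param layer `"normalized"` or `"raw"`.
#' @return Numeric edges-by-cells matrix.
#' @export
drm_layer <- function(drm, layer = c("normalized", "raw")) {
  layer <- match.arg(layer)
  if (is.matrix(drm)) return(drm)
  if (!inherits(drm, "delta_rank_matrix"))
    stop_validation("expected a delta_rank_matrix or an edges-by-cells matrix")
  x <- drm[[layer]]
  if (is.null(x))
    stop_validation(sprintf(
      "layer '%s' not present (built with normalize = FALSE?)", layer))
  x
}

#' @export
print.delta_rank_matrix <- function(x, ...) {
  cat(sprintf("delta rank matrix: %d edges x %d cells\n", x$l_after, x$n))
  cat(sprintf("  from %d genes; network %d -> %d edges after restriction\n",
              x$m, x$l_before, x$l_after))
  cat(sprintf("  ties = %s; layers: raw%s\n", x$tie_method,
              if (is.null(x$normalized)) "" else " + normalized (per-cell z-score, sample sd)"))
  invisible(x)
}

#' @export
dim.delta_rank_matrix <- function(x) c(x$l_after, x$n)
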