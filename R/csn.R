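#' Monte-Carlo empirical null for delta ranks
#'
#' Generates the null distribution of a delta rank within one cell by
#' random shuffling: each draw picks an ordered pair of two distinct
#' gene positions uniformly from the cell's own rank vector and records
#' their rank difference. This is equivalent to shuffling the gene
#' labels and reading a fixed edge, so a single null serves every edge
#' of the cell, with the cell's ties included.
#'
#' @param rank_column Numeric vector of one cell's within-cell ranks
#'   (one column of [rank_transform()]).
#' @param n_shuffles Number of null draws (default 10000).
#' @param seed Integer seed for reproducibility (optional).
#' @param cell_id Optional cell identifier, stored for bookkeeping.
#' @return A `null_distribution`: list with `samples` (length
#'   `n_shuffles`), `n_shuffles`, `m`, `seed`, `source_cell`.
#' @export
empirical_null <- function(rank_column, n_shuffles = 10000, seed = NULL,
                           cell_id = NULL) {
  m <- length(rank_column)
  if (m < 2L) stop_degenerate("need at least 2 genes for a null distribution")
  if (n_shuffles < 1L) stop_validation("n_shuffles must be >= 1")
  samples <- with_seed(seed, {
    a <- sample.int(m, n_shuffles, replace = TRUE)
    # offset trick: b uniform over the m-1 positions different from a
    off <- sample.int(m - 1L, n_shuffles, replace = TRUE)
    b <- 1L + (a - 1L + off) %% m
    unname(rank_column[a] - rank_column[b])
  })
  structure(list(samples = samples, n_shuffles = n_shuffles, m = m,
                 seed = seed, source_cell = cell_id),
            class = "null_distribution")
}

#' Closed-form null pmf for tie-free ranks
#'
#' When the `m` ranks of a cell are all distinct, the rank difference of
#' a uniformly drawn ordered pair of distinct genes has
#' P(Delta = d) = (m - |d|) / (m (m - 1)) for d in
#' \{-(m-1), ..., -1, 1, ..., m-1\}. Serves as the exact reference for
#' the shuffle-based null.
#'
#' @param m Number of genes (>= 2).
#' @return data.frame with columns `delta` and `prob`; probabilities sum
#'   to 1.
#' @export
analytic_null_pmf <- function(m) {
  if (m < 2L) stop_validation("m must be >= 2")
  d <- setdiff(seq.int(-(m - 1L), m - 1L), 0L)
  data.frame(delta = d, prob = (m - abs(d)) / (m * (m - 1)))
}

#' Empirical two-sided p-value against a null distribution
#'
#' p = (#\{|sample| >= |observed|\} + 1) / (N + 1); the add-one rule
#' keeps p away from zero and corresponds to counting the observed value
#' as one more draw from its own null.
#'
#' @param delta_obs Observed delta rank(s); vectorized.
#' @param null A `null_distribution` from [empirical_null()].
#' @return Numeric vector of p-values in (0, 1\].
#' @export
empirical_pvalue <- function(delta_obs, null) {
  if (!inherits(null, "null_distribution"))
    stop_validation("null must be an empirical_null() result")
  sa <- sort(abs(null$samples))
  n <- length(sa)
  # count of |sample| >= |obs| = n - (count strictly below |obs|); ranks
  # are multiples of 0.5, so nudge by far less than the grid spacing
  below <- findInterval(abs(delta_obs) - 1e-9, sa)
  (n - below + 1) / (n + 1)
}

#' Cell-specific network for one cell
#'
#' Tests every background-network edge of one cell against the cell's
#' own shuffle-based empirical null and keeps the significant ones. The
#' test uses raw delta ranks and |Delta| (two-sided); within a cell,
#' z-scoring is an affine map and would give identical p-values. No
#' multiple-testing correction is applied within the cell; the threshold
#' is a raw p < `alpha`. Only the cell's own profile is needed -- no
#' reference cells.
#'
#' @param rank_column One cell's within-cell ranks, named by gene
#'   (a column of [rank_transform()]).
#' @param net A `background_network` restricted to the ranked genes.
#' @param n_shuffles Null draws (default 10000).
#' @param alpha Significance threshold on the empirical p (default 0.05).
#' @param seed Seed for the null (optional).
#' @param cell_id Optional cell identifier.
#' @return A `cell_specific_network`: list with `cell_id`, `edges`
#'   (data.frame `edge_id`, `delta`, `p_value`, all with p < alpha),
#'   `alpha`, `n_shuffles`, `seed`.
#' @export
cell_specific_network <- function(rank_column, net, n_shuffles = 10000,
                                  alpha = 0.05, seed = NULL, cell_id = NULL) {
  net <- as_background_network(net)
  if (is.null(names(rank_column)))
    stop_validation("rank_column must be named by gene ID")
  ia <- match(net$gene_a, names(rank_column))
  ib <- match(net$gene_b, names(rank_column))
  if (anyNA(ia) || anyNA(ib))
    abort_drm("network genes absent from the rank column", "drm_missing_gene_error")
  null <- empirical_null(rank_column, n_shuffles, seed, cell_id)
  delta <- unname(rank_column[ia] - rank_column[ib])
  p <- empirical_pvalue(delta, null)
  keep <- p < alpha
  structure(list(
    cell_id = cell_id,
    edges = data.frame(edge_id = edge_id_of(net$gene_a, net$gene_b)[keep],
                       delta = delta[keep], p_value = p[keep],
                       stringsAsFactors = FALSE),
    alpha = alpha, n_shuffles = n_shuffles, seed = seed
  ), class = "cell_specific_network")
}

#' @export
print.cell_specific_network <- function(x, ...) {
  cat(sprintf("cell-specific network%s: %d significant edges (p < %g, %d shuffles)\n",
              if (is.null(x$cell_id)) "" else sprintf(" [%s]", x$cell_id),
              nrow(x$edges), x$alpha, x$n_shuffles))
  invisible(x)
}

#' Cell-specific networks for many cells
#'
#' Convenience wrapper: rank-transforms an expression matrix and builds
#' one [cell_specific_network()] per requested cell. Each cell's null
#' gets its own seed derived from `seed` and the cell's column index, so
#' any subset of cells is reproducible independently.
#'
#' @param gem Genes-by-cells expression matrix.
#' @param net Background network (restricted internally).
#' @param cells Cell IDs to process (default: all).
#' @param n_shuffles,alpha,seed As in [cell_specific_network()].
#' @return Named list of `cell_specific_network` objects.
#' @export
cell_specific_networks <- function(gem, net, cells = NULL, n_shuffles = 10000,
                                   alpha = 0.05, seed = 1) {
  gem <- validate_gem(gem)
  net <- restrict_to_genes(as_background_network(net), rownames(gem))
  ranks <- rank_transform(gem)
  if (is.null(cells)) cells <- colnames(gem)
  idx <- match(cells, colnames(gem))
  if (anyNA(idx))
    stop_validation(sprintf("unknown cell IDs: %s",
                            paste(head(cells[is.na(idx)], 5L), collapse = ", ")))
  out <- lapply(seq_along(idx), function(i) {
    j <- idx[[i]]
    cell_specific_network(ranks[, j], net, n_shuffles, alpha,
                          seed = if (is.null(seed)) NULL else seed + j,
                          cell_id = colnames(gem)[[j]])
  })
  names(out) <- cells
  out
}

#' Cell-type network by mean delta rank
#'
#' Aggregates cell-level signal into a cell-type-specific network: for
#' each background edge, the mean raw delta rank over the cells of one
#' type.
#'
#' @param drm A `delta_rank_matrix` or raw edges-by-cells matrix.
#' @param labels Per-cell type assignments.
#' @param type Cell type to aggregate.
#' @return data.frame with columns `edge_id` and `mean_delta`, in edge
#'   order.
#' @export
cell_type_network <- function(drm, labels, type) {
  x <- drm_layer(drm, "raw")
  labels <- align_labels(labels, colnames(x))
  in_t <- labels == type
  if (!any(in_t)) stop_validation(sprintf("unknown cell type '%s'", type))
  data.frame(edge_id = rownames(x),
             mean_delta = rowMeans(x[, in_t, drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Edge occurrence fractions around a gene
#'
#' For every background edge incident to `gene`, the fraction of cells
#' whose cell-specific network contains that edge -- the "common
#' pattern" of a gene's interactions across a population.
#'
#' @param csns List of `cell_specific_network` objects.
#' @param gene Gene ID.
#' @param net The background network the CSNs were built from.
#' @return data.frame with columns `edge_id` and `fraction` in \[0, 1\].
#' @export
common_pattern <- function(csns, gene, net) {
  if (length(csns) == 0L) stop_validation("need at least one cell-specific network")
  net <- as_background_network(net)
  inc <- net$gene_a == gene | net$gene_b == gene
  if (!any(inc))
    stop_validation(sprintf("gene '%s' has no edges in the background network", gene))
  ids <- edge_id_of(net$gene_a, net$gene_b)[inc]
  counts <- Reduce(`+`, lapply(csns, function(csn)
    as.integer(ids %in% csn$edges$edge_id)))
  data.frame(edge_id = ids, fraction = counts / length(csns),
             stringsAsFactors = FALSE)
}
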