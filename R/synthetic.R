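#' Simulate expression data with ordering-encoded cell types
#'
#' Generates a genes-by-cells expression matrix whose cell-type signal
#' lives in within-cell relative orderings rather than in mean shifts.
#' All cells share baseline per-gene levels drawn from a heavy-tailed
#' (log-normal) distribution. Each planted marker edge (g_i, g_j) gets
#' endpoint levels at baseline quantiles `centre +/- 0.45 * effect`
#' (jittered centre near the median), so `effect` is the fraction of the
#' within-cell rank range the pair spans: at `effect = 1` the endpoints
#' straddle ~90% of the ranks, at `effect = 0` they coincide and no
#' signal is planted. In the edge's assigned cell type the two levels
#' are swapped, so the within-cell ordering of the pair -- and the sign
#' of its delta rank -- flips between the assigned type and all others,
#' while the pair's value set is identical in every type. Marker edges
#' are gene-disjoint across types by construction. Multiplicative
#' per-entry log-normal noise (`noise_sd`) perturbs every value; at the
#' defaults the planted ordering survives noise in essentially every
#' cell. Uniform dropout then zeroes a fraction of entries, creating the
#' tied-at-zero ranks typical of scRNA-seq. The background network is
#' the planted edges plus random filler pairs over the non-marker genes
#' (so the planted edges are exactly the differential truth set), in
#' shuffled order.
#'
#' @param n_types Number of cell types (default 3).
#' @param cells_per_type Cells per type (default 30).
#' @param n_genes Genes (default 200).
#' @param n_edges Total background-network edges, planted included
#'   (default 400).
#' @param n_marker_edges_per_type Planted differential edges per type
#'   (default 20); requires `2 * n_types * n_marker_edges_per_type <=
#'   n_genes` so planted edges are gene-disjoint.
#' @param effect Rank-displacement magnitude of a planted pair, as a
#'   fraction of the rank range (default 1.0); 0 plants no signal.
#' @param noise_sd SD of per-entry log-normal noise (default 0.3).
#' @param dropout_rate Fraction of entries zeroed uniformly at random,
#'   in \[0, 1) (default 0.3).
#' @param seed Integer seed; the whole output is a deterministic
#'   function of the arguments.
#' @return A list of class `drm_simulation`: `expression`
#'   (genes-by-cells matrix), `labels` (named character vector of cell
#'   types), `network` (a `background_network`), `marker_edges`
#'   (data.frame `edge_id`, `gene_a`, `gene_b`, `type` of planted
#'   edges), and `scenario` (the parameters).
#' @examples
#' sim <- simulate_gem(seed = 7)
#' dim(sim$expression)
#' table(sim$labels)
#' @export
simulate_gem <- function(n_types = 3, cells_per_type = 30, n_genes = 200,
                         n_edges = 400, n_marker_edges_per_type = 20,
                         effect = 1.0, noise_sd = 0.3, dropout_rate = 0.3,
                         seed = 1) {
  if (n_types < 1L || cells_per_type < 1L || n_genes < 2L || n_edges < 1L ||
      n_marker_edges_per_type < 0L)
    stop_validation("all counts must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_validation("dropout_rate must lie in [0, 1)")
  n_marker <- n_types * n_marker_edges_per_type
  if (2L * n_marker > n_genes)
    stop_validation(sprintf(
      "%d disjoint planted edges need %d genes but only %d are available",
      n_marker, 2L * n_marker, n_genes
    ))
  if (n_edges < n_marker)
    stop_validation("n_edges must be at least the number of planted edges")
  max_pairs <- n_genes * (n_genes - 1) / 2
  if (n_edges > max_pairs)
    stop_validation("more edges requested than distinct gene pairs exist")

  n_cells <- n_types * cells_per_type
  genes <- sprintf("G%04d", seq_len(n_genes))
  types <- sprintf("T%d", seq_len(n_types))
  cells <- sprintf("%s_c%03d", rep(types, each = cells_per_type),
                   seq_len(n_cells))
  labels <- stats::setNames(rep(types, each = cells_per_type), cells)

  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 1, sdlog = 1)
    names(base) <- genes

    # planted marker pairs: gene-disjoint, one block of pairs per type
    marker_genes <- sample(genes, 2L * n_marker)
    ga <- marker_genes[seq_len(n_marker) * 2L - 1L]
    gb <- marker_genes[seq_len(n_marker) * 2L]
    marker_type <- rep(types, each = n_marker_edges_per_type)
    # effect = fraction of the within-cell rank range the planted pair is
    # displaced across: endpoints sit at baseline-level quantiles
    # centre +/- 0.45 * effect (jittered centre, clamped), so effect = 1
    # spans ~90% of the ranks and effect = 0 plants no signal
    half_width <- min(0.465, 0.45 * effect)
    centre <- runif(n_marker, 0.47, 0.53)
    hi <- stats::qlnorm(pmin(0.995, centre + half_width), meanlog = 1, sdlog = 1)
    lo <- stats::qlnorm(pmax(0.005, centre - half_width), meanlog = 1, sdlog = 1)

    # per-type level matrix: baseline everywhere, planted pairs swapped
    # in their assigned type
    level <- matrix(base, n_genes, n_types, dimnames = list(genes, types))
    if (n_marker > 0L) {
      for (t in seq_len(n_types)) {
        own <- marker_type == types[[t]]
        level[ga, t] <- ifelse(own, lo, hi)
        level[gb, t] <- ifelse(own, hi, lo)
      }
    }

    x <- level[, rep(seq_len(n_types), each = cells_per_type), drop = FALSE]
    x <- x * exp(matrix(rnorm(n_genes * n_cells, 0, noise_sd), n_genes))
    if (dropout_rate > 0)
      x[matrix(runif(n_genes * n_cells) < dropout_rate, n_genes)] <- 0
    dimnames(x) <- list(genes, cells)

    # background network: planted edges + unique random fillers, shuffled.
    # Fillers avoid planted marker genes entirely: any edge touching a
    # swapped gene would itself be differential, and the generator's
    # contract is that the planted edges are exactly the truth set.
    pool <- setdiff(genes, marker_genes)
    n_fill <- n_edges - n_marker
    if (n_fill > 0L && length(pool) * (length(pool) - 1) / 2 < n_fill)
      stop_validation(sprintf(
        "%d filler edges requested but only %d non-marker gene pairs exist",
        n_fill, length(pool) * (length(pool) - 1) %/% 2
      ))
    key_of <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    ea <- ga; eb <- gb
    seen <- key_of(ea, eb)
    while (length(ea) < n_edges) {
      need <- n_edges - length(ea)
      ca <- sample(pool, 2L * need, replace = TRUE)
      cb <- sample(pool, 2L * need, replace = TRUE)
      ok <- ca != cb & !duplicated(key_of(ca, cb)) &
        !(key_of(ca, cb) %in% seen)
      ea <- c(ea, ca[ok][seq_len(min(need, sum(ok)))])
      eb <- c(eb, cb[ok][seq_len(min(need, sum(ok)))])
      seen <- key_of(ea, eb)
    }
    ord <- sample.int(n_edges)
    net <- clean_network(data.frame(gene_a = ea[ord], gene_b = eb[ord],
                                    stringsAsFactors = FALSE))

    structure(list(
      expression = x,
      labels = labels,
      network = net,
      marker_edges = data.frame(
        edge_id = edge_id_of(ga, gb), gene_a = ga, gene_b = gb,
        type = marker_type, stringsAsFactors = FALSE
      ),
      scenario = list(
        n_types = n_types, cells_per_type = cells_per_type,
        n_genes = n_genes, n_edges = n_edges,
        n_marker_edges_per_type = n_marker_edges_per_type,
        effect = effect, noise_sd = noise_sd,
        dropout_rate = dropout_rate, seed = seed
      )
    ), class = "drm_simulation")
  })
}

#' @export
print.drm_simulation <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "synthetic scRNA-seq scenario: %d genes x %d cells (%d types x %d)\n",
    s$n_genes, s$n_types * s$cells_per_type, s$n_types, s$cells_per_type))
  cat(sprintf("  network: %d edges, %d planted marker edges per type\n",
              s$n_edges, s$n_marker_edges_per_type))
  cat(sprintf("  effect = %g, noise_sd = %g, dropout = %g, seed = %d\n",
              s$effect, s$noise_sd, s$dropout_rate, s$seed))
  invisible(x)
}

#' Apply a strictly increasing distortion to an expression matrix
#'
#' Transforms expression values with a monotone map -- log1p, affine
#' (`scale * x + shift`, `scale > 0`) or power (`x^exponent`,
#' `exponent > 0`) -- optionally with distinct parameters per cell.
#' Because every map is strictly increasing on \[0, Inf), within-cell
#' orderings, hence the raw delta rank matrix, are exactly unchanged.
#' This emulates cross-cell/cross-platform scale distortions
#' (library-size, normalization choices) that corrupt absolute values
#' but not orderings.
#'
#' @param gem Genes-by-cells matrix.
#' @param kind `"log1p"`, `"affine"` or `"power"`.
#' @param params List of parameters: `scale`/`shift` for affine,
#'   `exponent` for power. Scalars apply globally; with `per_cell =
#'   TRUE`, vectors of length `ncol(gem)` give each cell its own
#'   parameter.
#' @param per_cell Allow per-cell parameter vectors (default `FALSE`).
#' @return The distorted matrix, same shape and dimnames.
#' @export
apply_monotone_distortion <- function(gem, kind = c("log1p", "affine", "power"),
                                      params = list(), per_cell = FALSE) {
  kind <- match.arg(kind)
  gem <- validate_gem(gem)
  n <- ncol(gem)
  get_par <- function(name, default) {
    v <- params[[name]]
    if (is.null(v)) v <- default
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n)
      stop_validation(sprintf("parameter '%s' must be scalar or length n", name))
    if (!per_cell && length(unique(v)) > 1L)
      stop_validation("per-cell parameters require per_cell = TRUE")
    v
  }
  out <- switch(kind,
    log1p = log1p(gem),
    affine = {
      sc <- get_par("scale", 1); sh <- get_par("shift", 0)
      if (any(sc <= 0))
        stop_validation("affine scale must be > 0 for a strictly increasing map")
      sweep(sweep(gem, 2L, sc, "*"), 2L, sh, "+")
    },
    power = {
      ex <- get_par("exponent", 1)
      if (any(ex <= 0))
        stop_validation("power exponent must be > 0 for a strictly increasing map")
      sweep(gem, 2L, ex, "^")
    }
  )
  dimnames(out) <- dimnames(gem)
  out
}
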