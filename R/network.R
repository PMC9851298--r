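#' Clean a raw edge list into a background network
#'
#' The background network is an a-priori set of gene-gene interaction
#' edges (pathway-derived in typical use) that defines which gene pairs
#' become rows of the delta rank matrix. Cleaning removes self-loops and
#' collapses duplicate unordered pairs, keeping the first occurrence's
#' orientation. Orientation matters downstream: the delta rank of edge
#' (g_i, g_j) is r_i - r_j, so flipping an edge flips the sign of its
#' whole row. The first-seen orientation is the canonical one.
#'
#' @param raw A two-column data.frame or matrix of gene pairs (e.g. from
#'   [read_network()]), or a list of length-2 character vectors.
#' @return A `background_network`: a data.frame with columns `gene_a`,
#'   `gene_b` and attributes `n_self_loops` and `n_duplicates` recording
#'   what was removed.
#' @examples
#' clean_network(data.frame(gene_a = c("A", "B", "C", "A"),
#'                          gene_b = c("B", "A", "C", "B")))
#' @export
clean_network <- function(raw) {
  raw <- as_edge_frame(raw)
  if (nrow(raw) == 0L) stop_validation("raw edge list is empty")
  self <- raw$gene_a == raw$gene_b
  kept <- raw[!self, , drop = FALSE]
  key <- paste(pmin(kept$gene_a, kept$gene_b), pmax(kept$gene_a, kept$gene_b),
               sep = "\r")
  dup <- duplicated(key)
  net <- kept[!dup, , drop = FALSE]
  if (nrow(net) == 0L)
    stop_empty_net("no edges remain after removing self-loops and duplicates")
  rownames(net) <- NULL
  structure(net,
    class = c("background_network", "data.frame"),
    n_self_loops = sum(self),
    n_duplicates = sum(dup)
  )
}

as_edge_frame <- function(raw) {
  if (is.list(raw) && !is.data.frame(raw)) {
    raw <- do.call(rbind, lapply(raw, function(p) {
      if (length(p) < 2L) stop_format("each raw edge needs two genes")
      data.frame(gene_a = as.character(p[[1L]]), gene_b = as.character(p[[2L]]),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.matrix(raw)) raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (!is.data.frame(raw) || ncol(raw) < 2L)
    stop_format("edge list must have at least two columns")
  out <- data.frame(gene_a = as.character(raw[[1L]]),
                    gene_b = as.character(raw[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out) ) stop_validation("edge list contains missing gene IDs")
  out
}

#' Restrict a background network to a gene universe
#'
#' Keeps exactly the edges whose both endpoints occur in `genes`
#' (typically the row names of an expression matrix), preserving edge
#' order and orientation. Required before [delta_rank()] so that every
#' retained edge has defined endpoint ranks.
#'
#' @param net A `background_network` from [clean_network()].
#' @param genes Character vector of gene IDs.
#' @return A `background_network` with attribute `n_dropped`.
#' @export
restrict_to_genes <- function(net, genes) {
  net <- as_background_network(net)
  if (length(genes) == 0L) stop_validation("gene universe is empty")
  keep <- net$gene_a %in% genes & net$gene_b %in% genes
  out <- net[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_empty_net("no network edge has both endpoints in the gene universe")
  rownames(out) <- NULL
  structure(out,
    class = c("background_network", "data.frame"),
    n_self_loops = attr(net, "n_self_loops"),
    n_duplicates = attr(net, "n_duplicates"),
    n_dropped = sum(!keep)
  )
}

as_background_network <- function(net) {
  if (inherits(net, "background_network")) return(net)
  clean_network(net)
}

#' @export
print.background_network <- function(x, ...) {
  cat(sprintf("background network: %d edges over %d genes\n",
              nrow(x), length(unique(c(x$gene_a, x$gene_b)))))
  rm_s <- attr(x, "n_self_loops"); rm_d <- attr(x, "n_duplicates")
  if (!is.null(rm_s))
    cat(sprintf("  cleaned: %d self-loops, %d duplicate pairs removed\n", rm_s, rm_d))
  if (!is.null(attr(x, "n_dropped")))
    cat(sprintf("  restricted: %d edges dropped outside gene universe\n",
                attr(x, "n_dropped")))
  invisible(x)
}

#' Write a cleaned background network as TSV
#'
#' Emits a `gene_a`/`gene_b` TSV with a provenance comment header noting
#' the edge count and the orientation convention.
#'
#' @param net A `background_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  net <- as_background_network(net)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# deltarank background network: %d edges", nrow(net)),
    "# orientation = first-seen in source; delta rank sign follows it",
    "gene_a\tgene_b"
  ), con)
  write.table(as.data.frame(net), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
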