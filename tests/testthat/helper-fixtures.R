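# Small in-code fixtures shared across test files.

tiny_gem <- function(m = 6, n = 4, seed = 42, with_ties = FALSE) {
  set.seed(seed)
  x <- matrix(rlnorm(m * n), m, n,
              dimnames = list(paste0("g", seq_len(m)), paste0("c", seq_len(n))))
  if (with_ties) x[sample(length(x), ceiling(length(x) / 3))] <- 0
  x
}

tiny_net <- function(gene_a, gene_b) {
  clean_network(data.frame(gene_a = gene_a, gene_b = gene_b,
                           stringsAsFactors = FALSE))
}

# Dense expression TSV on disk; returns the path.
write_dense_fixture <- function(x, path = tempfile(fileext = ".tsv"),
                                sep = "\t", corner = TRUE) {
  header <- paste(c(if (corner) "gene" else NULL, colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 17)), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

random_partition <- function(n, k) sample.int(k, n, replace = TRUE)

# Edge columns only, ignoring bookkeeping attributes.
edges_df <- function(net) {
  data.frame(gene_a = net$gene_a, gene_b = net$gene_b,
             stringsAsFactors = FALSE)
}
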