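# Classed error conditions so callers (and the CLI) can distinguish
# user-input problems from internal failures.
abort_drm <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
    class = c(class, "deltarank_error", "error", "condition"),
    call = call
  ))
}

stop_validation <- function(message) abort_drm(message, "drm_validation_error")
stop_format     <- function(message) abort_drm(message, "drm_format_error")
stop_degenerate <- function(message) abort_drm(message, "drm_degenerate_error")
stop_empty_net  <- function(message) abort_drm(message, "drm_empty_network_error")

# Run code under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Sample variance per row without forming an apply() loop.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1L)
}

col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(colSums(sweep(x, 2L, mu)^2) / (n - 1L))
}

edge_id_of <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "|")

as_label_vector <- function(labels, cell_ids = NULL) {
  labels <- as.character(labels)
  if (!is.null(cell_ids)) {
    if (length(labels) != length(cell_ids))
      stop_validation(sprintf(
        "labels length (%d) does not match number of cells (%d)",
        length(labels), length(cell_ids)
      ))
  }
  if (anyNA(labels)) stop_validation("labels contain missing values")
  labels
}
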