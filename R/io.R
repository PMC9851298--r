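#' Read a genes-by-cells expression matrix
#'
#' Reads either a dense delimited table (header row of cell IDs, leading
#' column of gene IDs; comma or tab delimiter sniffed from the header
#' line) or a Matrix Market coordinate file with gene/barcode sidecar
#' files in CellRanger style (`genes.tsv`/`features.tsv` and
#' `barcodes.tsv` next to the `.mtx`, or given explicitly).
#'
#' The returned matrix is validated: at least 2 genes and 1 cell, unique
#' gene identifiers, and all values finite and non-negative. Gene and cell
#' identifiers are opaque, case-sensitive strings; no symbol mapping is
#' attempted.
#'
#' @param path Path to the matrix file.
#' @param layout `"auto"` (default; `.mtx` extension selects the sparse
#'   reader), `"dense"` or `"mtx"`.
#' @param genes,barcodes Optional explicit sidecar paths for the `mtx`
#'   layout. When `NULL`, `genes.tsv` (or `features.tsv`) and
#'   `barcodes.tsv` are looked up in the directory of `path`.
#' @return A numeric matrix with gene IDs as row names and cell IDs as
#'   column names. Entries absent from a sparse file are zero.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "g1\t0\t5", "g2\t2\t1"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path, layout = c("auto", "dense", "mtx"),
                            genes = NULL, barcodes = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (layout == "auto") {
    layout <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  x <- switch(layout,
    dense = read_dense_matrix(path),
    mtx   = read_mtx_matrix(path, genes, barcodes)
  )
  validate_gem(x)
}

read_dense_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop_format(sprintf("empty file: %s", path))
  delim <- sniff_delim(header)
  cells <- strsplit(header, delim, fixed = TRUE)[[1]]
  body <- read.table(path, sep = delim, header = FALSE, skip = 1L,
                     stringsAsFactors = FALSE, check.names = FALSE,
                     quote = "\"", comment.char = "")
  if (ncol(body) < 2L)
    stop_format("dense matrix must have a gene-ID column and at least one cell column")
  n_cells <- ncol(body) - 1L
  # header may or may not carry a corner label above the gene-ID column
  if (length(cells) == n_cells + 1L) cells <- cells[-1L]
  if (length(cells) != n_cells)
    stop_format(sprintf(
      "header declares %d cell IDs but data rows have %d value columns",
      length(cells), n_cells
    ))
  gene_ids <- as.character(body[[1L]])
  vals <- as.matrix(body[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_format("non-numeric expression values")
  dimnames(vals) <- list(gene_ids, cells)
  vals
}

sniff_delim <- function(line) {
  n_tab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  n_com <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

read_mtx_matrix <- function(path, genes = NULL, barcodes = NULL) {
  dir <- dirname(path)
  if (is.null(genes)) {
    for (cand in c("genes.tsv", "features.tsv")) {
      if (file.exists(file.path(dir, cand))) { genes <- file.path(dir, cand); break }
    }
  }
  if (is.null(barcodes) && file.exists(file.path(dir, "barcodes.tsv")))
    barcodes <- file.path(dir, "barcodes.tsv")
  if (is.null(genes) || is.null(barcodes))
    stop_format("mtx layout requires genes.tsv/features.tsv and barcodes.tsv sidecars")
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop_format(sprintf("invalid Matrix Market file: %s",
                                                        conditionMessage(e))))
  gene_ids <- read_id_column(genes)
  cell_ids <- read_id_column(barcodes)
  if (length(gene_ids) != nrow(m))
    stop_format(sprintf("gene sidecar has %d IDs but matrix declares %d rows",
                        length(gene_ids), nrow(m)))
  if (length(cell_ids) != ncol(m))
    stop_format(sprintf("barcode sidecar has %d IDs but matrix declares %d columns",
                        length(cell_ids), ncol(m)))
  m <- as.matrix(m)
  dimnames(m) <- list(gene_ids, cell_ids)
  m
}

# First tab-separated token of each line (CellRanger gene files carry
# a second symbol column).
read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

validate_gem <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop_validation("expression matrix needs at least 2 genes")
  if (ncol(x) < 1L) stop_validation("expression matrix needs at least 1 cell")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_validation("expression matrix must carry gene and cell identifiers")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop_validation(sprintf("duplicate gene IDs: %s",
                            paste(unique(dup), collapse = ", ")))
  if (anyDuplicated(colnames(x)))
    stop_validation("duplicate cell IDs")
  if (any(!is.finite(x))) stop_validation("expression values must be finite")
  if (any(x < 0)) stop_validation("expression values must be non-negative")
  x
}

#' Read a raw gene-pair edge list
#'
#' Reads a delimited text file with at least two columns (extra columns
#' are ignored) into an ordered list of gene pairs, in file order. A
#' header line is skipped when its first two fields look like column
#' names (`gene_a`/`gene_b`, `from`/`to`, `source`/`target`,
#' `node1`/`node2`). Lines starting with `#` are comments. No cleaning is
#' performed; pass the result to [clean_network()].
#'
#' @param path Path to the edge-list file.
#' @return A two-column character `data.frame` (`gene_a`, `gene_b`); zero
#'   rows for an empty file.
#' @seealso [clean_network()], [restrict_to_genes()]
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  delim <- sniff_delim(lines[[1L]])
  fields <- strsplit(lines, delim, fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop_format(sprintf("line %d has fewer than two columns", short[[1L]]))
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  hdr <- c("gene_a gene_b", "from to", "source target", "node1 node2")
  if (tolower(paste(a[1L], b[1L])) %in% hdr) {
    a <- a[-1L]; b <- b[-1L]
  }
  data.frame(gene_a = trimws(a), gene_b = trimws(b), stringsAsFactors = FALSE)
}

#' Write a delta rank matrix to disk
#'
#' Serializes one layer of a [build_drm()] result (or any edges-by-cells
#' matrix with `GENEA|GENEB` row names). The dense layout is a TSV with
#' an `edge_id` leading column and cell IDs in the header; the `mtx`
#' layout writes a Matrix Market coordinate file plus `<stem>.rows.tsv` /
#' `<stem>.cols.tsv` sidecars.
#'
#' @param drm A `delta_rank_matrix` from [build_drm()] or a numeric
#'   matrix with edge-ID row names.
#' @param path Output path.
#' @param layer `"normalized"` (default) or `"raw"`; ignored when `drm`
#'   is already a plain matrix.
#' @param layout `"dense"` (default) or `"mtx"`.
#' @return Invisibly, `path`.
#' @export
write_delta_rank <- function(drm, path, layer = c("normalized", "raw"),
                             layout = c("dense", "mtx")) {
  layout <- match.arg(layout)
  x <- drm_layer(drm, match.arg(layer))
  if (nrow(x) == 0L) stop_validation("delta rank matrix is empty")
  genes <- unlist(strsplit(rownames(x), "|", fixed = TRUE), use.names = FALSE)
  # edge IDs are "A|B"; a "|" inside a gene symbol would be unrecoverable
  if (length(genes) != 2L * nrow(x))
    stop_validation("gene identifiers must not contain the '|' edge delimiter")
  if (layout == "dense") {
    out <- data.frame(edge_id = rownames(x), x, check.names = FALSE,
                      stringsAsFactors = FALSE)
    ok <- tryCatch({
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort_drm(sprintf("cannot write to %s", path), "drm_io_error")
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(x), paste0(stem, ".rows.tsv"))
    writeLines(colnames(x), paste0(stem, ".cols.tsv"))
  }
  invisible(path)
}

#' Read a delta rank matrix written by [write_delta_rank()]
#'
#' @param path Path to the dense TSV or `.mtx` file.
#' @return A numeric edges-by-cells matrix with edge-ID row names.
#' @export
read_delta_rank <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", path)
    x <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(stem, ".rows.tsv"))
    cols <- readLines(paste0(stem, ".cols.tsv"))
    if (length(rows) != nrow(x) || length(cols) != ncol(x))
      stop_format("sidecar lengths do not match matrix dimensions")
    dimnames(x) <- list(rows, cols)
    return(x)
  }
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
  x <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(x) <- tab[[1L]]
  x
}

#' Read a cell-label table
#'
#' Two-column delimited file (`cell_id`, `type`), with or without a
#' header.
#'
#' @param path Path to the label file.
#' @return A named character vector of types, named by cell ID.
#' @export
read_labels <- function(path) {
  tab <- read_network(path)  # same two-column contract
  lab <- tab[[2L]]
  names(lab) <- tab[[1L]]
  if (length(lab) && tolower(lab[[1L]]) %in% c("type", "label", "cluster") &&
      tolower(names(lab)[[1L]]) %in% c("cell_id", "cell", "barcode"))
    lab <- lab[-1L]
  lab
}
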