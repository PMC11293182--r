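#' Gene-by-cell count container
#'
#' Wraps a cells-by-genes UMI count matrix (stored sparse) together with
#' optional per-cell type labels and a provenance record of the processing
#' steps applied so far. All pipeline stages consume and return this class.
#'
#' @param counts Numeric matrix or sparse `Matrix`, cells in rows and genes
#'   in columns, with unique row (cell) and column (gene) names. Entries
#'   must be non-negative; raw UMI counts unless noted in `provenance`.
#' @param labels Optional character vector of per-cell type annotations,
#'   length `nrow(counts)`, in row order.
#' @param provenance Optional list recording applied processing steps.
#' @return An object of class `sc_counts`.
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' x <- sc_counts(m, labels = c("A", "A", "B"))
#' dim(x)
#' @export
sc_counts <- function(counts, labels = NULL, provenance = list()) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have cell (row) and gene (column) names")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate cell ids in `counts`")
  if (anyDuplicated(colnames(counts)))
    abort("duplicate gene ids in `counts`")
  if (any(counts@x < 0)) abort("`counts` must be non-negative")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(counts))
      abort("`labels` must have one entry per cell")
    names(labels) <- rownames(counts)
  }
  structure(
    list(counts = counts, labels = labels, provenance = provenance),
    class = "sc_counts"
  )
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("labels:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
        "\n")
  }
  if (length(x$provenance))
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.sc_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  cnt <- x$counts[i, j, drop = FALSE]
  lab <- if (!is.null(x$labels)) unname(x$labels[rownames(cnt)]) else NULL
  sc_counts(cnt, labels = lab, provenance = x$provenance)
}

#' Cell type labels of an `sc_counts` object
#' @param x An `sc_counts` object.
#' @return Named character vector of labels, or `NULL`.
#' @export
cell_labels <- function(x) {
  stopifnot(is(x, "sc_counts"))
  x$labels
}

#' Read a 10x Genomics MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or the older
#' `genes.tsv`), optionally gzip-compressed. Per the 10x convention genes
#' are stored as matrix rows; the result is transposed to cells x genes.
#'
#' @param dir Directory containing the triplet files.
#' @param gene_column Column of the feature file to use as gene id
#'   (default 1, the feature id; 2 gives the symbol).
#' @return An [sc_counts] object with raw counts.
#' @export
read_counts_10x <- function(dir, gene_column = 1) {
  pick <- function(...) {
    cands <- file.path(dir, c(...))
    hit <- cands[file.exists(cands)]
    if (!length(hit))
      abort(paste0("none of ", paste(basename(cands), collapse = "/"),
                   " found in ", dir))
    hit[[1]]
  }
  mtx <- pick("matrix.mtx", "matrix.mtx.gz")
  bc <- pick("barcodes.tsv", "barcodes.tsv.gz")
  ft <- pick("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz")
  open_maybe_gz <- function(p) if (grepl("\\.gz$", p)) gzfile(p) else p
  m <- Matrix::readMM(open_maybe_gz(mtx))
  barcodes <- readr::read_tsv(bc, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  feats <- readr::read_tsv(ft, col_names = FALSE, show_col_types = FALSE)
  genes <- feats[[min(gene_column, ncol(feats))]]
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
    abort("matrix dimensions do not match feature/barcode files")
  genes <- make.unique(as.character(genes))
  dimnames(m) <- list(genes, barcodes)
  sc_counts(Matrix::t(m), provenance = list(source = mtx))
}

#' Write an `sc_counts` object as a 10x-style MatrixMarket triplet
#'
#' Writes uncompressed `matrix.mtx` (genes x cells), `features.tsv`,
#' `barcodes.tsv`, and — when labels are present — `truth.tsv` with the
#' per-cell type annotation.
#'
#' @param x An [sc_counts] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(x, dir) {
  stopifnot(is(x, "sc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  g <- colnames(x$counts)
  readr::write_tsv(tibble(id = g, symbol = g),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = rownames(x$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  if (!is.null(x$labels))
    readr::write_tsv(tibble(cell = rownames(x$counts),
                            label = unname(x$labels)),
                     file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a dense cells-by-genes count table (CSV or TSV)
#'
#' First column holds cell ids, header row holds gene ids. The delimiter
#' is inferred from the file extension (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path Path to the delimited file.
#' @param labels Optional per-cell labels (recycled onto the rows read).
#' @return An [sc_counts] object.
#' @export
read_counts_csv <- function(path, labels = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  sc_counts(m, labels = labels, provenance = list(source = path))
}
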