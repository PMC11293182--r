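#' Filter low-quality cells and rarely detected genes
#'
#' Cells are filtered first (a cell is kept when it expresses at least
#' `min_genes_per_cell` genes), then genes (a gene is kept when it is
#' detected in at least `min_cells_per_gene` of the remaining cells and,
#' for spatial data, in at least `min_spot_fraction` of them). Both
#' thresholds are inclusive: the conventional "fewer than 200 genes"
#' exclusion corresponds to `min_genes_per_cell = 200`.
#'
#' @param x An [sc_counts] object with raw counts.
#' @param min_genes_per_cell Minimum detected genes per retained cell.
#' @param min_cells_per_gene Minimum cells in which a retained gene is
#'   detected.
#' @param min_spot_fraction Optional minimum fraction of (retained) cells
#'   or spots in which a gene must be detected; used for spatial data.
#' @return The filtered [sc_counts]; labels are subset accordingly and the
#'   filter parameters are recorded in provenance.
#' @export
filter_cells_genes <- function(x, min_genes_per_cell = 200,
                               min_cells_per_gene = 3,
                               min_spot_fraction = NULL) {
  stopifnot(is(x, "sc_counts"),
            min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  if (!is.null(min_spot_fraction))
    stopifnot(min_spot_fraction >= 0, min_spot_fraction <= 1)
  detected <- x$counts > 0
  keep_cells <- Matrix::rowSums(detected) >= min_genes_per_cell
  if (!any(keep_cells)) abort("no cells survive filters")
  det_g <- Matrix::colSums(detected[keep_cells, , drop = FALSE])
  keep_genes <- det_g >= min_cells_per_gene
  if (!is.null(min_spot_fraction))
    keep_genes <- keep_genes & det_g >= min_spot_fraction * sum(keep_cells)
  if (!any(keep_genes)) abort("no genes survive filters")
  out <- x[keep_cells, keep_genes]
  out$provenance <- c(out$provenance, list(filter = list(
    min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene,
    min_spot_fraction = min_spot_fraction,
    order = "cells_then_genes",
    n_cells_removed = sum(!keep_cells),
    n_genes_removed = sum(!keep_genes)
  )))
  out
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (default 10,000 UMIs) and
#' applies `log1p`, the standard log-normalization for UMI data.
#'
#' @param x An [sc_counts] object; no cell may have zero total counts.
#' @param scale_total Target per-cell total before the log transform.
#' @return An [sc_counts] with normalized values and
#'   `provenance$normalized` set.
#' @export
normalize_log <- function(x, scale_total = 1e4) {
  stopifnot(is(x, "sc_counts"), scale_total > 0)
  tot <- Matrix::rowSums(x$counts)
  if (any(tot == 0))
    abort(paste0("cell(s) with zero counts: ",
                 paste(utils::head(rownames(x$counts)[tot == 0], 5),
                       collapse = ", ")))
  m <- Diagonal(x = scale_total / tot) %*% x$counts
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(x$counts)
  out <- sc_counts(m, labels = unname(x$labels), provenance = x$provenance)
  out$provenance$normalized <- list(scale_total = scale_total,
                                    transform = "log1p")
  out
}

# per-gene mean and variance of a cells x genes sparse matrix
sparse_col_stats <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colSums(m) / n
  v <- (Matrix::colSums(m^2) - n * mu^2) / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Highly variable gene selection (vst)
#'
#' Ranks genes by standardized variance computed on raw counts: expected
#' `log10` variance is fit as a loess (span 0.3) function of `log10` mean
#' across genes, each gene's values are standardized by its fitted
#' standard deviation with per-value clipping at `sqrt(n_cells)`, and
#' genes are ranked by the variance of the clipped standardized values.
#' Constant genes have standardized variance zero and rank last.
#'
#' @param x An [sc_counts] object with raw (untransformed) counts.
#' @param n_hvg Number of genes to return.
#' @param loess_span Span of the mean-variance loess fit.
#' @return Character vector of `n_hvg` gene ids, most variable first.
#' @export
select_hvg_vst <- function(x, n_hvg = 2000, loess_span = 0.3) {
  stopifnot(is(x, "sc_counts"))
  m <- x$counts
  if (n_hvg > ncol(m)) abort("`n_hvg` exceeds the number of genes")
  n <- nrow(m)
  st <- sparse_col_stats(m)
  varstd <- numeric(ncol(m))
  ok <- st$var > 0
  if (any(ok)) {
    fit <- loess(log10(v) ~ log10(mu),
                 data = data.frame(v = st$var[ok], mu = st$mean[ok]),
                 span = loess_span, degree = 2)
    sd_exp <- sqrt(10^fitted(fit))
    clip <- sqrt(n)
    # sum of squared clipped z-scores per gene, using sparsity: zeros of a
    # gene all standardize to -mu/sd (never clipped upward)
    mt <- as(m[, ok, drop = FALSE], "TsparseMatrix")
    mu <- st$mean[ok]
    j <- mt@j + 1L
    z <- pmin((mt@x - mu[j]) / sd_exp[j], clip)
    ssq_nz <- tapply_sum(z^2, j, length(mu))
    nnz <- tapply_sum(rep(1, length(j)), j, length(mu))
    z0 <- pmin(-mu / sd_exp, clip)
    varstd[ok] <- (ssq_nz + (n - nnz) * z0^2) / (n - 1)
  }
  ord <- order(-varstd)
  colnames(m)[ord[seq_len(n_hvg)]]
}

# grouped sum over integer bins 1..nbins (0 where empty)
tapply_sum <- function(x, bin, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Low-dimensional embedding container
#'
#' Cells-by-components coordinate matrix produced by [pca_embed()] (or
#' supplied externally) on which all neighbor distances are computed.
#'
#' @param coords Numeric matrix, cells x components, with cell row names.
#' @param provenance Optional list describing how it was computed.
#' @return An object of class `sc_embedding`.
#' @export
sc_embedding <- function(coords, provenance = list()) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) abort("`coords` must have cell row names")
  if (ncol(coords) < 2) abort("embedding needs at least 2 components")
  if (!all(is.finite(coords))) abort("embedding must be finite")
  if (is.null(colnames(coords)))
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coords = coords, provenance = provenance),
            class = "sc_embedding")
}

#' @export
dim.sc_embedding <- function(x) dim(x$coords)

#' @export
print.sc_embedding <- function(x, ...) {
  cat(sprintf("<sc_embedding> %d cells x %d components\n",
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' PCA embedding of normalized expression
#'
#' Restricts to the given highly variable genes, centers and scales each
#' gene to unit variance (clipping scaled values at +10), and projects
#' onto the top principal components by SVD. Component signs are fixed by
#' making the largest-magnitude gene loading of each component positive,
#' so results are reproducible across platforms.
#'
#' @param x An [sc_counts] object, normally log-normalized.
#' @param hvg Character vector of gene ids to use (subset of the genes).
#' @param n_pcs Number of principal components (must not exceed
#'   `min(n_cells, length(hvg))`).
#' @param clip_max Upper clip applied to scaled values before the SVD.
#' @return An [sc_embedding] whose provenance records component standard
#'   deviations and a `rank_deficient` flag when fewer informative
#'   components exist than requested.
#' @export
pca_embed <- function(x, hvg, n_pcs = 50, clip_max = 10) {
  stopifnot(is(x, "sc_counts"))
  if (!all(hvg %in% colnames(x$counts)))
    abort("`hvg` contains genes absent from the matrix")
  n <- nrow(x$counts)
  if (n_pcs > min(n, length(hvg)))
    abort("`n_pcs` exceeds min(n_cells, n_hvg)")
  z <- as.matrix(x$counts[, hvg, drop = FALSE])
  mu <- colMeans(z)
  sdv <- apply(z, 2, stats::sd)
  z <- sweep(z, 2, mu)
  pos <- sdv > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sdv[pos], "/")
  z[, !pos] <- 0
  z[z > clip_max] <- clip_max
  sv <- svd(z, nu = n_pcs, nv = n_pcs)
  d <- sv$d[seq_len(n_pcs)]
  rank_def <- sum(d > max(sv$d[1], .Machine$double.eps) * 1e-10) < n_pcs
  # deterministic sign: dominant loading of each component positive
  for (c in seq_len(n_pcs)) {
    ld <- sv$v[, c]
    if (ld[which.max(abs(ld))] < 0) {
      sv$u[, c] <- -sv$u[, c]
    }
  }
  scores <- sv$u %*% diag(d, nrow = n_pcs)
  rownames(scores) <- rownames(x$counts)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  sc_embedding(scores, provenance = c(x$provenance, list(pca = list(
    n_pcs = n_pcs, n_hvg = length(hvg), clip_max = clip_max,
    sdev = d / sqrt(n - 1), rank_deficient = rank_def
  ))))
}

#' Write an embedding to CSV
#' @param x An [sc_embedding].
#' @param path Output CSV path (cell id column plus one column per
#'   component).
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(x, path) {
  stopifnot(is(x, "sc_embedding"))
  df <- tibble(cell = rownames(x$coords))
  df <- dplyr::bind_cols(df, as_tibble(x$coords))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read an embedding from CSV (first column cell ids)
#' @param path CSV path as written by [write_embedding_csv()].
#' @return An [sc_embedding].
#' @export
read_embedding_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  sc_embedding(m, provenance = list(source = path))
}
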