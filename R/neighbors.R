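#' Exact k-nearest-neighbor table
#'
#' Computes, for every cell, its `k_max` nearest neighbors by Euclidean
#' distance in the embedding, excluding the cell itself. The search is
#' exact (block-wise full distance computation) and ties are broken by
#' the smaller cell index, so the result is fully deterministic.
#'
#' @param embedding An [sc_embedding].
#' @param k_max Number of neighbors to record per cell; must be smaller
#'   than the number of cells.
#' @param block Cells per distance block (memory/speed trade-off).
#' @return An object of class `aknn_neighbors` with integer matrix `idx`
#'   (cells x `k_max`), matrix `dist` with each row ascending, `k_max`,
#'   and the cell ids.
#' @export
neighbor_table <- function(embedding, k_max = 20, block = 512L) {
  stopifnot(is(embedding, "sc_embedding"), k_max >= 2)
  xm <- embedding$coords
  n <- nrow(xm)
  if (k_max >= n) abort("`k_max` must be smaller than the number of cells")
  rn <- rowSums(xm^2)
  idx <- matrix(0L, n, k_max)
  dst <- matrix(0, n, k_max)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(rn[rows], rn, "+") -
      2 * tcrossprod(xm[rows, , drop = FALSE], xm)
    for (r in seq_along(rows)) {
      i <- rows[r]
      di <- d2[r, ]
      di[i] <- Inf                       # self excluded
      o <- order(di)[seq_len(k_max)]     # stable: ties -> smaller index
      idx[i, ] <- o
      dst[i, ] <- sqrt(pmax(di[o], 0))
    }
  }
  structure(list(idx = idx, dist = dst, k_max = as.integer(k_max),
                 cell_ids = rownames(xm), metric = "euclidean"),
            class = "aknn_neighbors")
}

#' @export
print.aknn_neighbors <- function(x, ...) {
  cat(sprintf("<aknn_neighbors> %d cells, k_max = %d (exact Euclidean)\n",
              nrow(x$idx), x$k_max))
  invisible(x)
}
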