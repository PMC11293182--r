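#' Per-cell distance cutoff from the local distance distribution
#'
#' The closed-form threshold below which a neighbor distance counts as a
#' true connection:
#' \deqn{d_{cutoff} = \left(\frac{\sum_{l=1}^{K_{max}} \sqrt{d_l}}
#'   {K_{max} - 1 - \delta}\right)^2}
#' where `d_1 <= ... <= d_Kmax` are the cell's sorted neighbor distances
#' and `delta <= 0` tunes the sensitivity to local distance change: a more
#' negative `delta` shrinks the cutoff, keeping fewer neighbors.
#'
#' @param sorted_distances Non-negative distances, sorted ascending.
#' @param delta Non-positive sensitivity hyperparameter (default -0.5).
#' @return The cutoff distance (scalar).
#' @examples
#' cutoff_distance(c(rep(1, 5), rep(9, 5)), delta = -0.5)  # (20/10.5)^2
#' @export
cutoff_distance <- function(sorted_distances, delta = -0.5) {
  if (any(sorted_distances < 0)) abort("distances must be non-negative")
  if (delta > 0) abort("`delta` must be <= 0")
  (sum(sqrt(sorted_distances)) /
     (length(sorted_distances) - 1 - delta))^2
}

#' Adaptive neighbor count for one cell
#'
#' Counts the sorted neighbor distances strictly below the cell's
#' [cutoff_distance()]; equivalently, the largest `k` such that
#' `d_k < cutoff` and `d_(k+1) >= cutoff`. When even the nearest neighbor
#' lies at or beyond the cutoff the count is floored at 1 so no cell is
#' left isolated; it is capped at `K_max` when all distances fall below.
#'
#' @inheritParams cutoff_distance
#' @return Integer `k` in `[1, length(sorted_distances)]`.
#' @examples
#' adaptive_k(c(rep(1, 5), rep(9, 5)), delta = -0.5)  # 5: a rare, tight group
#' adaptive_k(rep(4, 10), delta = 0)                  # 10: uniform distances
#' @export
adaptive_k <- function(sorted_distances, delta = -0.5) {
  cut <- cutoff_distance(sorted_distances, delta)
  k <- sum(sorted_distances < cut)
  as.integer(min(max(k, 1L), length(sorted_distances)))
}

new_aknn_graph <- function(neighbors, k_per_cell, k_max, delta, cell_ids,
                           type) {
  structure(list(neighbors = neighbors,
                 k_per_cell = as.integer(k_per_cell),
                 k_max = as.integer(k_max), delta = delta,
                 cell_ids = cell_ids, type = type),
            class = "aknn_graph")
}

#' @export
print.aknn_graph <- function(x, ...) {
  cat(sprintf("<aknn_graph> %s, %d cells, k in [%d, %d]%s\n", x$type,
              length(x$neighbors), min(x$k_per_cell), max(x$k_per_cell),
              if (x$type == "adaptive")
                sprintf(", delta = %g", x$delta) else ""))
  invisible(x)
}

#' Build the adaptive k-nearest-neighbor graph
#'
#' For each cell `i`, keeps directed edges to its `k_i` nearest neighbors
#' where `k_i` is chosen by [adaptive_k()] from the cell's own sorted
#' distance profile. Cells in small tight populations get small `k_i`
#' (their distance profile jumps once the population is exhausted), cells
#' inside abundant populations get `k_i` near `k_max`.
#'
#' @param nbrs An [neighbor_table()] result.
#' @param delta Non-positive sensitivity hyperparameter.
#' @return An `aknn_graph` (directed; `k_per_cell` gives out-degrees).
#' @export
build_adaptive_graph <- function(nbrs, delta = -0.5) {
  stopifnot(is(nbrs, "aknn_neighbors"))
  if (delta > 0) abort("`delta` must be <= 0")
  k <- vapply(seq_len(nrow(nbrs$dist)),
              function(i) adaptive_k(nbrs$dist[i, ], delta), integer(1))
  nb <- lapply(seq_along(k), function(i) nbrs$idx[i, seq_len(k[i])])
  new_aknn_graph(nb, k, nbrs$k_max, delta, nbrs$cell_ids, "adaptive")
}

#' Build the fixed-k baseline graph
#'
#' Conventional kNN graph in which every cell keeps exactly its `k`
#' nearest neighbors; the baseline against which the adaptive graph is
#' compared.
#'
#' @param nbrs An [neighbor_table()] result.
#' @param k Global neighbor count, at most `nbrs$k_max`.
#' @return An `aknn_graph` with constant `k_per_cell`.
#' @export
build_fixed_graph <- function(nbrs, k = 20) {
  stopifnot(is(nbrs, "aknn_neighbors"))
  if (k > nbrs$k_max) abort("`k` exceeds the neighbor table's k_max")
  n <- nrow(nbrs$idx)
  nb <- lapply(seq_len(n), function(i) nbrs$idx[i, seq_len(k)])
  new_aknn_graph(nb, rep(k, n), nbrs$k_max, NA_real_, nbrs$cell_ids,
                 "fixed")
}

#' Shared-nearest-neighbor graph with Jaccard weights
#'
#' Reweights the directed neighbor graph by neighbor-set overlap: for
#' every pair of cells connected by at least one directed edge, the edge
#' weight becomes the Jaccard similarity
#' `|N(i) \U{2229} N(j)| / |N(i) \U{222A} N(j)|` of their retained neighbor
#' sets (each set including the cell itself). Edges with weight at or
#' below `prune` are removed. The result is symmetric with weights in
#' `(prune, 1]`, and is robust to outliers and stray long-range edges.
#'
#' @param graph An `aknn_graph` (adaptive or fixed).
#' @param prune Pruning threshold in `[0, 1)`; default 1/15.
#' @return A symmetric sparse weight matrix (`dgCMatrix`) with cell id
#'   dimnames and the pruning threshold attached as attribute `"prune"`.
#' @export
snn_jaccard <- function(graph, prune = 1 / 15) {
  stopifnot(is(graph, "aknn_graph"), prune >= 0, prune < 1)
  n <- length(graph$neighbors)
  k <- graph$k_per_cell
  ii <- rep.int(seq_len(n), k)
  jj <- unlist(graph$neighbors, use.names = FALSE)
  # neighbor-set membership matrix, each set including the cell itself
  a <- sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)), x = 1,
                    dims = c(n, n))
  sizes <- k + 1
  # candidate pairs: union of the directed edges (no self-loops)
  cand <- sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1, dims = c(n, n))
  cand <- as(drop0(cand), "nMatrix")
  inter <- tcrossprod(a) * cand          # intersection sizes on candidates
  tt <- as(inter, "TsparseMatrix")
  w <- tt@x / (sizes[tt@i + 1L] + sizes[tt@j + 1L] - tt@x)
  keep <- w > prune & tt@i != tt@j
  snn <- sparseMatrix(i = tt@i[keep] + 1L, j = tt@j[keep] + 1L,
                      x = w[keep], dims = c(n, n),
                      dimnames = list(graph$cell_ids, graph$cell_ids))
  attr(snn, "prune") <- prune
  snn
}

#' @importFrom Matrix drop0
NULL

#' Export a weighted graph as a whitespace-delimited edge list
#'
#' Writes one `i j weight` line per undirected edge (upper triangle,
#' 1-based indices).
#'
#' @param snn A sparse SNN weight matrix from [snn_jaccard()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(snn, path) {
  tt <- as(as(snn, "CsparseMatrix"), "TsparseMatrix")
  up <- tt@i < tt@j
  df <- data.frame(i = tt@i[up] + 1L, j = tt@j[up] + 1L, w = tt@x[up])
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export per-cell adaptive neighbor counts as TSV
#' @param graph An `aknn_graph`.
#' @param path Output TSV (columns: cell, k).
#' @return `path`, invisibly.
#' @export
write_k_per_cell <- function(graph, path) {
  stopifnot(is(graph, "aknn_graph"))
  readr::write_tsv(tibble(cell = graph$cell_ids, k = graph$k_per_cell),
                   path)
  invisible(path)
}
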