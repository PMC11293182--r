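new_clustering <- function(labels, cell_ids, resolution, delta_used, seed,
                           k_per_cell = NULL, trace = NULL,
                           provenance = list()) {
  names(labels) <- cell_ids
  structure(list(labels = labels,
                 n_communities = length(unique(labels)),
                 resolution = resolution, delta_used = delta_used,
                 seed = seed, k_per_cell = k_per_cell, trace = trace,
                 provenance = provenance),
            class = "aknn_clustering")
}

#' @export
print.aknn_clustering <- function(x, ...) {
  cat(sprintf(
    "<aknn_clustering> %d cells, %d communities (resolution %g, delta %s)\n",
    length(x$labels), x$n_communities, x$resolution,
    if (is.na(x$delta_used)) "n/a" else format(x$delta_used)))
  tb <- sort(table(x$labels), decreasing = TRUE)
  cat("sizes:", paste(tb, collapse = ", "), "\n")
  invisible(x)
}

#' Louvain community detection on an SNN graph
#'
#' Runs modularity-maximizing Louvain clustering (with the resolution
#' parameter scaling the configuration-model null term) on the weighted
#' shared-nearest-neighbor graph. Isolated vertices become singleton
#' communities. The RNG seed is fixed for the call, so identical inputs
#' give identical labels.
#'
#' @param snn Symmetric sparse weight matrix from [snn_jaccard()].
#' @param resolution Positive resolution parameter; larger values favor
#'   more communities.
#' @param seed Integer RNG seed.
#' @return An `aknn_clustering` with 0-based contiguous community labels.
#' @export
louvain_cluster <- function(snn, resolution = 0.8, seed = 0) {
  if (!is(snn, "sparseMatrix") || nrow(snn) == 0)
    abort("`snn` must be a non-empty sparse matrix")
  stopifnot(resolution > 0)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution)))
  # contiguous 0-based ids, numbered by first appearance
  labels <- match(memb, unique(memb)) - 1L
  new_clustering(labels, rownames(snn), resolution, NA_real_, seed,
                 provenance = list(prune = attr(snn, "prune")))
}

snn_cluster_count <- function(nbrs, delta, resolution, prune, seed) {
  g <- build_adaptive_graph(nbrs, delta)
  cl <- louvain_cluster(snn_jaccard(g, prune), resolution, seed)
  list(n = cl$n_communities, clustering = cl, graph = g)
}

#' Pick delta from a community-count trace
#'
#' Applies the stopping rule of the grid search: walking down the
#' (strictly decreasing) delta grid, stop at the first position whose
#' community count jumps by at least `jump_abs` communities *and* by a
#' factor of at least `jump_ratio` over the previous position — the
#' signature of overclustering — and return the delta just before the
#' jump. If no jump occurs the most negative delta evaluated is returned.
#'
#' @param grid Strictly decreasing vector of non-positive delta values.
#' @param n_communities Community count observed at each grid value.
#' @param jump_abs Minimum absolute increase that counts as a jump.
#' @param jump_ratio Minimum fold increase that counts as a jump.
#' @return List with `chosen_delta` and `jump_index` (`NA` if no jump).
#' @examples
#' select_delta(c(0, -0.5, -1, -1.5, -2), c(5, 5, 5, 12, 30))
#' @export
select_delta <- function(grid, n_communities, jump_abs = 5,
                         jump_ratio = 1.5) {
  stopifnot(length(grid) == length(n_communities), length(grid) >= 1)
  if (any(grid > 0) || any(diff(grid) >= 0))
    abort("`grid` must be non-positive and strictly decreasing")
  for (t in seq_along(n_communities)[-1]) {
    prev <- n_communities[t - 1]
    if (n_communities[t] - prev >= jump_abs &&
        n_communities[t] / max(prev, 1) >= jump_ratio)
      return(list(chosen_delta = grid[t - 1], jump_index = t))
  }
  list(chosen_delta = grid[length(grid)], jump_index = NA_integer_)
}

#' Grid search for the sensitivity hyperparameter delta
#'
#' Decreases delta along the grid, rebuilding the adaptive graph, the SNN
#' graph and the Louvain clustering at each value, and records the number
#' of communities. The search stops at the first rapid increase in
#' community count (see [select_delta()]) and returns the delta just
#' before it; community counts are recorded up to and including the
#' stopping point.
#'
#' @param nbrs An [neighbor_table()] result.
#' @param grid Strictly decreasing vector of non-positive delta values.
#' @param resolution Louvain resolution used during the search.
#' @param prune SNN pruning threshold.
#' @param seed Integer RNG seed (reused at every grid value).
#' @param jump_abs,jump_ratio Jump-rule thresholds, see [select_delta()].
#' @return An `aknn_delta_trace`: the evaluated `(delta, n_communities)`
#'   trace plus `chosen_delta` and `jump_index`.
#' @export
optimize_delta <- function(nbrs, grid = seq(0, -5, by = -0.5),
                           resolution = 0.8, prune = 1 / 15, seed = 0,
                           jump_abs = 5, jump_ratio = 1.5) {
  stopifnot(is(nbrs, "aknn_neighbors"))
  if (!length(grid)) abort("`grid` must be non-empty")
  if (any(grid > 0) || (length(grid) > 1 && any(diff(grid) >= 0)))
    abort("`grid` must be non-positive and strictly decreasing")
  counts <- integer(0)
  chosen <- grid[length(grid)]
  jump_at <- NA_integer_
  for (t in seq_along(grid)) {
    counts[t] <- snn_cluster_count(nbrs, grid[t], resolution, prune, seed)$n
    if (t >= 2) {
      sel <- select_delta(grid[seq_len(t)], counts, jump_abs, jump_ratio)
      if (!is.na(sel$jump_index)) {
        chosen <- sel$chosen_delta
        jump_at <- sel$jump_index
        break
      }
    }
  }
  structure(list(trace = tibble(delta = grid[seq_along(counts)],
                                n_communities = counts),
                 chosen_delta = chosen, jump_index = jump_at,
                 resolution = resolution, prune = prune, seed = seed),
            class = "aknn_delta_trace")
}

#' @export
print.aknn_delta_trace <- function(x, ...) {
  cat(sprintf("<aknn_delta_trace> chosen delta = %g%s\n", x$chosen_delta,
              if (is.na(x$jump_index)) " (no jump detected)"
              else sprintf(" (jump at grid position %d)", x$jump_index)))
  print(x$trace)
  invisible(x)
}

#' Run the full adaptive-kNN clustering pipeline
#'
#' From raw counts: filter cells/genes, log-normalize, select highly
#' variable genes, embed by PCA, build the exact neighbor table, then
#' construct the adaptive (or fixed-k baseline) graph, reweight it by
#' shared-nearest-neighbor Jaccard similarity and cluster with Louvain.
#' An [sc_embedding] input skips preprocessing. With `optimize = TRUE`
#' the delta grid search is run first and its chosen delta used.
#'
#' @param x An [sc_counts] (raw counts) or [sc_embedding].
#' @param method `"adaptive"` (per-cell k) or `"fixed"` (constant-k
#'   baseline).
#' @param k_max Maximum neighbors per cell (the neighbor table width).
#' @param delta Non-positive sensitivity hyperparameter used when
#'   `optimize = FALSE`.
#' @param optimize If `TRUE`, choose delta by [optimize_delta()].
#' @param delta_grid Grid for the delta search.
#' @param fixed_k Neighbor count for `method = "fixed"`.
#' @param prune SNN pruning threshold.
#' @param resolution Louvain resolution.
#' @param n_hvg Number of highly variable genes; `NULL` means
#'   `min(2000, n_genes)` after filtering.
#' @param n_pcs Number of principal components.
#' @param min_genes_per_cell,min_cells_per_gene,min_spot_fraction Filters,
#'   see [filter_cells_genes()].
#' @param scale_total Normalization target, see [normalize_log()].
#' @param seed Integer RNG seed; identical inputs and seed reproduce the
#'   labels exactly.
#' @return An `aknn_clustering` carrying `delta_used`, `k_per_cell`, the
#'   delta-search trace (when run) and full provenance.
#' @examples
#' \donttest{
#' sim <- simulate_counts(simulation_design(type_sizes = c(100, 100, 8),
#'                                          n_genes = 400, seed = 1))
#' cl <- run_adaknn(sim, n_hvg = 200, n_pcs = 20,
#'                  min_genes_per_cell = 50, seed = 1)
#' table(cl$labels, cell_labels(sim))
#' }
#' @export
run_adaknn <- function(x, method = c("adaptive", "fixed"), k_max = 20,
                       delta = -0.5, optimize = FALSE,
                       delta_grid = seq(0, -5, by = -0.5), fixed_k = 20,
                       prune = 1 / 15, resolution = 0.8, n_hvg = NULL,
                       n_pcs = 50, min_genes_per_cell = 200,
                       min_cells_per_gene = 3, min_spot_fraction = NULL,
                       scale_total = 1e4, seed = 0) {
  method <- match.arg(method)
  if (is(x, "sc_counts")) {
    emb <- with_stage("preprocess", {
      filt <- filter_cells_genes(x, min_genes_per_cell, min_cells_per_gene,
                                 min_spot_fraction)
      nh <- n_hvg %||% min(2000L, ncol(filt$counts))
      hvg <- select_hvg_vst(filt, n_hvg = nh)
      pca_embed(normalize_log(filt, scale_total), hvg, n_pcs = n_pcs)
    })
  } else if (is(x, "sc_embedding")) {
    emb <- x
  } else {
    abort("`x` must be an sc_counts or sc_embedding object")
  }
  nbrs <- with_stage("neighbors", neighbor_table(emb, k_max = k_max))
  trace <- NULL
  if (method == "adaptive" && optimize) {
    trace <- with_stage("delta_search",
      optimize_delta(nbrs, delta_grid, resolution, prune, seed))
    delta <- trace$chosen_delta
  }
  graph <- with_stage("graph", switch(method,
    adaptive = build_adaptive_graph(nbrs, delta),
    fixed = build_fixed_graph(nbrs, fixed_k)))
  snn <- with_stage("snn", snn_jaccard(graph, prune))
  cl <- with_stage("louvain", louvain_cluster(snn, resolution, seed))
  new_clustering(cl$labels, nbrs$cell_ids, resolution,
                 if (method == "adaptive") delta else NA_real_, seed,
                 k_per_cell = graph$k_per_cell, trace = trace,
                 provenance = c(emb$provenance, list(run = list(
                   method = method, k_max = k_max,
                   fixed_k = if (method == "fixed") fixed_k else NULL,
                   prune = prune, resolution = resolution,
                   optimized = isTRUE(optimize), seed = seed))))
}

#' Write cluster labels as TSV with a JSON provenance sidecar
#'
#' @param clustering An `aknn_clustering`.
#' @param path Output TSV path (columns: cell, cluster); provenance and
#'   run parameters are written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(clustering, path) {
  stopifnot(is(clustering, "aknn_clustering"))
  readr::write_tsv(tidy(clustering), path)
  meta <- list(n_communities = clustering$n_communities,
               resolution = clustering$resolution,
               delta_used = clustering$delta_used,
               seed = clustering$seed,
               provenance = clustering$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
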