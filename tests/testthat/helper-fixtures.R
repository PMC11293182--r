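# small deterministic count matrix with named cells/genes
toy_counts <- function(values, labels = NULL) {
  m <- as.matrix(values)
  dimnames(m) <- list(paste0("c", seq_len(nrow(m))),
                      paste0("g", seq_len(ncol(m))))
  sc_counts(m, labels = labels)
}

# embedding from raw coordinates
toy_embedding <- function(coords) {
  m <- as.matrix(coords)
  rownames(m) <- paste0("c", seq_len(nrow(m)))
  sc_embedding(m)
}

# neighbor table built directly from coordinates
toy_neighbors <- function(coords, k_max) {
  neighbor_table(toy_embedding(coords), k_max = k_max)
}

# directed neighbor graph from an explicit neighbor list (indices exclude
# self); used to test SNN Jaccard weights against hand-computed sets
graph_from_sets <- function(neighbors, k_max = NULL) {
  k <- lengths(neighbors)
  adaknn:::new_aknn_graph(neighbors, k, k_max %||% max(k), -0.5,
                          paste0("c", seq_along(neighbors)), "adaptive")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force exact kNN by full pairwise distances (independent oracle)
brute_knn <- function(coords, k_max) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  idx <- matrix(0L, n, k_max)
  dst <- matrix(0, n, k_max)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    o <- order(di)[seq_len(k_max)]
    idx[i, ] <- o
    dst[i, ] <- di[o]
  }
  list(idx = idx, dist = dst)
}

# brute-force Jaccard SNN weights over materialized neighbor sets
brute_snn <- function(graph, prune) {
  n <- length(graph$neighbors)
  sets <- lapply(seq_len(n), function(i) c(i, graph$neighbors[[i]]))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in graph$neighbors[[i]]) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    jac <- inter / (length(sets[[i]]) + length(sets[[j]]) - inter)
    w[i, j] <- jac
    w[j, i] <- jac
  }
  w[w <= prune] <- 0
  diag(w) <- 0
  w
}
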