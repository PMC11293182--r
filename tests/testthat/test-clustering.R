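# enumerate all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxblock) {
    pos <- length(prefix) + 1
    if (pos > n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1))
      rec(c(prefix, b), max(maxblock, b))
  }
  rec(integer(0), 0L)
  out
}

# Reichardt-Bornholdt modularity of a membership vector on weights `a`
rb_modularity <- function(memb, a, gamma) {
  m2 <- sum(a)  # twice total edge weight
  deg <- rowSums(a)
  b <- a - gamma * outer(deg, deg) / m2
  sum(b[outer(memb, memb, "==")]) / m2
}

test_that("disconnected components become separate communities", {
  tri <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    tri[p[1], p[2]] <- tri[p[2], p[1]] <- 1
  snn <- as(Matrix::Matrix(tri, sparse = TRUE), "CsparseMatrix")
  dimnames(snn) <- list(paste0("c", 1:6), paste0("c", 1:6))
  cl <- louvain_cluster(snn, resolution = 0.8, seed = 1)
  expect_equal(cl$n_communities, 2L)
  expect_equal(cl$labels[1:3], rep(cl$labels[1], 3), ignore_attr = TRUE)
  expect_equal(cl$labels[4:6], rep(cl$labels[4], 3), ignore_attr = TRUE)
  expect_setequal(unique(cl$labels), c(0L, 1L))
})

test_that("louvain attains the exhaustive modularity optimum on two weak
           joined cliques", {
  n <- 10
  a <- matrix(0, n, n)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 0.1
  snn <- as(Matrix::Matrix(a, sparse = TRUE), "CsparseMatrix")
  dimnames(snn) <- list(paste0("c", 1:n), paste0("c", 1:n))
  cl <- louvain_cluster(snn, resolution = 0.8, seed = 0)
  expect_equal(cl$n_communities, 2L)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  # exhaustive oracle over all 115,975 partitions of 10 nodes
  m2 <- sum(a)
  deg <- rowSums(a)
  b <- a - 0.8 * outer(deg, deg) / m2
  parts <- all_partitions(n)
  best <- max(vapply(parts, function(p) sum(b[outer(p, p, "==")]) / m2,
                     numeric(1)))
  expect_equal(rb_modularity(cl$labels, a, 0.8), best, tolerance = 1e-12)
})

test_that("clustering is deterministic for identical graph and seed", {
  coords <- withr::with_seed(17, matrix(rnorm(200 * 3), 200, 3))
  snn <- snn_jaccard(build_adaptive_graph(toy_neighbors(coords, 10), -0.5))
  c1 <- louvain_cluster(snn, 0.8, seed = 42)
  c2 <- louvain_cluster(snn, 0.8, seed = 42)
  expect_identical(c1$labels, c2$labels)
  # labels cover all cells with contiguous 0-based community ids
  expect_length(c1$labels, 200)
  expect_setequal(unique(c1$labels), seq_len(c1$n_communities) - 1L)
})

test_that("isolated vertices become singleton communities", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  snn <- as(Matrix::Matrix(a, sparse = TRUE), "CsparseMatrix")
  dimnames(snn) <- list(paste0("c", 1:4), paste0("c", 1:4))
  cl <- louvain_cluster(snn, 0.8, seed = 0)
  expect_equal(cl$n_communities, 3L)
  expect_equal(cl$labels[[1]], cl$labels[[2]])
  expect_false(cl$labels[[3]] == cl$labels[[4]])
})

test_that("the delta stop rule fires just before a rapid increase", {
  sel <- select_delta(c(0, -0.5, -1, -1.5, -2), c(5, 5, 5, 12, 30))
  expect_equal(sel$chosen_delta, -1)
  expect_equal(sel$jump_index, 4L)
  # constant counts never fire: the most negative delta is kept
  sel2 <- select_delta(c(0, -1, -2, -3), c(7, 7, 7, 7))
  expect_equal(sel2$chosen_delta, -3)
  expect_true(is.na(sel2$jump_index))
  # single-element grid returns that delta
  sel3 <- select_delta(-0.5, 4)
  expect_equal(sel3$chosen_delta, -0.5)
  # absolute or relative increase alone is not enough
  expect_true(is.na(select_delta(c(0, -1), c(40, 46))$jump_index))
  expect_true(is.na(select_delta(c(0, -1), c(2, 4))$jump_index))
  expect_error(select_delta(c(0, 1), c(1, 2)), "decreasing")
})

test_that("grid search records counts up to the jump and picks from grid", {
  sim <- simulate_counts(simulation_design(seed = 4))
  filt <- filter_cells_genes(sim)
  emb <- pca_embed(normalize_log(filt), select_hvg_vst(filt, 500), 30)
  nbrs <- neighbor_table(emb, 20)
  tr <- optimize_delta(nbrs, seed = 4)
  expect_s3_class(tr, "aknn_delta_trace")
  expect_true(tr$chosen_delta %in% tr$trace$delta)
  expect_equal(nrow(tr$trace),
               if (is.na(tr$jump_index)) 11L else tr$jump_index)
  # the chosen delta keeps the community count below the post-jump level
  if (!is.na(tr$jump_index)) {
    expect_equal(tr$chosen_delta, tr$trace$delta[tr$jump_index - 1])
    expect_gte(tr$trace$n_communities[tr$jump_index] -
                 tr$trace$n_communities[tr$jump_index - 1], 5)
  }
  expect_error(optimize_delta(nbrs, numeric(0)), "non-empty")
})

test_that("pipeline runs identically from counts or their embedding", {
  sim <- simulate_counts(simulation_design(type_sizes = c(120, 120, 8),
                                           n_genes = 600, seed = 6))
  filt <- filter_cells_genes(sim)
  emb <- pca_embed(normalize_log(filt), select_hvg_vst(filt, 300),
                   n_pcs = 20)
  from_counts <- run_adaknn(sim, n_hvg = 300, n_pcs = 20, seed = 2)
  from_emb <- run_adaknn(emb, seed = 2)
  expect_identical(from_counts$labels, from_emb$labels)
  # rerun with the same seed reproduces labels exactly
  again <- run_adaknn(sim, n_hvg = 300, n_pcs = 20, seed = 2)
  expect_identical(from_counts$labels, again$labels)
  # the fixed-k baseline marks delta as not applicable
  fixed <- run_adaknn(emb, method = "fixed", seed = 2)
  expect_true(is.na(fixed$delta_used))
  expect_true(all(fixed$k_per_cell == 20))
})

test_that("stage failures carry the stage name", {
  sim <- simulate_counts(simulation_design(type_sizes = c(20, 20),
                                           n_genes = 100, seed = 8))
  expect_error(run_adaknn(sim, n_hvg = 500, min_genes_per_cell = 10),
               "preprocess")
  emb <- toy_embedding(matrix(rnorm(40), 20, 2))
  expect_error(run_adaknn(emb, k_max = 30), "neighbors")
})

test_that("optimized runs carry the trace and its chosen delta", {
  sim <- simulate_counts(simulation_design(type_sizes = c(120, 120, 8),
                                           n_genes = 600, seed = 10))
  cl <- run_adaknn(sim, optimize = TRUE, delta_grid = c(0, -0.5, -1),
                   n_hvg = 300, n_pcs = 20, seed = 1)
  expect_s3_class(cl$trace, "aknn_delta_trace")
  expect_equal(cl$delta_used, cl$trace$chosen_delta)
})
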