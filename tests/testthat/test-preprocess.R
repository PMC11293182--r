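test_that("cell and gene filters apply inclusive thresholds, cells first", {
  # cell 1 expresses 2 genes; with a threshold of 3 it is dropped
  m <- rbind(c(1, 1, 0, 0), c(1, 1, 1, 1), c(2, 1, 1, 1))
  x <- toy_counts(m)
  out <- filter_cells_genes(x, min_genes_per_cell = 3,
                            min_cells_per_gene = 1)
  expect_equal(rownames(out$counts), c("c2", "c3"))

  # every cell/gene clears the default thresholds: identity
  big <- toy_counts(matrix(1, 10, 500))
  out2 <- filter_cells_genes(big, 200, 3)
  expect_equal(dim(out2), c(10L, 500L))

  # gene detection is recounted after cell removal (cells first)
  m3 <- rbind(c(1, 0, 0), c(0, 1, 1), c(0, 1, 1), c(0, 1, 1))
  out3 <- filter_cells_genes(toy_counts(m3), min_genes_per_cell = 2,
                             min_cells_per_gene = 1)
  # gene g1 was only detected in the dropped cell c1
  expect_false("g1" %in% colnames(out3$counts))
  expect_equal(out3$provenance$filter$order, "cells_then_genes")
})

test_that("spot-fraction filter keeps genes at exactly the boundary", {
  m <- matrix(0, 10, 3)
  m[1, 1] <- 1  # gene 1 detected in 1/10 spots; gene 3 in none
  m[, 2] <- 1   # gene 2 everywhere
  x <- toy_counts(m)
  out <- filter_cells_genes(x, min_genes_per_cell = 0,
                            min_cells_per_gene = 0,
                            min_spot_fraction = 0.1)
  expect_true("g1" %in% colnames(out$counts))   # 1/10 = 0.10 >= 0.10
  expect_false("g3" %in% colnames(out$counts))  # 0/10 < 0.10
})

test_that("log-normalization rescales each cell to the target total", {
  x <- toy_counts(rbind(c(1, 1, 2), c(2, 2, 4)))
  out <- normalize_log(x, scale_total = 1e4)
  expect_equal(as.numeric(out$counts[1, ]),
               log1p(c(2500, 2500, 5000)))
  # pre-log totals equal scale_total for every cell
  pre <- expm1(as.matrix(out$counts))
  expect_equal(unname(rowSums(pre)), rep(1e4, 2), tolerance = 1e-6)
  # a cell already summing to scale_total is unchanged before the log
  y <- toy_counts(matrix(c(2500, 2500, 5000), 1, 3))
  expect_equal(expm1(as.numeric(normalize_log(y, 1e4)$counts[1, ])),
               c(2500, 2500, 5000))
  # zeros stay zero and the error names the offending cell
  expect_equal(out$counts[1, 1] > 0, TRUE)
  z <- toy_counts(rbind(c(1, 1), c(0, 0)))
  expect_error(normalize_log(z), "c2")
})

test_that("normalization total is preserved on simulated data", {
  sim <- simulate_counts(simulation_design(type_sizes = c(30, 20),
                                           n_genes = 200, seed = 5))
  out <- normalize_log(sim, 1e4)
  tot <- rowSums(expm1(as.matrix(out$counts)))
  expect_equal(unname(tot), rep(1e4, 50), tolerance = 1e-6)
})

test_that("vst ranks planted markers at the top", {
  # moderate expression floor so every marker is detectable at this depth
  des <- simulation_design(type_sizes = c(100, 100), n_genes = 1000,
                           marker_fraction = 0.025, log2_fc = 3,
                           baseline_logmean = c(0, 1), seed = 11)
  sim <- simulate_counts(des)  # 2 x 25 = 50 marker genes, 950 flat
  marker_ids <- sprintf("gene%04d",
                        unlist(sim$provenance$simulation$marker_sets))
  expect_length(marker_ids, 50)
  top100 <- select_hvg_vst(sim, n_hvg = 100)
  expect_true(all(marker_ids %in% top100))
})

test_that("vst edge cases: full set, constant genes, bad n_hvg", {
  m <- matrix(rpois(200 * 40, 2), 200, 40)
  m[, 40] <- 5L  # constant gene
  x <- toy_counts(m)
  all_genes <- select_hvg_vst(x, n_hvg = 40)
  expect_setequal(all_genes, colnames(x$counts))
  # the constant gene ranks last among all genes
  expect_equal(all_genes[40], "g40")
  expect_error(select_hvg_vst(x, n_hvg = 41), "exceeds")
})

test_that("vst standardized-variance ranking matches Seurat's vst", {
  sim <- simulate_counts(simulation_design(type_sizes = c(60, 40),
                                           n_genes = 300, seed = 7))
  ours <- select_hvg_vst(sim, n_hvg = 300)
  hv <- suppressWarnings(Seurat::FindVariableFeatures(
    Matrix::t(sim$counts), selection.method = "vst", verbose = FALSE))
  theirs <- rownames(hv)[order(-hv$vst.variance.standardized)]
  expect_gte(length(intersect(ours[1:50], theirs[1:50])), 48)
  expect_gt(cor(match(ours, theirs), seq_along(ours),
                method = "spearman"), 0.99)
})

test_that("pca separates planted clusters and orders variances", {
  sim <- simulate_counts(simulation_design(type_sizes = c(80, 80),
                                           n_genes = 500, log2_fc = 3,
                                           seed = 2))
  lab <- unname(cell_labels(sim))
  filt <- filter_cells_genes(sim, 50, 3)
  emb <- pca_embed(normalize_log(filt), select_hvg_vst(filt, 200),
                   n_pcs = 10)
  expect_equal(rownames(emb$coords), rownames(filt$counts))
  pc1 <- emb$coords[, 1]
  # the two label groups do not overlap on PC1
  expect_true(max(pc1[lab == "type1"]) < min(pc1[lab == "type2"]) ||
              max(pc1[lab == "type2"]) < min(pc1[lab == "type1"]))
  sdev <- emb$provenance$pca$sdev
  expect_true(all(diff(sdev) <= 1e-8))
  expect_error(pca_embed(normalize_log(filt), select_hvg_vst(filt, 30),
                         n_pcs = 40), "exceeds")
})

test_that("pca embedding is invariant to cell permutation up to sign", {
  sim <- simulate_counts(simulation_design(type_sizes = c(40, 40),
                                           n_genes = 300, seed = 9))
  filt <- filter_cells_genes(sim, 20, 1)
  hvg <- select_hvg_vst(filt, 150)
  norm <- normalize_log(filt)
  emb1 <- pca_embed(norm, hvg, n_pcs = 5)
  perm <- withr::with_seed(1, sample(nrow(norm$counts)))
  emb2 <- pca_embed(norm[perm, ], hvg, n_pcs = 5)
  back <- emb2$coords[match(rownames(emb1$coords),
                            rownames(emb2$coords)), ]
  for (c in 1:5) {
    agree <- max(abs(back[, c] - emb1$coords[, c]))
    flipped <- max(abs(back[, c] + emb1$coords[, c]))
    expect_lt(min(agree, flipped), 1e-6)
  }
})

test_that("embedding CSV round-trips", {
  emb <- toy_embedding(matrix(rnorm(20), 5, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedding_csv(emb, path)
  back <- read_embedding_csv(path)
  expect_equal(back$coords, emb$coords, ignore_attr = TRUE,
               tolerance = 1e-12)
})
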