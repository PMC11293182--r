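# Parameter-recovery runs on the planted 200/200/10 design, shared by the
# acceptance checks on rare-cell recovery and resolution stability.
# Memoised so the sweep is computed once per test session.
.recovery_cache <- new.env(parent = emptyenv())

recovery_runs <- function(seeds = 1:20, resolutions = c(0.1, 0.3, 0.8)) {
  key <- paste0("s", paste(range(seeds), collapse = "_"))
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  out <- purrr::map_dfr(seeds, function(s) {
    sim <- simulate_counts(simulation_design(type_sizes = c(200, 200, 10),
                                             log2_fc = 3, seed = s))
    filt <- filter_cells_genes(sim)
    truth <- unname(cell_labels(filt))
    hvg <- select_hvg_vst(filt, n_hvg = 500)
    emb <- pca_embed(normalize_log(filt), hvg, n_pcs = 30)
    nbrs <- neighbor_table(emb, k_max = 20)
    snn_a <- snn_jaccard(build_adaptive_graph(nbrs, -0.5))
    snn_f <- snn_jaccard(build_fixed_graph(nbrs, 20))
    purrr::map_dfr(resolutions, function(r) {
      dplyr::bind_rows(
        dplyr::mutate(evaluate_clustering(
          louvain_cluster(snn_a, r, seed = s), truth, rare_type = "type3"),
          method = "adaptive"),
        dplyr::mutate(evaluate_clustering(
          louvain_cluster(snn_f, r, seed = s), truth, rare_type = "type3"),
          method = "fixed")) |>
        dplyr::mutate(seed = s, resolution = r)
    })
  })
  .recovery_cache[[key]] <- out
  out
}
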