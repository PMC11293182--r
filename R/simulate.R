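#' Design for the negative-binomial count simulator
#'
#' Describes a planted-cluster single-cell dataset: per-type cell counts,
#' gene number, per-type marker sets (disjoint by default), marker effect
#' size, the lognormal distribution of baseline gene means, lognormal
#' cell size factors, and NB overdispersion. Defaults emulate a small
#' UMI experiment with two abundant types and one rare type: roughly
#' 1,000 UMIs and 350-400 detected genes per cell, 5% of genes up-
#' regulated per type at 8-fold, moderate overdispersion.
#'
#' @param type_sizes Integer cells per type (named or not).
#' @param n_genes Number of genes.
#' @param marker_fraction Fraction of genes forming each type's marker
#'   set (per type; sets are disjoint unless `marker_sets` is given).
#' @param log2_fc log2 fold change applied to a type's markers.
#' @param baseline_logmean `c(meanlog, sdlog)` of the lognormal baseline
#'   gene means.
#' @param libsize_sigma Lognormal sd of per-cell size factors.
#' @param nb_dispersion NB `size` parameter (smaller = more overdispersed).
#' @param marker_sets Optional list (one integer vector of gene indices
#'   per type) overriding random disjoint marker assignment; sets may
#'   overlap, which makes the involved types transcriptionally similar.
#' @param seed Integer seed; the design is fully reproducible.
#' @return A `sim_design` list.
#' @export
simulation_design <- function(type_sizes = c(200, 200, 10), n_genes = 1000,
                              marker_fraction = 0.05, log2_fc = 3,
                              baseline_logmean = c(-1, 1.2),
                              libsize_sigma = 0.3, nb_dispersion = 10,
                              marker_sets = NULL, seed = 1) {
  stopifnot(all(type_sizes >= 1), n_genes >= 1,
            marker_fraction > 0, marker_fraction < 1, log2_fc >= 0,
            libsize_sigma >= 0, nb_dispersion > 0,
            length(baseline_logmean) == 2)
  n_types <- length(type_sizes)
  per_type <- round(marker_fraction * n_genes)
  if (is.null(marker_sets) && per_type * n_types > n_genes)
    abort("marker sets exceed the gene count")
  if (!is.null(marker_sets)) {
    stopifnot(length(marker_sets) == n_types)
    if (any(unlist(marker_sets) > n_genes))
      abort("marker sets exceed the gene count")
  }
  if (is.null(names(type_sizes)))
    names(type_sizes) <- paste0("type", seq_len(n_types))
  structure(list(type_sizes = type_sizes, n_genes = n_genes,
                 marker_fraction = marker_fraction, log2_fc = log2_fc,
                 baseline_logmean = baseline_logmean,
                 libsize_sigma = libsize_sigma,
                 nb_dispersion = nb_dispersion,
                 marker_sets = marker_sets, seed = seed),
            class = "sim_design")
}

#' Simulate a labeled NB count matrix with planted cell types
#'
#' Gene baseline means are drawn lognormal; each type's marker genes are
#' upregulated by `2^log2_fc`; per-cell size factors are lognormal; and
#' counts are negative binomial with mean `sizefactor * genemean` and
#' size `nb_dispersion`. The same design (including its seed) always
#' yields the identical matrix.
#'
#' @param design A [simulation_design()].
#' @return An [sc_counts] with per-cell type labels and the marker sets
#'   recorded in provenance.
#' @export
simulate_counts <- function(design) {
  stopifnot(is(design, "sim_design"))
  d <- design
  with_seed(d$seed, {
    g <- d$n_genes
    n_types <- length(d$type_sizes)
    mu <- rlnorm(g, d$baseline_logmean[1], d$baseline_logmean[2])
    marks <- d$marker_sets
    if (is.null(marks)) {
      per <- round(d$marker_fraction * g)
      marks <- split(sample.int(g, per * n_types),
                     rep(seq_len(n_types), each = per))
    }
    n <- sum(d$type_sizes)
    labels <- rep(names(d$type_sizes), d$type_sizes)
    sf <- rlnorm(n, 0, d$libsize_sigma)
    counts <- matrix(0L, n, g)
    offset <- 0L
    for (t in seq_len(n_types)) {
      m <- mu
      m[marks[[t]]] <- m[marks[[t]]] * 2^d$log2_fc
      idx <- offset + seq_len(d$type_sizes[t])
      counts[idx, ] <- rnbinom(length(idx) * g, mu = outer(sf[idx], m),
                               size = d$nb_dispersion)
      offset <- offset + d$type_sizes[t]
    }
    rownames(counts) <- sprintf("cell%04d", seq_len(n))
    colnames(counts) <- sprintf("gene%04d", seq_len(g))
    names(marks) <- names(d$type_sizes)
    sc_counts(counts, labels = labels,
              provenance = list(simulation = list(
                design = unclass(d)[setdiff(names(d), "marker_sets")],
                marker_sets = marks)))
  })
}

#' Synthetic stand-in for the labeled PBMC reference
#'
#' Builds a four-type labeled count matrix mimicking the structure of a
#' PBMC reference used for subsampling benchmarks: two abundant-capable
#' types (`B`, `CD4T`), a rare-capable type transcriptionally *similar*
#' to CD4T (`NK`, whose marker set half-overlaps CD4T's — the hard
#' setting), and a rare-capable *distinct* type (`Mono`). Labels mark
#' every cell, so scenario datasets can be drawn with
#' [subsample_reference()].
#'
#' @param n_per_type Cells generated per type (defaults give enough for
#'   200 + 200 abundant and up to 20 rare draws).
#' @param n_genes,log2_fc,marker_fraction,nb_dispersion See
#'   [simulation_design()].
#' @param seed Integer seed.
#' @return An [sc_counts] with labels `B`, `CD4T`, `NK`, `Mono`.
#' @export
benchmark_reference <- function(n_per_type = c(B = 250, CD4T = 250,
                                               NK = 30, Mono = 30),
                                n_genes = 1000, log2_fc = 3,
                                marker_fraction = 0.05,
                                nb_dispersion = 10, seed = 1) {
  per <- round(marker_fraction * n_genes)
  idx <- with_seed(seed, sample.int(n_genes, ceiling(per * 3.5)))
  sets <- list(
    B = idx[seq_len(per)],
    CD4T = idx[per + seq_len(per)],
    # NK shares half of CD4T's markers: the similar rare type
    NK = c(idx[per + seq_len(per %/% 2)],
           idx[2 * per + seq_len(per - per %/% 2)]),
    Mono = idx[ceiling(2.5 * per) + seq_len(per)]
  )
  design <- simulation_design(type_sizes = n_per_type, n_genes = n_genes,
                              marker_fraction = marker_fraction,
                              log2_fc = log2_fc,
                              nb_dispersion = nb_dispersion,
                              marker_sets = sets, seed = seed)
  simulate_counts(design)
}

#' Design of the rare-cell subsampling benchmark
#'
#' Two abundant types of 200 cells each plus `n_rare` rare cells (2-20)
#' drawn from a labeled reference. Setting 1 uses a rare type similar to
#' one abundant type (`NK` vs `CD4T`); setting 2 a distinct rare type
#' (`Mono`). Replicate `r` uses seed `seed_base + r` so every draw is
#' reproducible.
#'
#' @param setting 1 (similar rare type) or 2 (distinct rare type).
#' @param n_rare Number of rare cells, between 2 and 20.
#' @param n_replicates Datasets per scenario.
#' @param abundant_sizes Cells per abundant type.
#' @param abundant_types,rare_type Truth labels to draw from; defaults
#'   match [benchmark_reference()].
#' @param seed_base Base seed; replicate `r` uses `seed_base + r`.
#' @return A `benchmark_design` list.
#' @export
benchmark_design <- function(setting = 1, n_rare = 5, n_replicates = 50,
                             abundant_sizes = c(200, 200),
                             abundant_types = c("B", "CD4T"),
                             rare_type = NULL, seed_base = 0) {
  stopifnot(setting %in% c(1, 2), n_rare >= 2, n_rare <= 20,
            n_replicates >= 1, length(abundant_sizes) == 2,
            length(abundant_types) == 2)
  rare_type <- rare_type %||% if (setting == 1) "NK" else "Mono"
  structure(list(setting = setting, n_rare = as.integer(n_rare),
                 n_replicates = as.integer(n_replicates),
                 abundant_sizes = abundant_sizes,
                 abundant_types = abundant_types, rare_type = rare_type,
                 seed_base = seed_base),
            class = "benchmark_design")
}

#' Draw one benchmark dataset from a labeled reference
#'
#' Samples, without replacement, `abundant_sizes` cells of each abundant
#' type and `n_rare` cells of the rare type from the reference, using
#' seed `seed_base + replicate`.
#'
#' @param reference A labeled [sc_counts] (real or from
#'   [benchmark_reference()]).
#' @param design A [benchmark_design()].
#' @param replicate Replicate index (determines the seed).
#' @return An [sc_counts] of `sum(abundant_sizes) + n_rare` cells whose
#'   provenance records the scenario and rare type.
#' @export
subsample_reference <- function(reference, design, replicate = 1) {
  stopifnot(is(reference, "sc_counts"), is(design, "benchmark_design"))
  if (is.null(reference$labels))
    abort("`reference` must carry cell type labels")
  wanted <- c(stats::setNames(design$abundant_sizes,
                              design$abundant_types),
              stats::setNames(design$n_rare, design$rare_type))
  avail <- table(reference$labels)
  for (ty in names(wanted)) {
    if (is.na(avail[ty]) || avail[ty] < wanted[ty])
      abort(paste0("reference has fewer '", ty, "' cells (",
                   ifelse(is.na(avail[ty]), 0, avail[ty]),
                   ") than requested (", wanted[ty], ")"))
  }
  cells <- with_seed(design$seed_base + replicate,
    unlist(lapply(names(wanted), function(ty)
      sample(which(reference$labels == ty), wanted[ty]))))
  out <- reference[cells, ]
  out$provenance <- c(out$provenance, list(benchmark = list(
    setting = design$setting, n_rare = design$n_rare,
    replicate = replicate, rare_type = design$rare_type,
    seed = design$seed_base + replicate)))
  out
}

#' Run the rare-cell benchmark sweep
#'
#' For each scenario (number of rare cells) and replicate, draws a
#' dataset from the reference, preprocesses it once, and clusters it with
#' each requested method at each resolution, scoring rare-cell accuracy
#' and ARI against the planted labels. Failures in individual replicates
#' are logged as warnings and reported as `NA` rows rather than aborting
#' the sweep.
#'
#' @param reference Labeled [sc_counts] reference.
#' @param design A [benchmark_design()]; its `n_rare` is overridden by
#'   each value of `n_rare_values`.
#' @param n_rare_values Scenario sizes to sweep.
#' @param n_replicates Replicates per scenario (default from `design`).
#' @param methods Any of `"adaptive"`, `"fixed"`.
#' @param resolutions Louvain resolutions to score.
#' @param k_max,delta,fixed_k,prune,n_hvg,n_pcs Pipeline parameters; the
#'   preprocessing defaults are scaled to the 1,000-gene synthetic
#'   reference.
#' @param min_genes_per_cell Cell filter used on each drawn dataset.
#' @param seed Base RNG seed for clustering.
#' @return An `aknn_benchmark` tibble with one row per
#'   scenario x replicate x method x resolution:
#'   `setting, n_rare, replicate, method, resolution, n_communities,
#'   rare_accuracy, ari`.
#' @export
run_benchmark <- function(reference, design = benchmark_design(),
                          n_rare_values = design$n_rare,
                          n_replicates = design$n_replicates,
                          methods = c("adaptive", "fixed"),
                          resolutions = c(0.1, 0.3, 0.5, 0.8),
                          k_max = 20, delta = -0.5, fixed_k = 20,
                          prune = 1 / 15, n_hvg = 500, n_pcs = 30,
                          min_genes_per_cell = 200, seed = 0) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- tidyr::expand_grid(n_rare = n_rare_values,
                             replicate = seq_len(n_replicates))
  res <- purrr::pmap_dfr(grid, function(n_rare, replicate) {
    des <- design
    des$n_rare <- as.integer(n_rare)
    scores <- tryCatch({
      ds <- subsample_reference(reference, des, replicate)
      truth <- unname(ds$labels)
      filt <- filter_cells_genes(ds, min_genes_per_cell, 3)
      truth <- truth[rownames(ds$counts) %in% rownames(filt$counts)]
      hvg <- select_hvg_vst(filt, n_hvg = min(n_hvg, ncol(filt$counts)))
      emb <- pca_embed(normalize_log(filt), hvg,
                       n_pcs = min(n_pcs, length(hvg)))
      nbrs <- neighbor_table(emb, k_max = k_max)
      purrr::map_dfr(methods, function(m) {
        g <- if (m == "adaptive") build_adaptive_graph(nbrs, delta)
             else build_fixed_graph(nbrs, fixed_k)
        snn <- snn_jaccard(g, prune)
        purrr::map_dfr(resolutions, function(r) {
          cl <- louvain_cluster(snn, resolution = r, seed = seed)
          dplyr::mutate(
            evaluate_clustering(cl, truth, rare_type = des$rare_type),
            method = m, resolution = r, .before = 1)
        })
      })
    }, error = function(e) {
      warn(sprintf("replicate %d (n_rare %d) failed: %s", replicate,
                   n_rare, conditionMessage(e)))
      tidyr::expand_grid(method = methods, resolution = resolutions,
                         ari = NA_real_, n_communities = NA_integer_,
                         rare_accuracy = NA_real_)
    })
    dplyr::mutate(scores, setting = design$setting, n_rare = n_rare,
                  replicate = replicate, .before = 1)
  })
  res <- dplyr::select(res, "setting", "n_rare", "replicate", "method",
                       "resolution", "n_communities", "rare_accuracy",
                       "ari")
  class(res) <- c("aknn_benchmark", class(res))
  res
}

#' Per-scenario benchmark means
#'
#' Aggregates a [run_benchmark()] table to mean rare-cell accuracy and
#' mean ARI per setting, scenario size, method and resolution.
#'
#' @param results An `aknn_benchmark` tibble.
#' @return Tibble of per-scenario means with replicate counts.
#' @export
summarize_benchmark <- function(results) {
  out <- results |>
    dplyr::group_by(.data$setting, .data$n_rare, .data$method,
                    .data$resolution) |>
    dplyr::summarise(
      mean_rare_accuracy = mean(.data$rare_accuracy, na.rm = TRUE),
      mean_ari = mean(.data$ari, na.rm = TRUE),
      n_replicates = dplyr::n(), .groups = "drop")
  class(out) <- c("aknn_benchmark_summary", class(out))
  out
}
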