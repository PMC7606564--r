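## End-to-end pipeline: simulate -> count -> enrich -> TSS/motif ->
## geometry -> (optional) TLI, driven by a single run configuration and a
## global seed, writing TSV result tables plus a YAML manifest that echoes
## every threshold.

#' Default run configuration
#'
#' Aggregates the analysis thresholds (enrichment: FC > 1.414 /
#' FC < 0.707, NBM > 1, p < 0.05; TSS: 18-nt cluster window, 50-nt
#' upstream extension, n >= 30 trend gate, sharp value > 4; motif: top-25
#' selection; shifts: 10 nt and TLI 0.1 at FDR < 0.1) together with the
#' simulation configuration.
#'
#' @param sim [sim_config()] to use for data generation.
#' @param seed Global seed (overrides the one in `sim`).
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(sim = sim_config(), seed = sim$seed) {
  sim$seed <- as.integer(seed)
  cfg <- list(
    sim = sim,
    seed = as.integer(seed),
    thresholds = list(
      fc_up = 1.414, fc_down = 0.707, nbm_min = 1, alpha = 0.05,
      window = 18L, upstream = 50L, n_min = 30L, min_reads = 2L,
      sharp_min = 4, motif_top_k = 25L, shift_min = 10, tli_min = 0.1,
      tli_fdr = 0.1, full_length_tol = 3L, count_upstream = 120L,
      count_downstream = 65L
    )
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Unspecified fields fall back to [default_run_config()] values; the
#' `sim` block is passed to [sim_config()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  sim <- do.call(sim_config, sim_args)
  cfg <- default_run_config(sim, seed = y$seed %||% sim$seed)
  for (nm in names(y$thresholds %||% list())) {
    cfg$thresholds[[nm]] <- y$thresholds[[nm]]
  }
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a genome and paired S/N libraries for every configured
#' strain, counts 5'-UTR-window features, runs enrichment and
#' alternative-TSS trend analyses, calls sharp-A TSSs and builds the
#' top-enriched and background promoter matrices, computes per-gene 2D
#' read geometry, full-length fractions and the truncation contrast, and
#' (when at least two strains are configured) the TLI table between the
#' first two strains.  All result tables are written as TSV under `out`;
#' the manifest records the seed and every threshold.  Reruns with the
#' same configuration are byte-identical.
#'
#' @param config A `run_config` from [default_run_config()] /
#'   [read_run_config()].
#' @param out Output directory.
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config, out) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(config$sim)
  expt <- simulate_experiment(sim)
  write_simulation(sim, expt, file.path(out, "sim"))

  strains <- names(config$sim$strains)
  results <- list(sim = sim)
  enrich_by_strain <- list()
  s_reads_by_strain <- list()
  for (st in strains) {
    ix <- expt$samples$strain == st
    sids <- expt$samples$sample_id[ix]
    reads <- expt$reads[expt$reads$sample_id %in% sids, ]
    meta <- expt$samples[ix, ]
    cm <- count_features(reads, sim$annotation,
                         upstream = th$count_upstream,
                         downstream = th$count_downstream)
    enr <- enrichment_test(cm$counts, meta, fc_up = th$fc_up,
                           fc_down = th$fc_down, nbm_min = th$nbm_min,
                           alpha = th$alpha)
    write_results_table(enr, file.path(out, paste0("enrichment_", st, ".tsv")))
    enrich_by_strain[[st]] <- enr
    s_reads_by_strain[[st]] <- reads[meta$group[match(reads$sample_id,
                                                      meta$sample_id)] == "S", ]

    trend <- trend_test_genes(reads, meta, sim$annotation,
                              upstream = th$upstream, window = th$window,
                              min_reads = th$min_reads, n_min = th$n_min)
    write_results_table(trend, file.path(out, paste0("trend_", st, ".tsv")))

    calls <- call_sharp_a(s_reads_by_strain[[st]], sim$annotation, sim$genome,
                          upstream = th$upstream, sharp_min = th$sharp_min)
    write_results_table(calls, file.path(out, paste0("sharpA_", st, ".tsv")))

    shifts <- tss_shift_vs_reference(reads, meta, sim$annotation,
                                     reference = "canonical",
                                     upstream = th$upstream,
                                     shift_min = th$shift_min,
                                     fdr_max = th$tli_fdr)
    write_results_table(shifts, file.path(out, paste0("shifts_", st, ".tsv")))

    prof <- build_2d_profile(reads, meta, sim$annotation,
                             upstream = th$upstream)
    write_results_table(prof, file.path(out, paste0("profile2d_", st, ".tsv")))
    fl <- full_length_fraction(prof, sim$annotation, tol = th$full_length_tol)
    write_results_table(fl, file.path(out, paste0("full_length_", st, ".tsv")))
    contrast <- truncation_contrast(
      fl,
      enriched_ids = enr$feature_id[enr$verdict == "enriched"],
      nonenriched_ids = enr$feature_id[enr$verdict == "ns"]
    )
    write_results_table(as.data.frame(contrast),
                        file.path(out, paste0("truncation_", st, ".tsv")))

    ## promoter matrices for the first strain with enough sharp-A calls
    sa <- calls[calls$is_sharp_a, ]
    top <- select_promoter_set(enr[enr$feature_id %in% sa$gene_id, ],
                               "topK_enriched", k = th$motif_top_k,
                               fc_up = th$fc_up, fc_down = th$fc_down)
    if (length(top) >= 5L) {
      pm <- promoter_matrix(sa[sa$gene_id %in% top, ], sim$annotation,
                            sim$genome)
      pfm <- as.data.frame(t(pm$pfm))
      pfm$position <- as.integer(rownames(pfm))
      pfm$ic <- pm$ic
      write_results_table(pfm, file.path(out, paste0("promoter_pfm_", st, ".tsv")))
    }

    results[[paste0("strain_", st)]] <-
      list(counts = cm, enrich = enr, trend = trend, sharp_a = calls,
           shifts = shifts, full_length = fl, contrast = contrast)
  }

  if (length(strains) >= 2L) {
    tli <- compute_tli(s_reads_by_strain[[1]], s_reads_by_strain[[2]],
                       sim$annotation, upstream = th$upstream,
                       window = th$window, min_reads = th$min_reads,
                       n_min = th$n_min, tli_min = th$tli_min,
                       fdr_max = th$tli_fdr)
    write_results_table(
      tli, file.path(out, paste0("tli_", strains[1], "_vs_", strains[2], ".tsv")))
    results$tli <- tli
  }

  manifest <- list(seed = config$seed, thresholds = th,
                   strains = config$sim$strains,
                   n_genes = config$sim$n_genes,
                   package_version = as.character(utils::packageVersion("nadscape")))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(results)
}
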