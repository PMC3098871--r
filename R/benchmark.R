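#' Default configuration for the synthetic benchmark
#'
#' All tunables of [run_benchmark()] with their defaults: the study-like
#' conditions (500 promoters, 10% bound at fold 3, log2 noise 0.1, 3
#' replicates; 3-replicate 0/2/12/24 h vehicle/SIS3 expression design) and
#' the analysis thresholds (p < 0.01, height > 1.5, >= 2 replicates; motif
#' planting rate 0.7 with a stringent per-window alpha; BH FDR 0.1).
#'
#' @param ... Named overrides of the defaults; unknown names are an error.
#' @return A named list of class `benchmark_config`.
#' @export
benchmark_config <- function(...) {
  cfg <- list(
    n_genes = 500, frac_bound = 0.1, fold = 3, noise_chip_sd_log2 = 0.1,
    n_chip_replicates = 3, B = 199, grid_step = 25,
    p_thresh = 0.01, height_thresh = 1.5, min_reps = 2,
    frag_min = 200, frag_max = 700,
    motif_plant_frac = 0.7, motif_alpha = 5e-5, motif_samples = 200000,
    background_gc = 0.5,
    n_up = 25, n_down = 25, effect_log2 = 1.5, sis3_attenuation = 0.2,
    noise_expr_sd_log2 = 0.25, dye_bias = 0.3, probes_per_gene = 3,
    loess_subset = 5000, loess_epsilon = 0.02, loess_span = 0.7,
    loess_max_iter = 10,
    de_time = 24, de_fdr = 0.1,
    n_gene_sets = 10, gene_set_size = 50, top_k = 57
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "benchmark_config"
  cfg
}

## One global seed fans out to fixed per-stage offsets so each stage is
## reproducible in isolation.
stage_seed <- function(seed, stage) {
  (as.integer(seed) + 101L * stage) %% .Machine$integer.max
}

#' Run the full synthetic benchmark
#'
#' Generates promoter layouts, two-color ChIP arrays with planted binding
#' events, promoter sequences with planted motif instances, an expression
#' time course with planted regulation attenuated under SIS3, and gene
#' sets; runs peak calling, condition comparison, region extraction, motif
#' scanning, cyclic loess normalization, permutation differential testing
#' and Fisher enrichment; and writes per-stage outputs plus a recovery
#' report with the seed needed to reproduce it.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param config A [benchmark_config()].
#' @param verbose Emit stage progress messages.
#' @return Invisibly, the report as a named list (also written to
#'   `report.json` when the jsonlite package is available, and always to
#'   `report.tsv`).
#' @export
run_benchmark <- function(out_dir, seed = 1, config = benchmark_config(),
                          verbose = getOption("tilepeak.verbose", FALSE)) {
  if (!inherits(config, "benchmark_config")) {
    stop("'config' must come from benchmark_config()")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- config
  say <- function(...) if (verbose) message(sprintf(...))

  ## --- ChIP-on-chip stage -------------------------------------------------
  say("stage 1: simulating ChIP arrays")
  layout <- generate_layout(cfg$n_genes, seed = stage_seed(seed, 1))
  write_layout(layout, file.path(out_dir, "layout.tsv"))
  frag <- frag_dist_uniform(cfg$frag_min, cfg$frag_max)
  shape <- peak_shape(frag)
  truth_stim <- plant_chip_truth(layout, cfg$frac_bound, cfg$fold,
                                 condition = "stimulated",
                                 seed = stage_seed(seed, 2))
  truth_basal <- chip_truth(unique(layout$gene_id), 0L, 1, "basal")
  arrays <- simulate_chip_arrays(
    layout, rbind(truth_stim, truth_basal), frag,
    noise_sd_log2 = cfg$noise_chip_sd_log2,
    n_replicates = cfg$n_chip_replicates, seed = stage_seed(seed, 3)
  )
  write_chip_tables(arrays, file.path(out_dir, "chip_tables"))
  utils::write.table(rbind(truth_stim, truth_basal),
                     file.path(out_dir, "chip_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage 2: peak calling")
  calls_stim <- call_condition(arrays, "stimulated", shape,
                               p_thresh = cfg$p_thresh,
                               height_thresh = cfg$height_thresh,
                               min_reps = cfg$min_reps, B = cfg$B,
                               grid_step = cfg$grid_step,
                               seed = stage_seed(seed, 4))
  calls_basal <- call_condition(arrays, "basal", shape,
                                p_thresh = cfg$p_thresh,
                                height_thresh = cfg$height_thresh,
                                min_reps = cfg$min_reps, B = cfg$B,
                                grid_step = cfg$grid_step,
                                seed = stage_seed(seed, 5))
  write_peaks(rbind(calls_stim, calls_basal),
              file.path(out_dir, "peaks.tsv"))
  comparison <- compare_conditions(calls_basal, calls_stim)
  utils::write.table(comparison, file.path(out_dir, "binding_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truly_bound <- truth_stim$gene_id[truth_stim$true_fold > 1]
  called <- calls_stim$gene_id[calls_stim$passes]
  sensitivity <- if (length(truly_bound) > 0) {
    mean(truly_bound %in% called)
  } else NA_real_
  fdp <- if (length(called) > 0) {
    mean(!(called %in% truly_bound))
  } else 0

  ## --- motif stage --------------------------------------------------------
  say("stage 3: motif planting and scanning")
  motif <- read_motif_matrix(
    system.file("extdata", "smad_like_synthetic.transfac",
                package = "tilepeak"),
    dialect = "transfac_counts"
  )
  set.seed(stage_seed(seed, 6))
  plant_genes <- sample(truly_bound,
                        round(cfg$motif_plant_frac * length(truly_bound)))
  centers <- truth_stim$true_center[match(plant_genes, truth_stim$gene_id)]
  plant_at <- stats::setNames(as.integer(centers - motif$width %/% 2),
                              plant_genes)
  seqs <- generate_promoter_sequences(
    layout, motif, plant_in = plant_genes, plant_at = plant_at,
    background_gc = cfg$background_gc, seed = stage_seed(seed, 7)
  )
  write_fasta(seqs$sequences, file.path(out_dir, "promoters.fasta"))
  motif <- calibrate_cutoff(motif, alpha = cfg$motif_alpha,
                            n_samples = cfg$motif_samples,
                            seed = stage_seed(seed, 8))
  regions <- extract_bound_regions(calls_stim, seqs$sequences)
  motif_fraction <- NA_real_
  null_fraction <- NA_real_
  if (nrow(regions) > 0) {
    hits <- fraction_with_hit(regions, motif)
    motif_fraction <- hits$fraction
    utils::write.table(hits$table, file.path(out_dir, "motif_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # chance-hit rate measured on matched windows of unbound promoters
    unbound <- setdiff(unique(layout$gene_id), truly_bound)
    ctrl <- as.character(seqs$sequences[utils::head(unbound, nrow(regions))])
    ctrl <- substr(ctrl, 1300, 1500)
    null_fraction <- fraction_with_hit(ctrl, motif)$fraction
  }

  ## --- expression stage ---------------------------------------------------
  say("stage 4: expression time course")
  gene_ids <- unique(layout$gene_id)
  expr_truth <- plant_expression_truth(
    gene_ids, n_up = cfg$n_up, n_down = cfg$n_down,
    effect_log2 = cfg$effect_log2, sis3_attenuation = cfg$sis3_attenuation,
    seed = stage_seed(seed, 9)
  )
  em <- simulate_expression_timecourse(
    length(gene_ids), gene_ids = gene_ids, truth = expr_truth,
    probes_per_gene = cfg$probes_per_gene, dye_bias = cfg$dye_bias,
    noise_sd_log2 = cfg$noise_expr_sd_log2, seed = stage_seed(seed, 10)
  )
  write_expression_table(em, file.path(out_dir, "expression.tsv"))
  norm <- cyclic_loess_normalize(em, subset_size = cfg$loess_subset,
                                 epsilon = cfg$loess_epsilon,
                                 max_iter = cfg$loess_max_iter,
                                 span = cfg$loess_span,
                                 seed = stage_seed(seed, 11))
  tc <- normalize_to_baseline(summarize_probes_to_genes(norm))
  de_dmso <- de_test_timepoint(tc, "DMSO", cfg$de_time)
  de_sis3 <- de_test_timepoint(tc, "SIS3", cfg$de_time)
  utils::write.table(de_dmso, file.path(out_dir, "de_dmso.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  planted_de <- expr_truth$gene_id[expr_truth$direction != "null"]
  sig_dmso <- de_dmso$gene_id[de_dmso$p_adj < cfg$de_fdr]
  sig_sis3 <- de_sis3$gene_id[de_sis3$p_adj < cfg$de_fdr]
  de_sensitivity <- mean(planted_de %in% sig_dmso)
  sis3_planted_sig <- mean(planted_de %in% sig_sis3)

  ## --- integration stage --------------------------------------------------
  say("stage 5: integration and enrichment")
  integrated <- build_integrated_table(calls_basal, calls_stim, tc)
  utils::write.table(integrated, file.path(out_dir, "integrated_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- top_k(integrated, min(cfg$top_k, nrow(integrated)))
  utils::write.table(top, file.path(out_dir, "top_binding_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- generate_gene_sets(gene_ids, cfg$n_gene_sets, cfg$gene_set_size,
                             enriched_genes = truly_bound,
                             seed = stage_seed(seed, 12))
  write_gmt(sets, file.path(out_dir, "gene_sets.gmt"))
  enr <- if (length(called) > 0) {
    fisher_enrichment(called, sets, gene_ids)
  } else NULL
  if (!is.null(enr)) {
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    seed = seed,
    n_genes = cfg$n_genes,
    n_planted_bound = length(truly_bound),
    n_called_stimulated = sum(calls_stim$passes),
    n_called_basal = sum(calls_basal$passes),
    chip_sensitivity = sensitivity,
    chip_fdp = fdp,
    motif_plant_frac = cfg$motif_plant_frac,
    motif_hit_fraction = motif_fraction,
    motif_null_fraction = null_fraction,
    loess_iterations = attr(norm, "iterations"),
    loess_converged = attr(norm, "converged"),
    de_sensitivity = de_sensitivity,
    de_sis3_planted_sig = sis3_planted_sig,
    enrichment_top_set = if (is.null(enr)) NA_character_ else enr$set_name[1],
    enrichment_top_rank_of_truth = if (is.null(enr)) NA_integer_ else
      which(enr$set_name == "enriched_set")
  )
  report_df <- data.frame(metric = names(report),
                          value = vapply(report, function(x)
                            paste(format(x), collapse = ","), character(1)),
                          stringsAsFactors = FALSE)
  utils::write.table(report_df, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
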