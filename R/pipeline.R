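## End-to-end orchestration: one config, deterministic seeds, a manifest.

default_pipeline_config <- function() {
  list(
    seed = 1,
    simulate = list(n_genes = 100, n_chroms = 2, frac_bound = 0.5,
                    rho_target = 0.56, spacing = 20, gain = 5,
                    noise_sd = 0.3, n_reads = 20000, n_replicates = 2,
                    dispersion = 0.2, n_de = 20, frac_up = 0.7,
                    planted_overlap = 10),
    chipchip = list(p_cutoff = 1e-3, window_bp = 300, maxgap_bp = 300),
    chipseq = list(policy = "mask", read_len = 50),
    metagene = list(flank = 1000, body_bins = 1000),
    classify = list(theta_low = -1, theta_high = 1, min_signal = 0),
    correlate = list(top_fraction = 0.9),
    overlap = list(reps = 1000)
  )
}

merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) {
      user[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      user[[k]] <- merge_config(user[[k]], defaults[[k]])
    }
  }
  user
}

#' Run the occupancy pipeline end-to-end
#'
#' Executes the stages in dependency order on synthetic data: simulate
#' (annotation, occupancy truth, probe arrays, ChIP-seq reads, expression,
#' DE labels) -> per-gene array signals -> enriched-gene calls -> ChIP-seq
#' coverage -> metagene profiles -> occupancy/expression correlation ->
#' ratio classification -> gene-set overlap test. Every artifact is written
#' under `outdir` and listed in `manifest.json` together with the config, a
#' content hash per file, the per-component seeds and the gene counts at
#' each filter. All randomness flows from `config$seed`; the same config
#' yields byte-identical artifacts and manifest hashes.
#'
#' @param config Nested configuration list, or the path to a YAML file; any
#'   missing entries fall back to the documented defaults (see
#'   `tidychip:::default_pipeline_config()`).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(config, default_pipeline_config())
  sim <- config$simulate
  if (sim$planted_overlap > sim$n_de) {
    abort("config error: simulate$planted_overlap must be <= simulate$n_de")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- sim_seeds(config$seed)
  files <- character(0)
  counts <- list()
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  # simulate
  ann <- simulate_annotation(seeds[["annotation"]], n_genes = sim$n_genes,
                             n_chroms = sim$n_chroms)
  truth <- simulate_occupancy(seeds[["occupancy"]], ann,
                              frac_bound = sim$frac_bound,
                              rho_target = sim$rho_target)
  arr_upf1 <- simulate_probe_array(seeds[["probe_array"]], ann, truth,
                                   occupancy = "upf1", spacing = sim$spacing,
                                   gain = sim$gain, noise_sd = sim$noise_sd)
  arr_ctl2 <- simulate_probe_array(seeds[["probe_control"]], ann, truth,
                                   occupancy = "upf1", spacing = sim$spacing,
                                   gain = sim$gain, noise_sd = sim$noise_sd)
  reads <- simulate_chipseq(seeds[["chipseq"]], ann, truth,
                            occupancy = "polii", n_reads = sim$n_reads,
                            read_len = config$chipseq$read_len)
  fpkm <- simulate_expression(seeds[["expression"]], truth,
                              n_replicates = sim$n_replicates,
                              dispersion = sim$dispersion)
  de <- simulate_de_labels(seeds[["de_labels"]], truth, n_de = sim$n_de,
                           frac_up = sim$frac_up,
                           planted_overlap = min(sim$planted_overlap,
                                                 sum(truth$bound)))
  emit("annotation.gff3", function(p) write_annotation(ann, p))
  emit("ground_truth.tsv", function(p) readr::write_tsv(truth, p,
                                                        progress = FALSE))
  emit("probes_ip.tsv", function(p) write_probe_table(arr_upf1$ip, p))
  emit("probes_control_1.tsv",
       function(p) write_probe_table(arr_upf1$control, p))
  emit("probes_control_2.tsv",
       function(p) write_probe_table(arr_ctl2$control, p))
  emit("reads_ip.bed", function(p) write_bed(reads$ip, p))
  emit("reads_input.bed", function(p) write_bed(reads$input, p))
  emit("fpkm.tsv", function(p) readr::write_tsv(fpkm, p, progress = FALSE))
  emit("de_labels.tsv", function(p) readr::write_tsv(de, p, progress = FALSE))
  counts$genes <- nrow(ann$genes)
  counts$bound_genes <- sum(truth$bound)

  # array signals: control pair -> common median -> mean -> normalization
  sig_ip <- summarize_gene_signals(arr_upf1$ip, origin = "ip",
                                   assay = "upf1")
  ctl_pair <- scale_to_common_median(
    summarize_gene_signals(arr_upf1$control, origin = "control",
                           assay = "upf1_control_1"),
    summarize_gene_signals(arr_ctl2$control, origin = "control",
                           assay = "upf1_control_2"))
  sig_ctl <- average_tables(list(ctl_pair$a, ctl_pair$b))
  sig_norm <- normalize_by_control(sig_ip, sig_ctl)
  emit("gene_signal_normalized.tsv",
       function(p) readr::write_tsv(sig_norm, p, progress = FALSE))
  counts$genes_with_signal <- nrow(sig_norm)

  # enriched calls from per-probe normalized values
  pvals <- probe_normalized_values(arr_upf1$ip,
                                   list(arr_upf1$control, arr_ctl2$control))
  calls <- call_enriched_genes(pvals, ann,
                               p_cutoff = config$chipchip$p_cutoff,
                               window_bp = config$chipchip$window_bp,
                               maxgap_bp = config$chipchip$maxgap_bp)
  emit("enriched_calls.tsv",
       function(p) readr::write_tsv(calls, p, progress = FALSE))
  counts$enriched_genes <- sum(calls$enriched)

  # ChIP-seq coverage
  ip_cov <- depth_normalize(coverage_from_reads(reads$ip, ann$chrom_lengths),
                            nrow(reads$ip))
  input_cov <- depth_normalize(
    coverage_from_reads(reads$input, ann$chrom_lengths), nrow(reads$input))
  norm_cov <- input_normalize(ip_cov, input_cov,
                              policy = config$chipseq$policy)
  emit("coverage_normalized.bedgraph",
       function(p) write_bedgraph(norm_cov, p))

  # metagenes
  probe_mg <- build_probe_metagene(pvals, ann)
  seq_mg <- build_flank_body_metagene(norm_cov, ann,
                                      flank = config$metagene$flank,
                                      body_bins = config$metagene$body_bins)
  emit("metagene_probes.tsv", function(p) write_metagene(probe_mg, p))
  emit("metagene_coverage.tsv", function(p) write_metagene(seq_mg, p))

  # correlation with expression
  expr <- mean_log_fpkm(fpkm)
  corr_df <- dplyr::inner_join(
    dplyr::select(sig_norm, "gene_id", "signal"), expr, by = "gene_id")
  corr <- spearman_correlation(corr_df, .data$signal, .data$log_fpkm,
                               top_expressed_fraction =
                                 config$correlate$top_fraction)
  emit("correlation.tsv",
       function(p) readr::write_tsv(corr, p, progress = FALSE))

  # ratio classification on the measured signal columns
  classified <- classify_ratio_groups(
    dplyr::select(truth, "gene_id", signal = "upf1_signal"),
    dplyr::select(truth, "gene_id", signal = "polii_signal"),
    theta_low = config$classify$theta_low,
    theta_high = config$classify$theta_high,
    min_signal = config$classify$min_signal)
  emit("ratio_groups.tsv",
       function(p) readr::write_tsv(classified, p, progress = FALSE))
  counts$ratio_groups <- as.list(table(classified$group))

  # overlap of enriched genes with DE labels
  enriched_ids <- calls$gene_id[calls$enriched]
  overlap <- overlap_permutation_test(
    set_a = enriched_ids, universe_a = ann$genes$gene_id,
    set_b = de$gene_id, universe_b = ann$genes$gene_id,
    reps = config$overlap$reps, seed = seeds[["permutation"]])
  emit("overlap_test.tsv",
       function(p) readr::write_tsv(tidy(overlap), p, progress = FALSE))

  manifest <- list(
    config = config,
    seeds = as.list(seeds),
    counts = counts,
    files = lapply(files, function(p) {
      list(path = basename(p),
           hash = rlang::hash(readLines(p, warn = FALSE)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annotation = ann, truth = truth, signals = sig_norm,
                 calls = calls, coverage = norm_cov,
                 metagene_probes = probe_mg, metagene_coverage = seq_mg,
                 correlation = corr, classified = classified,
                 overlap = overlap, manifest = manifest))
}
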