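# End-to-end orchestration over synthetic inputs: genome + genes,
# coverage tracks, CNC calling and replicate intersection, permutation
# enrichment, traveling-ratio and GC-skew stratified comparisons, and
# qPCR tables. Every stage writes a TSV next to a resolved-config JSON
# and a machine-readable summary, and two runs with the same config are
# identical.

#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with the analysis parameters
#' (permutation count, promoter window, thresholds, stratification
#' quantiles). All analysis defaults mirror the constants the pipeline
#' is built around: a -30/+300 bp promoter window, 1,000 permutations,
#' 10%/90% skew quantiles, and a 100-kb gene-length cutoff.
#'
#' @param sim a [sim_config()] list.
#' @param n_perm permutations for the enrichment tests.
#' @param promoter_upstream,promoter_downstream promoter window in bp.
#' @param cnc_threshold_log2,cnc_min_probes CNC-caller parameters.
#' @param active_enrichment,active_min_density active-gene thresholds.
#' @param skew_low_quantile,skew_high_quantile GC-skew stratification
#'   quantiles.
#' @param length_threshold_bp short/long gene-length cutoff.
#' @return a validated nested configuration list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_perm = 1000,
                            promoter_upstream = 30,
                            promoter_downstream = 300,
                            cnc_threshold_log2 = 0.5,
                            cnc_min_probes = 5,
                            active_enrichment = 2,
                            active_min_density = 0.25,
                            skew_low_quantile = 0.10,
                            skew_high_quantile = 0.90,
                            length_threshold_bp = 1e5) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Rejects out-of-range parameters with a targeted message before any
#' stage runs.
#'
#' @param cfg a configuration list as built by [pipeline_config()].
#' @return the configuration, invisibly usable.
#' @export
validate_pipeline_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg)
  check(cfg$n_perm >= 1, "n_perm must be >= 1")
  check(cfg$promoter_upstream >= 0, "promoter_upstream must be >= 0")
  check(cfg$promoter_downstream > 0, "promoter_downstream must be > 0")
  check(cfg$cnc_threshold_log2 > 0, "cnc_threshold_log2 must be > 0")
  check(cfg$cnc_min_probes >= 1, "cnc_min_probes must be >= 1")
  check(cfg$active_enrichment > 0, "active_enrichment must be > 0")
  check(cfg$active_min_density > 0, "active_min_density must be > 0")
  check(cfg$skew_low_quantile > 0 &&
          cfg$skew_low_quantile < cfg$skew_high_quantile &&
          cfg$skew_high_quantile < 1,
        "need 0 < skew_low_quantile < skew_high_quantile < 1")
  check(cfg$length_threshold_bp > 0, "length_threshold_bp must be > 0")
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Generates the synthetic genome, coverage, array and qPCR inputs from
#' `cfg$sim`, runs every analysis stage, and writes per-stage TSVs plus
#' `summary.json` and the fully resolved `config.json` into `outdir`.
#' Identical configurations produce byte-identical numeric outputs.
#'
#' @param cfg a [pipeline_config()] list.
#' @param outdir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with the summary and the main in-memory
#'   results.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  sim <- cfg$sim

  say("stage 1/5: synthetic genome and gene models")
  gg <- simulate_genome_genes(sim)
  writeXStringSet(gg$genome_seq, file.path(outdir, "genome.fa"))
  write_gene_table(gg$genes, file.path(outdir, "genes.tsv"))
  write_chrom_sizes(gg$genome, file.path(outdir, "chrom.sizes"))

  say("stage 2/5: copy-number changes and fragile-site enrichment")
  cncsim <- simulate_cnc_features(gg$genome, sim)
  rep1 <- call_cnc(simulate_probe_table(cncsim$cnc, gg$genome,
                                        spacing = sim$probe_spacing_bp,
                                        noise_sd = sim$probe_noise_sd,
                                        amplitude = sim$cnc_amplitude,
                                        seed = sim$seed + 101L),
                   cfg$cnc_threshold_log2, cfg$cnc_min_probes, gg$genome)
  rep2 <- call_cnc(simulate_probe_table(cncsim$cnc, gg$genome,
                                        spacing = sim$probe_spacing_bp,
                                        noise_sd = sim$probe_noise_sd,
                                        amplitude = sim$cnc_amplitude,
                                        seed = sim$seed + 102L),
                   cfg$cnc_threshold_log2, cfg$cnc_min_probes, gg$genome)
  common <- intersect_replicates(rep1, rep2)
  cnc_sum <- summarize_cnc(common, gg$genes)
  write_bed(common, file.path(outdir, "cnc_common.bed"))
  write_bed(cncsim$features, file.path(outdir, "features.bed"))
  perm <- list(
    gain_vs_features = permutation_overlap_test(
      common[mcols(common)$cnc_class == "gain"], cncsim$features,
      gg$genome, n_perm = cfg$n_perm, seed = sim$seed + 11L),
    loss_vs_features = permutation_overlap_test(
      common[mcols(common)$cnc_class == "loss"], cncsim$features,
      gg$genome, n_perm = cfg$n_perm, seed = sim$seed + 12L))
  perm_tab <- permutation_result_table(perm)
  tsv(perm_tab, "permutation_tests.tsv")
  tsv(data.frame(region = seq_along(common),
                 distance_kb = nearest_tss_distance(common, gg$genes),
                 gene_count = genes_per_region(common, gg$genes,
                                               window_bp = 10000)),
      "cnc_annotation.tsv")

  say("stage 3/5: RNAPII traveling ratios")
  chip_wt <- simulate_coverage(gg$genes, gg$genome, "chip",
                               pausing = sim$pausing_wt, config = sim,
                               seed = sim$seed + 21L)
  # pausing increases on SETX loss preferentially at high-GC-skew
  # (R-loop-prone) promoters: high-skew genes get the KO pausing factor,
  # low-skew genes keep the WT one
  pausing_ko_gene <- setNames(ifelse(gg$genes$skew_class == "high",
                                     sim$pausing_ko, sim$pausing_wt),
                              gg$genes$gene_id)
  chip_ko <- simulate_coverage(gg$genes, gg$genome, "chip",
                               pausing = pausing_ko_gene, config = sim,
                               seed = sim$seed + 22L)
  input_wt <- simulate_coverage(gg$genes, gg$genome, "input", config = sim,
                                seed = sim$seed + 23L)
  input_ko <- simulate_coverage(gg$genes, gg$genome, "input", config = sim,
                                seed = sim$seed + 24L)
  tr_args <- list(upstream = cfg$promoter_upstream,
                  downstream = cfg$promoter_downstream)
  tr_wt <- do.call(traveling_ratio, c(list(chip_wt, gg$genes), tr_args))
  tr_ko <- do.call(traveling_ratio, c(list(chip_ko, gg$genes), tr_args))
  tr_in_wt <- do.call(traveling_ratio, c(list(input_wt, gg$genes), tr_args))
  tr_in_ko <- do.call(traveling_ratio, c(list(input_ko, gg$genes), tr_args))
  rotr_wt <- ratio_of_traveling_ratios(tr_wt, tr_in_wt)
  rotr_ko <- ratio_of_traveling_ratios(tr_ko, tr_in_ko)
  active <- call_active_genes(chip_wt, input_wt, gg$genes,
                              cfg$active_enrichment, cfg$active_min_density)
  expressed_tr <- merge(
    data.frame(gene_id = rotr_wt$gene_id, rotr_wt = rotr_wt$rotr),
    data.frame(gene_id = rotr_ko$gene_id, rotr_ko = rotr_ko$rotr),
    by = "gene_id")
  expressed_tr <- expressed_tr[expressed_tr$gene_id %in% active, ]
  cmp <- compare_distributions(expressed_tr$rotr_ko, expressed_tr$rotr_wt)
  tsv(merge(tr_wt, tr_ko, by = "gene_id",
            suffixes = c("_wt", "_ko")), "traveling_ratios.tsv")
  tsv(expressed_tr, "rotr_active_genes.tsv")

  say("stage 4/5: GC skew and length stratification")
  skew <- genic_gcskew(gg$genome_seq, gg$genes, mode = "promoter_proximal",
                       upstream = cfg$promoter_upstream,
                       downstream = cfg$promoter_downstream)
  strat <- stratify_by_gcskew(skew, active,
                              cfg$skew_low_quantile, cfg$skew_high_quantile)
  tr_diff <- merge(
    data.frame(gene_id = tr_wt$gene_id[!tr_wt$excluded],
               tr_wt = tr_wt$tr[!tr_wt$excluded]),
    data.frame(gene_id = tr_ko$gene_id[!tr_ko$excluded],
               tr_ko = tr_ko$tr[!tr_ko$excluded]),
    by = "gene_id")
  tr_diff$delta <- tr_diff$tr_ko - tr_diff$tr_wt
  hi <- tr_diff$delta[tr_diff$gene_id %in% strat$high]
  lo <- tr_diff$delta[tr_diff$gene_id %in% strat$low]
  skew_cmp <- if (length(hi) && length(lo)) {
    compare_distributions(hi, lo)
  } else list(statistic = NA_real_, p_value = NA_real_, method = "none")
  lengths <- stratify_by_length(gg$genes,
                                threshold_bp = cfg$length_threshold_bp)
  tsv(skew, "gcskew.tsv")

  say("stage 5/5: qPCR quantification")
  truth <- data.frame(
    sample = rep(c("CTRL", "SETXko"), each = 3),
    region = rep(c("locusA", "locusB", "negctrl"), 2),
    percent_input_true = c(1, 1, 1, 5, 3, 1))
  ct <- simulate_qpcr(truth, sim, seed = sim$seed + 31L)
  qp <- summarize_qpcr(ct, negctrl_region = "negctrl")
  tsv(ct, "qpcr_ct.tsv")
  tsv(qp, "qpcr_summary.tsv")

  summary <- list(
    n_genes = nrow(gg$genes),
    n_cnc_rep1 = length(rep1), n_cnc_rep2 = length(rep2),
    n_cnc_common = length(common),
    cnc_genic_fraction_pct = cnc_sum$genic_fraction_pct,
    gain_enrichment = perm_tab[1, c("statistic", "z", "p_value",
                                    "p_empirical", "direction")],
    loss_enrichment = perm_tab[2, c("statistic", "z", "p_value",
                                    "p_empirical", "direction")],
    n_active_genes = length(active),
    median_rotr_wt = median(expressed_tr$rotr_wt),
    median_rotr_ko = median(expressed_tr$rotr_ko),
    rotr_wilcoxon_p = cmp$p_value,
    n_skew_high = length(strat$high), n_skew_low = length(strat$low),
    skew_delta_tr_p = skew_cmp$p_value,
    n_short_genes = length(lengths$short),
    n_long_genes = length(lengths$long),
    seed = sim$seed)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", outdir)
  invisible(list(summary = summary, genes = gg$genes, cnc = common,
                 permutation = perm, rotr = expressed_tr,
                 stratification = strat, qpcr = qp))
}
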