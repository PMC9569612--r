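#' Cohort mutation summary
#'
#' Counts and percentages of mutated patients. Display percentages are
#' rounded to the nearest integer (as in the published cohort summary:
#' 17/186 -> 9%, 13/186 -> 7%); the exact fraction is retained.
#'
#' @param samples sample sheet data.frame.
#' @return data.frame with mutation, n, total, fraction, percent.
#' @export
cohort_summary <- function(samples) {
  total <- nrow(samples)
  counts <- c(RUNX1 = sum(samples$runx1_mutated, na.rm = TRUE),
              CEBPA = sum(samples$cebpa_mutated, na.rm = TRUE))
  data.frame(mutation = names(counts), n = unname(counts), total = total,
             fraction = unname(counts) / total,
             percent = round(100 * unname(counts) / total),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generates a synthetic study under the scenario, then runs every
#' stage in dependency order: motif scan (optional, when sequences are
#' requested), Traffic Lights, differential methylation/expression,
#' proximity stratification and proportion contrast, coverage
#' metaprofiles, stage profiles, deconvolution, and landmark survival.
#' All thresholds come from the config only. Returns every stage result
#' plus a run manifest (config snapshot, seed, per-stage record counts).
#'
#' @param scenario a `simulation_scenario`.
#' @param config a `pipeline_config`.
#' @param motif optional `motif_model`; when supplied, sequences are
#'   generated and proximity is recomputed by scanning (otherwise the
#'   generator's truth labels stand in for the scan).
#' @param outdir optional directory; when given, stage outputs are
#'   written as TSV/BED/bedGraph/FASTA files and checksummed.
#' @return list of stage results with elements `sim`, `proximity`,
#'   `tls`, `dm`, `deg`, `strat`, `prop_test`, `gene_table`,
#'   `profiles`, `stage_means`, `deconv`, `surv`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(scenario, config = pipeline_config(),
                         motif = NULL, outdir = NULL) {
  mut_col <- if (scenario$preset == "cebpa") "cebpa_mutated" else
    "runx1_mutated"
  if (!is.null(motif)) {
    gen <- simulate_genome_with_motifs(
      motif, scenario$n_cpgs, scenario$frac_near_tfbs,
      window_halfwidth = scenario$window_halfwidth,
      seed = scenario$rng_seed)
    truth0 <- gen$truth[c("cpg_id", "gene", "near_tfbs")]
    sites <- scan_windows(gen$genome, gen$manifest, motif,
                          window_halfwidth = scenario$window_halfwidth)
    proximity <- annotate_cpg_proximity(gen$manifest, sites)
    manifest <- gen$manifest
  } else {
    truth0 <- simulate_truth_table(scenario$n_cpgs,
                                   scenario$frac_near_tfbs,
                                   seed = scenario$rng_seed)
    proximity <- data.frame(cpg_id = truth0$cpg_id,
                            near_tfbs = truth0$near_tfbs,
                            stringsAsFactors = FALSE)
    manifest <- data.frame(cpg_id = truth0$cpg_id, chrom = "sim",
                           pos = scenario$window_halfwidth,
                           gene = truth0$gene, stringsAsFactors = FALSE)
    sites <- NULL
  }
  sim <- simulate_cohort(scenario, truth0)
  cohort <- sim$cohort

  tls <- call_traffic_lights(cohort, manifest, config)
  dm <- call_dm_dhm(cohort, mut_col, config)
  deg <- call_deg(cohort, mut_col, config)
  strat <- stratify_delta(dm, proximity, restrict = "dm")
  near <- proximity$near_tfbs[match(dm$feature_id, proximity$cpg_id)]
  prop <- proportion_test(dm$is_dhm[near], dm$is_dhm[!near])
  gene_table <- select_strong_tl_genes(tls, dm, deg, proximity, config)

  track <- simulate_coverage(
    if (is.null(motif)) manifest_per_contig(manifest) else manifest,
    truth0, scenario$coverage_enrichment,
    contig_length = 2L * scenario$window_halfwidth,
    seed = scenario$rng_seed + 1L)
  profiles <- metaprofile_by_class(
    track, if (is.null(motif)) manifest_per_contig(manifest) else manifest,
    proximity, flank_bp = scenario$window_halfwidth,
    n_bins = 20L)

  stage_beta <- simulate_stage_profiles(sim$truth,
                                        seed = scenario$rng_seed + 2L)
  strong <- strong_traffic_lights(tls, dm, deg)
  stage_cpgs <- if (nrow(strong)) strong$cpg_id else
    sim$truth$cpg_id[sim$truth$near_tfbs]
  stage_means <- stage_profile(stage_cpgs, stage_beta, cohort, mut_col,
                               n_boot = 200L)

  est <- estimate_proportions_matrix(sim$marker_beta, sim$atlas)
  deconv <- list(
    estimates = est,
    comparison = compare_cell_proportions(est$proportions,
                                          cohort$samples[[mut_col]]))

  surv <- survival_by_cpg(cohort, sim$survival_cpg, config)
  summary <- cohort_summary(cohort$samples)

  manifest_rec <- list(
    config = unclass(config), seed = scenario$rng_seed,
    preset = scenario$preset,
    counts = c(cpgs = nrow(dm), genes = nrow(deg),
               tested_pairs = nrow(tls), tl = sum(tls$is_tl),
               dm = sum(dm$is_dm), dhm = sum(dm$is_dhm),
               deg = sum(deg$is_dm), strong_tl = nrow(strong),
               genes_prioritized = nrow(gene_table)),
    r_version = as.character(getRversion()))

  out <- list(sim = sim, sites = sites, proximity = proximity,
              tls = tls, dm = dm, deg = deg, strat = strat,
              prop_test = prop, gene_table = gene_table,
              profiles = profiles, stage_means = stage_means,
              deconv = deconv, surv = surv, summary = summary,
              manifest = manifest_rec)
  if (!is.null(outdir)) {
    out$manifest$checksums <- write_pipeline_outputs(out, cohort, outdir)
  }
  out
}

# when no genome was generated each CpG still needs its own contig for
# the coverage simulation
manifest_per_contig <- function(manifest) {
  manifest$chrom <- sprintf("locus%06d", seq_len(nrow(manifest)))
  manifest
}

write_pipeline_outputs <- function(out, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)
  write_value_matrix(cohort$beta, path("beta.tsv"))
  write_value_matrix(cohort$expression, path("expression.tsv"),
                     id_col = "gene")
  utils::write.table(cohort$samples, path("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$tls, path("traffic_lights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$dm, path("dm_cpgs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$deg, path("deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(out$gene_table, path("strong_tl_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$strat$summary, path("delta_strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- list.files(outdir, full.names = TRUE)
  stats::setNames(as.character(tools::md5sum(files)), basename(files))
}
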