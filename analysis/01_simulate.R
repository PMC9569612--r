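#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Builds a RUNX-like position count matrix, derives its log-odds model at
# the p < 0.001 exact threshold, plants motif instances in CpG-centered
# 200 bp loci, and simulates the full RUNX1-scenario cohort: 186 patients
# (17 mutated), beta gains of 0.18 near planted motifs and 0.06 at a
# fraction of distal CpGs, methylation-expression coupling, cell-type
# mixtures, coverage, stage profiles and survival. Everything downstream
# reads the flat files written here.

suppressMessages(library(cpgtl))
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

# RUNX core binding motif (TGTGGTTT-like), written as a plain-text PCM
pcm <- rbind(
  c(  5, 10,  8, 77),   # T
  c(  4,  6, 85,  5),   # G
  c(  6,  4,  6, 84),   # T
  c(  3,  5, 88,  4),   # G
  c(  4,  3, 89,  4),   # G
  c( 12, 10,  8, 70),   # T
  c( 15, 12, 13, 60),   # T
  c( 25, 15, 15, 45))   # T
colnames(pcm) <- c("A", "C", "G", "T")
write_pwm(pcm, file.path(outdir, "runx_motif.pcm"), name = "RUNX_core")

motif <- build_motif(pcm, target_pvalue = 0.001, name = "RUNX_core")
print(motif)

scenario <- simulation_scenario("runx1", n_cpgs = 400, rng_seed = seed)
gen <- simulate_genome_with_motifs(motif, scenario$n_cpgs,
                                   scenario$frac_near_tfbs, seed = seed)
write_genome(gen$genome, file.path(outdir, "genome.fa"))
write_cpg_manifest(gen$manifest, file.path(outdir, "manifest.tsv"))

sim <- simulate_cohort(scenario, gen$truth[c("cpg_id", "gene", "near_tfbs")])
write_value_matrix(sim$cohort$beta, file.path(outdir, "beta.tsv"))
write_value_matrix(sim$cohort$expression,
                   file.path(outdir, "expression.tsv"), id_col = "gene")
write.table(sim$cohort$samples, file.path(outdir, "samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(sim$truth,
                  motif_start = gen$truth$motif_start,
                  motif_strand = gen$truth$motif_strand),
            file.path(outdir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_value_matrix(sim$atlas, file.path(outdir, "atlas.tsv"),
                   id_col = "cpg_id")
write_value_matrix(sim$marker_beta, file.path(outdir, "marker_beta.tsv"),
                   id_col = "cpg_id")
write_value_matrix(sim$cell_fractions,
                   file.path(outdir, "cell_fractions_truth.tsv"),
                   id_col = "sample_id")
writeLines(sim$survival_cpg, file.path(outdir, "survival_cpg.txt"))

# ChIP-like peaks over the planted motifs (what a Cistrome track would
# supply), padded by 20 bp
planted <- gen$truth[gen$truth$near_tfbs, ]
peaks <- data.frame(chrom = gen$manifest$chrom[match(planted$cpg_id,
                                                     gen$manifest$cpg_id)],
                    start = pmax(0L, planted$motif_start - 20L),
                    end = pmin(200L, planted$motif_start +
                                 nrow(motif$log_odds) + 20L))
write_bed(peaks, file.path(outdir, "peaks.bed"))

track <- simulate_coverage(gen$manifest, gen$truth,
                           scenario$coverage_enrichment, seed = seed + 1L)
write_bedgraph(track, file.path(outdir, "tet2_coverage.bedGraph"))

stages <- simulate_stage_profiles(sim$truth, n_stages = 5,
                                  seed = seed + 2L)
write_value_matrix(stages, file.path(outdir, "stages.tsv"))

cs <- cohort_summary(sim$cohort$samples)
print(cs)
cat(sprintf("\nSimulated %d CpG loci (%d motif-proximal), %d samples.\n",
            scenario$n_cpgs, sum(gen$truth$near_tfbs),
            scenario$n_samples))
cat(sprintf("Cohort summary: %d/%d RUNX1-mutated (%d%%).\n",
            cs$n[1], cs$total[1], cs$percent[1]))
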