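#!/usr/bin/env Rscript
# Stage 4 — differential methylation, expression, and gene prioritization.
#
# Pooled-variance t-tests between RUNX1-mutated and wild-type patients:
# DM CpGs at FDR < 0.05, DHM CpGs additionally requiring delta > 0.15,
# DEGs on the expression side, then the published gene gates
# (strong Traffic Light, FC > 2, FDR < 0.05, expression > 0.5).

suppressMessages(library(cpgtl))
indir <- "results/synthetic"
manifest <- read_cpg_manifest(file.path(indir, "manifest.tsv"))
beta <- read_beta_matrix(file.path(indir, "beta.tsv"), manifest)
expr <- read_expression_matrix(file.path(indir, "expression.tsv"))
samples <- read_sample_sheet(file.path(indir, "samples.tsv"))
truth <- read.delim(file.path(indir, "truth.tsv"))
prox <- read.delim("results/cpg_proximity.tsv")
tls <- read.delim("results/traffic_lights.tsv")

cohort <- cohort_matrices(beta, expr, samples)
cfg <- pipeline_config()
dm <- call_dm_dhm(cohort, "runx1_mutated", cfg)
deg <- call_deg(cohort, "runx1_mutated", cfg)
genes <- select_strong_tl_genes(tls, dm, deg, prox, cfg)

write.table(dm, "results/dm_cpgs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(deg, "results/deg.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(genes, "results/strong_tl_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

planted <- truth$gene[truth$is_strong_gene]
cat(sprintf("DM CpGs: %d; DHM CpGs: %d; DEGs: %d.\n",
            sum(dm$is_dm), sum(dm$is_dhm), sum(deg$is_dm)))
cat(sprintf("Prioritized genes: %d (planted: %d; recovered: %d).\n",
            nrow(genes), length(planted),
            sum(planted %in% genes$gene)))
print(genes[, c("gene", "n_strong_tl", "fc", "expr_q")], digits = 3)
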