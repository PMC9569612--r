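#!/usr/bin/env Rscript
# Stage 7 — survival.
#
# (a) Kaplan-Meier and log-rank comparison of the cohort dichotomized at
#     the designated survival CpG (median rule), overall and with the
#     500-day landmark.
# (b) The late-divergence scenario: hazard ratio 1 before day 500 and 3
#     after, where the landmark test is expected to detect what the
#     overall test dilutes; significance rates over 30 generator seeds.

suppressMessages(library(cpgtl))
indir <- "results/synthetic"
manifest <- read_cpg_manifest(file.path(indir, "manifest.tsv"))
beta <- read_beta_matrix(file.path(indir, "beta.tsv"), manifest)
expr <- read_expression_matrix(file.path(indir, "expression.tsv"))
samples <- read_sample_sheet(file.path(indir, "samples.tsv"))
cohort <- cohort_matrices(beta, expr, samples)
surv_cpg <- readLines(file.path(indir, "survival_cpg.txt"))[1]

sv <- survival_by_cpg(cohort, surv_cpg)
cat(sprintf("Survival at %s (median dichotomization):\n", surv_cpg))
cat(sprintf("  overall log-rank:      chi2 = %.2f, p = %.3g\n",
            sv$overall$chi2, sv$overall$p))
cat(sprintf("  landmark (> 500 days): chi2 = %.2f, p = %.3g\n",
            sv$landmark$chi2, sv$landmark$p))
km_tab <- do.call(rbind, lapply(names(sv$km), function(g) {
  if (!nrow(sv$km[[g]])) return(NULL)
  cbind(group = g, sv$km[[g]])
}))
write.table(km_tab, "results/kaplan_meier.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

res <- t(sapply(1:30, function(s) {
  d <- simulate_survival_landmark(n = 186, hr_before = 1, hr_after = 3,
                                  changepoint = 500, seed = 500 + s)
  c(overall_p = logrank(d$time, d$event, d$group)$p,
    landmark_p = logrank(d$time, d$event, d$group,
                         landmark_days = 500)$p)
}))
write.table(data.frame(seed = 1:30, res),
            "results/landmark_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nLate-divergence scenario over 30 seeds:\n"))
cat(sprintf("  landmark-500 significant: %.0f%% of seeds\n",
            100 * mean(res[, "landmark_p"] < 0.05, na.rm = TRUE)))
cat(sprintf("  overall non-significant:  %.0f%% of seeds\n",
            100 * mean(res[, "overall_p"] >= 0.05)))
cat("The landmark test isolates the late divergence; the overall test\n")
cat("dilutes it with the shared early hazard.\n")
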