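# cpgtl

DNA methylation analysis around transcription-factor binding sites in
AML, built as a reusable R pipeline. RUNX1 and CEBPA normally keep the
DNA near their binding sites unmethylated (recruiting the demethylase
TET2); in patients whose factor is mutated, those sites gain
methylation and the factor's target genes are silenced. `cpgtl`
implements every computational step of that analysis:

* **PWM motif scanning** of CpG-centered ±100 bp windows on both
  strands, with the match threshold derived from the *exact* score
  distribution at p < 0.001 (dynamic-programming convolution, verified
  against exhaustive enumeration), and ChIP-peak filtering of predicted
  sites.
* **CpG Traffic Lights** — CpGs whose methylation correlates with the
  expression of their associated gene (Spearman across patients,
  Benjamini–Hochberg FDR < 0.005).
* **Differential methylation/expression** between mutated and
  wild-type patients (pooled-variance t, BH FDR < 0.05), with
  differentially hypermethylated CpGs requiring Δmeth > 0.15, and the
  prioritized gene list (strong Traffic Light, FC > 2, FDR < 0.05,
  expression > 0.5).
* **TFBS-proximity effects** — Δmeth stratified near sites vs the
  rest, Fisher tests on hypermethylated proportions, coverage
  metaprofiles around CpG classes, and maturation-stage profiles.
* **Cell-type deconvolution** by constrained least squares
  (w ≥ 0, Σw = 1) against a reference atlas.
* **Survival** — Kaplan–Meier and log-rank, including the landmark
  variant conditioning on survival past day 500.
* **A synthetic-cohort generator** that plants all of the above at the
  published effect sizes (186 patients, 17/13 mutated, Δmeth 0.18/0.06
  near/far for RUNX1 and 0.13/0.09 for CEBPA, 12/11 strong-TL genes),
  so every stage is validated against known truth.

## Worked example

```r
library(cpgtl)

scenario <- simulation_scenario("runx1", n_cpgs = 2000, rng_seed = 7)
truth    <- simulate_truth_table(2000, scenario$frac_near_tfbs, seed = 7)
sim      <- simulate_cohort(scenario, truth)
cfg      <- pipeline_config()

manifest <- data.frame(cpg_id = truth$cpg_id, chrom = "sim",
                       pos = 100L, gene = truth$gene)
tls <- call_traffic_lights(sim$cohort, manifest, cfg)
dm  <- call_dm_dhm(sim$cohort, "runx1_mutated", cfg)
deg <- call_deg(sim$cohort, "runx1_mutated", cfg)
prox <- data.frame(cpg_id = truth$cpg_id, near_tfbs = truth$near_tfbs)

stratify_delta(dm, prox)$summary
#>     stratum   n mean_delta prop_hyper
#> 1 near_tfbs 100 0.17808873  1.0000000
#> 2      rest 584 0.05704939  0.9828767

nrow(select_strong_tl_genes(tls, dm, deg, prox, cfg))
#> [1] 12
```

The stratified means recover the planted gains (0.18 near predicted
RUNX1 sites, 0.06 elsewhere, over differentially methylated CpGs), and
the published gene gates recover exactly the 12 planted
strong-Traffic-Light genes.

The full analysis lives in `analysis/01_simulate.R` …
`analysis/07_survival.R` — numbered drivers that write their inputs
and result tables under `results/` and narrate what they find (site
prediction vs planted truth, Traffic-Light sensitivity and FDR,
DM/DHM/DEG counts, stratified Δmeth, the coverage metaprofile fold,
deconvolution error and group shifts, and the overall vs landmark
log-rank contrast). Run them in order from the repository root.

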