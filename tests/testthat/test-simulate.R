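test_that("generator is deterministic and truth schema is stable", {
  sc <- tiny_scenario(5, n_cpgs = 200)
  tr <- simulate_truth_table(200, 0.1, seed = 5)
  a <- simulate_cohort(sc, tr)
  b <- simulate_cohort(sc, tr)
  expect_identical(a$cohort$beta, b$cohort$beta)
  expect_identical(a$cohort$expression, b$cohort$expression)
  expect_identical(a$truth, b$truth)
  other <- simulate_cohort(tiny_scenario(6, n_cpgs = 200),
                           simulate_truth_table(200, 0.1, seed = 6))
  expect_false(identical(a$cohort$beta, other$cohort$beta))
  expect_identical(names(a$truth), names(other$truth))
})

test_that("generated values respect their ranges", {
  sc <- tiny_scenario(7, n_cpgs = 300)
  sim <- simulate_cohort(sc, simulate_truth_table(300, 0.05, seed = 7))
  expect_true(all(sim$cohort$beta >= 0 & sim$cohort$beta <= 1))
  expect_true(all(sim$cohort$expression >= 0))
  expect_true(all(sim$marker_beta >= 0 & sim$marker_beta <= 1))
  expect_true(all(abs(rowSums(sim$cell_fractions) - 1) < 1e-9))
  expect_true(all(sim$cohort$samples$survival_days >= 0))
})

test_that("null scenario plants no group difference", {
  sc <- simulation_scenario("custom", n_cpgs = 500, delta_near = 0,
                            delta_far = 0, strong_gene_fc = 1,
                            rng_seed = 8)
  sim <- simulate_cohort(sc, simulate_truth_table(500, 0.05, seed = 8))
  beta <- sim$cohort$beta
  mut <- sim$cohort$samples$runx1_mutated
  delta <- rowMeans(beta[, mut]) - rowMeans(beta[, !mut])
  se <- sqrt(apply(beta[, mut], 1, var) / sum(mut) +
               apply(beta[, !mut], 1, var) / sum(!mut))
  # per-CpG |delta| within 3 SE for essentially all CpGs, and the
  # planted truth records a ~zero realized delta
  expect_gt(mean(abs(delta) < 3 * se), 0.99)
  expect_lt(abs(mean(sim$truth$delta_realized)), 0.005)
})

test_that("full coupling with no noise gives Spearman exactly -1", {
  sc <- simulation_scenario("custom", n_cpgs = 100, tl_coupling = 1,
                            n_strong_genes = 0, rng_seed = 9)
  sim <- simulate_cohort(sc, simulate_truth_table(100, 0.05, seed = 9))
  tl_idx <- which(sim$truth$is_tl)[1:5]
  for (j in tl_idx) {
    rho <- cor(sim$cohort$beta[j, ],
               sim$cohort$expression[sim$truth$gene[j], ],
               method = "spearman")
    expect_equal(rho, -1)
  }
})

test_that("realized near-TFBS delta matches the planted 0.18 at 1000 CpGs", {
  sc <- simulation_scenario("runx1", n_cpgs = 1000, rng_seed = 10)
  sim <- simulate_cohort(sc, simulate_truth_table(1000, 0.05, seed = 10))
  near_mean <- mean(sim$truth$delta_realized[sim$truth$near_tfbs])
  expect_lt(abs(near_mean - 0.18), 0.02)
})

test_that("rejection sampling honors frac_near_tfbs extremes", {
  counts <- random_pwm_counts(6, seed = 12)
  m <- build_motif(counts, target_pvalue = 0.001)
  none <- simulate_genome_with_motifs(m, 15, 0, seed = 13)
  expect_equal(nrow(scan_windows(none$genome, none$manifest, m)), 0L)
  all_near <- simulate_genome_with_motifs(m, 15, 1, seed = 14)
  sites <- scan_windows(all_near$genome, all_near$manifest, m)
  expect_setequal(unique(sites$cpg_id), all_near$manifest$cpg_id)
  long <- build_motif(random_pwm_counts(250, seed = 15),
                      target_pvalue = 0.001)
  expect_error(simulate_genome_with_motifs(long, 5, 0.5, seed = 15),
               "longer than the window")
})

test_that("coverage generator plants the stated enrichment profile", {
  truth <- simulate_truth_table(60, 0.5, seed = 16)
  manifest <- data.frame(cpg_id = truth$cpg_id,
                         chrom = sprintf("locus%06d", seq_len(60)),
                         pos = 100L, gene = truth$gene)
  flat <- simulate_coverage(manifest, truth, coverage_enrichment = 1,
                            seed = 17, noise = "none")
  expect_equal(length(unique(flat$value)), 1L)
  peaked <- simulate_coverage(manifest, truth, coverage_enrichment = 5,
                              seed = 17, noise = "none")
  prox <- data.frame(cpg_id = truth$cpg_id, near_tfbs = truth$near_tfbs)
  prof <- metaprofile_by_class(peaked, manifest, prox, flank_bp = 100L,
                               n_bins = 20L)
  center <- c(10L, 11L)  # bins flanking the anchor
  expect_equal(which.max(prof$near$mean) %in% center, TRUE)
  expect_gt(mean(prof$near$mean[center]), mean(prof$rest$mean[center]))
  expect_equal(mean(prof$rest$mean), 20, tolerance = 1e-9)
})

test_that("stage profiles carry a monotone maturation gradient", {
  truth <- simulate_truth_table(300, 0.3, seed = 18)
  stages <- simulate_stage_profiles(truth, n_stages = 5, seed = 18)
  prox_means <- colMeans(stages[truth$near_tfbs, ])
  expect_true(all(diff(prox_means) < 0))
  rest_means <- colMeans(stages[!truth$near_tfbs, ])
  expect_lt(max(abs(rest_means - 0.5)), 0.02)
})

test_that("late-divergence survival generator is reproducible and labeled", {
  d <- simulate_survival_landmark(n = 100, seed = 19)
  d2 <- simulate_survival_landmark(n = 100, seed = 19)
  expect_identical(d, d2)
  expect_setequal(unique(d$group), c("hyper", "hypo"))
  expect_true(all(d$time <= 1000))
  expect_true(all(d$time[!d$event] == 1000))
})
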