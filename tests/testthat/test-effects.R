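make_dm_table <- function(deltas, is_dm = rep(TRUE, length(deltas)),
                          is_dhm = deltas > 0.15) {
  data.frame(feature_id = sprintf("cg%03d", seq_along(deltas)),
             mean_mut = 0.5 + deltas / 2, mean_wt = 0.5 - deltas / 2,
             delta = deltas, t_stat = 1, p_value = 0.01,
             q_value = 0.01, is_dm = is_dm, is_dhm = is_dhm)
}

test_that("delta stratification: equal deltas give equal means, p near 1", {
  dm <- make_dm_table(rep(0.2, 40))
  prox <- data.frame(cpg_id = dm$feature_id,
                     near_tfbs = rep(c(TRUE, FALSE), 20))
  st <- stratify_delta(dm, prox)
  expect_equal(st$summary$mean_delta, c(0.2, 0.2))
  expect_equal(st$summary$n, c(20L, 20L))
  expect_gt(st$test_p, 0.9)
})

test_that("stratum means conserve the overall mean (restrict = all)", {
  set.seed(41)
  dm <- make_dm_table(runif(100, -0.1, 0.3), is_dm = runif(100) < 0.5)
  prox <- data.frame(cpg_id = dm$feature_id, near_tfbs = runif(100) < 0.3)
  st <- stratify_delta(dm, prox, restrict = "all")
  w <- st$summary$n / sum(st$summary$n)
  expect_equal(sum(w * st$summary$mean_delta), mean(dm$delta))
})

test_that("empty stratum is reported with n = 0 and no test", {
  dm <- make_dm_table(rep(0.2, 10))
  prox <- data.frame(cpg_id = dm$feature_id, near_tfbs = FALSE)
  st <- stratify_delta(dm, prox)
  expect_equal(st$summary$n[st$summary$stratum == "near_tfbs"], 0L)
  expect_true(is.na(st$test_p))
})

test_that("rank test p equals the exact permutation p for small strata", {
  d_near <- c(0.31, 0.18, 0.25)
  d_rest <- c(0.02, 0.07, -0.01, 0.12)
  dm <- make_dm_table(c(d_near, d_rest))
  prox <- data.frame(cpg_id = dm$feature_id,
                     near_tfbs = rep(c(TRUE, FALSE), c(3, 4)))
  st <- stratify_delta(dm, prox)
  expect_equal(st$test_p, permutation_ranksum_p(d_near, d_rest))
})

test_that("proportion contrast matches hypergeometric enumeration", {
  near <- rep(c(TRUE, FALSE), c(8, 2))
  rest <- rep(c(TRUE, FALSE), c(1, 9))
  pt <- proportion_test(near, rest)
  expect_equal(pt$prop_near, 0.8)
  expect_equal(pt$p, fisher_enum(pt$table))
  expect_equal(pt$p, fisher.test(pt$table)$p.value)
  # transpose invariance
  expect_equal(fisher.test(t(pt$table))$p.value, pt$p)
  # identical proportions: p in the ~1 region
  pt2 <- proportion_test(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 50))
  expect_gt(pt2$p, 0.9)
  # empty margin flagged
  expect_true(is.na(proportion_test(logical(0), rest)$p))
})

test_that("metaprofile of a constant track is flat at the track value", {
  track <- coverage_track(data.frame(chrom = "c1", start = 0L,
                                     end = 4000L, value = 3.5))
  anchors <- data.frame(chrom = "c1", pos = 2000L)
  prof <- metaprofile(track, anchors, flank_bp = 1000L, n_bins = 10L)
  expect_equal(prof$mean, rep(3.5, 10))
  expect_equal(prof$bin_mid[1], -900)
})

test_that("metaprofile bins equal direct length-weighted averages", {
  track <- coverage_track(data.frame(chrom = "c1",
                                     start = c(0L, 95L),
                                     end = c(95L, 140L),
                                     value = c(1, 5)))
  anchors <- data.frame(chrom = "c1", pos = 70L)
  prof <- metaprofile(track, anchors, flank_bp = 60L, n_bins = 6L)
  # bins of 20 bp from 10 to 130; hand-computed means
  hand <- vapply(seq(10, 110, 20), function(s) {
    track_mean(track, "c1", s, s + 20L)
  }, numeric(1))
  expect_equal(prof$mean, hand)
  # off-contig bins are missing
  edge <- metaprofile(track, data.frame(chrom = "c1", pos = 10L),
                      flank_bp = 60L, n_bins = 6L)
  expect_true(any(is.na(edge$matrix)))
})

test_that("single-anchor class profile equals the anchor's own profile", {
  set.seed(42)
  vals <- rpois(40, 10)
  track <- coverage_track(data.frame(chrom = "c1",
                                     start = seq(0L, 390L, 10L),
                                     end = seq(10L, 400L, 10L),
                                     value = vals))
  a <- data.frame(chrom = "c1", pos = 200L)
  one <- metaprofile(track, a, flank_bp = 100L, n_bins = 10L)
  expect_equal(one$mean, as.numeric(one$matrix[1, ]))
})

test_that("stage profile recovers planted ordering and group contrast", {
  sc <- tiny_scenario(51, n_cpgs = 300)
  truth <- simulate_truth_table(300, 0.1, seed = 51)
  sim <- simulate_cohort(sc, truth)
  stages <- simulate_stage_profiles(sim$truth, n_stages = 5, seed = 52)
  strong_cpgs <- sim$truth$cpg_id[sim$truth$near_tfbs]
  prof <- stage_profile(strong_cpgs, stages, sim$cohort,
                        "runx1_mutated", n_boot = 100)
  stage_rows <- grep("^stage", prof$group)
  expect_true(all(diff(prof$mean_beta[stage_rows]) < 0))
  mut_mean <- prof$mean_beta[prof$group == "aml_mut"]
  wt_mean <- prof$mean_beta[prof$group == "aml_wt"]
  expect_gt(mut_mean, wt_mean)
  expect_true(all(prof$ci_lo <= prof$mean_beta &
                    prof$mean_beta <= prof$ci_hi))
})

test_that("single-CpG stage profile returns the raw beta", {
  stages <- matrix(0.7, 1, 3,
                   dimnames = list("cg1", paste0("stage0", 1:3)))
  beta <- matrix(c(0.5, 0.6, 0.4, 0.55), 1,
                 dimnames = list("cg1", paste0("s", 1:4)))
  expr <- matrix(1, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  sheet <- data.frame(sample_id = paste0("s", 1:4),
                      runx1_mutated = c(TRUE, TRUE, FALSE, FALSE),
                      cebpa_mutated = FALSE)
  co <- cohort_matrices(beta, expr, sheet)
  prof <- stage_profile("cg1", stages, co, "runx1_mutated", n_boot = 10)
  expect_equal(prof$mean_beta[prof$group == "stage01"], 0.7)
  expect_equal(prof$mean_beta[prof$group == "aml_mut"], 0.55)
})
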