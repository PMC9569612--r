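test_that("pooled t-test matches the textbook formula and t.test", {
  res <- ttest_two_groups(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(res$delta, 0)
  expect_equal(res$p, 1)

  mut <- c(0.8, 0.9, 0.7); wt <- c(0.2, 0.3, 0.1)
  res <- ttest_two_groups(mut, wt)
  # hand computation: pooled variance of two sd=0.1 triples
  sp2 <- (2 * 0.01 + 2 * 0.01) / 4
  t_hand <- (mean(mut) - mean(wt)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand)
  ref <- t.test(mut, wt, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  # degenerate conventions
  res <- ttest_two_groups(c(0.7, 0.7), c(0.2, 0.2))
  expect_true(is.infinite(res$t) && res$t > 0)
  expect_equal(res$p, 0)
  expect_true(res$degenerate)
  expect_error(ttest_two_groups(0.5, c(0.1, 0.2)), "at least 2")
})

test_that("row-wise t-tests agree with t.test under missing data", {
  set.seed(21)
  m1 <- matrix(rnorm(200), 20); m2 <- matrix(rnorm(300), 20)
  m1[sample(length(m1), 15)] <- NA
  m2[sample(length(m2), 15)] <- NA
  res <- row_ttest(m1, m2)
  for (i in c(1, 7, 20)) {
    ref <- t.test(m1[i, ], m2[i, ], var.equal = TRUE)
    expect_equal(res$t[i], unname(ref$statistic))
    expect_equal(res$p[i], ref$p.value)
  }
  resw <- row_ttest(m1, m2, welch = TRUE)
  ref <- t.test(m1[3, ], m2[3, ])
  expect_equal(resw$t[3], unname(ref$statistic))
  expect_equal(resw$p[3], ref$p.value)
})

test_that("swapping group labels negates t and preserves p", {
  set.seed(22)
  m1 <- matrix(rnorm(50), 5); m2 <- matrix(rnorm(70), 5)
  a <- row_ttest(m1, m2)
  b <- row_ttest(m2, m1)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$delta, -b$delta)
})

test_that("t-test type-I error is calibrated on null features", {
  set.seed(23)
  n_feat <- 5000
  m1 <- matrix(rnorm(n_feat * 10), n_feat)
  m2 <- matrix(rnorm(n_feat * 12), n_feat)
  res <- row_ttest(m1, m2)
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_feat) + 0.002)
})

make_mini_cohort <- function(deltas, n_per_group = 10, seed = 24) {
  set.seed(seed)
  n <- 2 * n_per_group
  p <- length(deltas)
  mut <- rep(c(TRUE, FALSE), each = n_per_group)
  base <- matrix(rep(c(0.30, 0.31), length.out = n * p), p, n, byrow = TRUE)
  beta <- base + outer(deltas, as.numeric(mut))
  dimnames(beta) <- list(sprintf("cg%02d", seq_len(p)),
                         sprintf("s%02d", seq_len(n)))
  expr <- matrix(rexp(p * n) + 1, p, n,
                 dimnames = list(sprintf("g%02d", seq_len(p)),
                                 colnames(beta)))
  sheet <- data.frame(sample_id = colnames(beta), runx1_mutated = mut,
                      cebpa_mutated = FALSE)
  cohort_matrices(beta, expr, sheet)
}

test_that("DHM requires a strictly greater than 0.15 mean difference", {
  co <- make_mini_cohort(c(0.16, 0.15, 0.40, 0))
  dm <- call_dm_dhm(co, "runx1_mutated")
  expect_equal(dm$delta[1:3], c(0.16, 0.15, 0.40))
  expect_true(dm$is_dm[1] && dm$is_dhm[1])
  expect_true(dm$is_dm[2])
  expect_false(dm$is_dhm[2])  # exactly 0.15: DM but not DHM
  expect_true(dm$is_dhm[3])
  expect_false(dm$is_dm[4])
  # DHM is a subset of DM
  expect_true(all(!dm$is_dhm | dm$is_dm))
})

test_that("DEG fold change uses linear group means with the stabilizer", {
  beta <- matrix(0.5, 1, 6, dimnames = list("cg1", paste0("s", 1:6)))
  expr <- matrix(rep(c(2, 1), each = 3), 1, byrow = FALSE,
                 dimnames = list("g1", paste0("s", 1:6)))
  expr[1, ] <- c(2, 2.0001, 1.9999, 1, 1.0001, 0.9999)
  sheet <- data.frame(sample_id = paste0("s", 1:6),
                      runx1_mutated = rep(c(TRUE, FALSE), each = 3),
                      cebpa_mutated = FALSE)
  co <- cohort_matrices(beta, expr, sheet)
  deg <- call_deg(co, "runx1_mutated")
  expect_equal(deg$fc, 2 / 1.01, tolerance = 1e-4)
})

test_that("gene gates enforce FC, significance, and expression floor", {
  tls <- data.frame(cpg_id = c("cg1", "cg2"), gene = c("g1", "g2"),
                    rho = -0.8, n_used = 20L, p_value = 1e-6,
                    q_value = 1e-5, is_tl = TRUE)
  dm <- data.frame(feature_id = c("cg1", "cg2"), mean_mut = 0.6,
                   mean_wt = 0.3, delta = 0.3, t_stat = 5,
                   p_value = 1e-6, q_value = 1e-5, is_dm = TRUE,
                   is_dhm = TRUE)
  deg <- data.frame(feature_id = c("g1", "g2"),
                    mean_mut = c(1.0, 0.45), mean_wt = c(0.4, 0.18),
                    delta = c(0.6, 0.27), t_stat = 5, p_value = 1e-6,
                    q_value = c(0.01, 0.01), is_dm = TRUE)
  deg$fc <- deg$mean_mut / (deg$mean_wt + 0.01)
  deg$log2_fc <- log2(deg$fc)
  out <- select_strong_tl_genes(tls, dm, deg)
  # g1 passes all gates; g2 has FC > 2 but both means below 0.5
  expect_equal(out$gene, "g1")
  expect_equal(out$n_strong_tl, 1L)

  # dropping the TL kills the gene
  tls2 <- tls; tls2$is_tl[1] <- FALSE
  expect_equal(nrow(select_strong_tl_genes(tls2, dm, deg)), 0L)
})

test_that("null generator yields an empty strong-gene list", {
  empties <- vapply(1:5, function(s) {
    sc <- simulation_scenario("custom", n_cpgs = 300, delta_near = 0,
                              delta_far = 0, strong_gene_fc = 1,
                              rng_seed = 30 + s)
    sim <- simulate_cohort(sc, simulate_truth_table(300, 0.05,
                                                    seed = 30 + s))
    tls <- call_traffic_lights(
      sim$cohort,
      data.frame(cpg_id = sim$truth$cpg_id, chrom = "sim", pos = 100L,
                 gene = sim$truth$gene))
    dm <- call_dm_dhm(sim$cohort, "runx1_mutated")
    deg <- call_deg(sim$cohort, "runx1_mutated")
    nrow(select_strong_tl_genes(tls, dm, deg))
  }, numeric(1))
  expect_true(all(empties == 0))
})

test_that("planted strong genes are recovered exactly on a small preset", {
  sc <- simulation_scenario("runx1", n_cpgs = 800, rng_seed = 33)
  sim <- simulate_cohort(sc, simulate_truth_table(800, 0.05, seed = 33))
  manifest <- data.frame(cpg_id = sim$truth$cpg_id, chrom = "sim",
                         pos = 100L, gene = sim$truth$gene)
  tls <- call_traffic_lights(sim$cohort, manifest)
  dm <- call_dm_dhm(sim$cohort, "runx1_mutated")
  deg <- call_deg(sim$cohort, "runx1_mutated")
  prox <- data.frame(cpg_id = sim$truth$cpg_id,
                     near_tfbs = sim$truth$near_tfbs)
  out <- select_strong_tl_genes(tls, dm, deg, prox)
  expect_setequal(out$gene, sim$truth$gene[sim$truth$is_strong_gene])
  expect_true(all(c("fc", "expr_q") %in% names(out)))
  expect_true(all(abs(out$log2_fc) > 1))
})
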