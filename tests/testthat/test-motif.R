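test_that("uniform motif is the identity case", {
  counts <- matrix(1, 4, 4)  # proportional to uniform background
  m <- build_motif(counts, target_pvalue = 1, pseudocount = 0)
  expect_equal(unname(m$log_odds), matrix(0, 4, 4))
  expect_equal(m$threshold_score, 0)
  expect_equal(m$threshold_pvalue, 1)
})

test_that("length-3 threshold equals brute force over all 64 trinucleotides", {
  counts <- random_pwm_counts(3, seed = 11)
  m <- build_motif(counts, target_pvalue = 0.05)
  expect_equal(m$threshold_score, enum_threshold(m$log_odds, 0.05),
               tolerance = 1e-12)
})

test_that("DP threshold matches enumeration for random PWMs up to length 8", {
  for (L in 4:8) {
    # p chosen above the single-sequence probability so a finite
    # threshold exists at every length
    p <- max(0.001, 8 * 0.25^L)
    counts <- random_pwm_counts(L, seed = 100 + L)
    m <- build_motif(counts, target_pvalue = p)
    thr <- enum_threshold(m$log_odds, p)
    expect_equal(m$threshold_score, thr, tolerance = 1e-9)
    # self-consistency: exact tail at the threshold is <= p, and the
    # next achievable score below it overshoots p
    expect_lte(enum_tail(m$log_odds, m$threshold_score), p)
    en <- enumerate_scores(m$log_odds)
    lower <- max(en$score[en$score < thr - 1e-9])
    expect_gt(enum_tail(m$log_odds, lower), p)
  }
  # below the granularity of the score distribution no threshold exists
  m3 <- build_motif(random_pwm_counts(3, seed = 103),
                    target_pvalue = 0.001)
  expect_identical(m3$threshold_score, Inf)
  expect_identical(enum_threshold(m3$log_odds, 0.001), Inf)
})

test_that("binned DP is conservative and classification-compatible", {
  counts <- random_pwm_counts(7, seed = 5)
  exact <- build_motif(counts, target_pvalue = 0.001, method = "exact")
  binned <- build_motif(counts, target_pvalue = 0.001, method = "binned")
  # the binned threshold never lets the true match probability exceed p
  expect_lte(enum_tail(exact$log_odds, binned$threshold_score), 0.001)
  # and it admits at least every sequence the exact threshold admits
  expect_lte(binned$threshold_score, exact$threshold_score + 1e-9)
  # long-motif path stays finite and usable
  long <- build_motif(random_pwm_counts(18, seed = 6),
                      target_pvalue = 0.001)
  expect_identical(long$method, "binned")
  expect_true(is.finite(long$threshold_score))
})

test_that("threshold is monotone in the target p-value", {
  counts <- random_pwm_counts(6, seed = 21)
  ps <- c(0.002, 0.01, 0.05, 0.2)
  thr <- vapply(ps, function(p) {
    build_motif(counts, target_pvalue = p)$threshold_score
  }, numeric(1))
  expect_true(all(is.finite(thr)))
  expect_true(all(diff(thr) <= 1e-12))
})

test_that("background zero with non-zero counts is rejected", {
  counts <- matrix(c(2, 0, 0, 0), 1)
  expect_error(build_motif(counts, background = c(0, 0.4, 0.3, 0.3)),
               "zero entry")
})

test_that("scanner equals brute-force all-offset scoring on both strands", {
  counts <- random_pwm_counts(6, seed = 31)
  m <- build_motif(counts, target_pvalue = 0.01)
  set.seed(32)
  for (rep in 1:20) {
    chars <- sample(c("A", "C", "G", "T", "N"), 120, TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    seq <- paste(chars, collapse = "")
    hits <- scan_sequence(seq, m)
    fwd <- naive_scan_strand(chars, m$log_odds)
    rev <- naive_scan_strand(revcomp_chars(chars), m$log_odds)
    L <- nrow(m$log_odds)
    exp_f <- which(fwd >= m$threshold_score) - 1L
    exp_r <- length(chars) - (which(rev >= m$threshold_score) - 1L) - L
    got_f <- sort(hits$start[hits$strand == "+"])
    got_r <- sort(hits$start[hits$strand == "-"])
    expect_equal(got_f, sort(exp_f))
    expect_equal(got_r, sort(exp_r))
    if (nrow(hits)) {
      for (k in seq_len(nrow(hits))) {
        ref <- if (hits$strand[k] == "+") fwd[hits$start[k] + 1L] else
          rev[length(chars) - hits$end[k] + 1L]
        expect_equal(hits$score[k], ref)
      }
    }
  }
})

test_that("scanning is strand-symmetric", {
  counts <- random_pwm_counts(5, seed = 41)
  m <- build_motif(counts, target_pvalue = 0.01)
  set.seed(42)
  chars <- sample(c("A", "C", "G", "T"), 200, TRUE)
  seq <- paste(chars, collapse = "")
  rc <- paste(revcomp_chars(chars), collapse = "")
  a <- scan_sequence(seq, m)
  b <- scan_sequence(rc, m)
  # mirrored coordinates, flipped strand, identical scores
  b$start_m <- length(chars) - b$end
  key_a <- paste(a$start, a$strand)
  key_b <- paste(b$start_m, ifelse(b$strand == "+", "-", "+"))
  expect_setequal(key_a, key_b)
  expect_equal(sort(a$score), sort(b$score))
})

test_that("all-N windows yield no sites and window scan honors contigs", {
  counts <- random_pwm_counts(5, seed = 51)
  m <- build_motif(counts, target_pvalue = 0.5)
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("N", 200)))
  manifest <- data.frame(cpg_id = "cg1", chrom = "c1", pos = 100L,
                         gene = "g1")
  expect_equal(nrow(scan_windows(genome, manifest, m)), 0L)
  bad <- data.frame(cpg_id = "cg1", chrom = "c1", pos = 500L, gene = "g1")
  expect_error(scan_windows(genome, bad, m), "exceeds contig")
  missing <- data.frame(cpg_id = "cg1", chrom = "nope", pos = 1L,
                        gene = "g1")
  expect_error(scan_windows(genome, missing, m), "absent")
})

test_that("planted motifs are recovered at the planted offset and strand", {
  counts <- random_pwm_counts(8, seed = 61)
  m <- build_motif(counts, target_pvalue = 0.001)
  gen <- simulate_genome_with_motifs(m, 40, frac_near_tfbs = 0.5, seed = 62)
  sites <- scan_windows(gen$genome, gen$manifest, m)
  prox <- annotate_cpg_proximity(gen$manifest, sites)
  expect_equal(prox$near_tfbs, gen$truth$near_tfbs)
  planted <- gen$truth[gen$truth$near_tfbs, ]
  for (i in seq_len(nrow(planted))) {
    s <- sites[sites$cpg_id == planted$cpg_id[i], ]
    expect_true(planted$motif_start[i] %in% s$start)
    expect_true(planted$motif_strand[i] %in%
                  s$strand[s$start == planted$motif_start[i]])
  }
})

test_that("raising the target p-value never removes sites", {
  counts <- random_pwm_counts(6, seed = 71)
  m_strict <- build_motif(counts, target_pvalue = 0.001)
  m_loose <- build_motif(counts, target_pvalue = 0.01)
  gen <- simulate_genome_with_motifs(m_strict, 20, 0.5, seed = 72)
  strict <- scan_windows(gen$genome, gen$manifest, m_strict)
  loose <- scan_windows(gen$genome, gen$manifest, m_loose)
  key <- function(s) paste(s$cpg_id, s$start, s$strand)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("peak support uses half-open >=1 bp overlap", {
  sites <- data.frame(cpg_id = c("a", "b"), chrom = "c1",
                      start = c(10L, 10L), end = c(20L, 20L),
                      strand = "+", score = 1)
  peaks1 <- data.frame(chrom = "c1", start = 19L, end = 25L)
  peaks2 <- data.frame(chrom = "c1", start = 20L, end = 30L)
  expect_true(all(filter_by_peaks(sites, peaks1)$peak_supported))
  expect_false(any(filter_by_peaks(sites, peaks2)$peak_supported))
  expect_false(any(filter_by_peaks(sites, NULL)$peak_supported))
  expect_equal(nrow(filter_by_peaks(sites, peaks2, require_peak = TRUE)), 0L)
})

test_that("peak flags match the quadratic all-pairs oracle", {
  set.seed(81)
  sites <- data.frame(cpg_id = paste0("cg", 1:60),
                      chrom = sample(c("c1", "c2"), 60, TRUE),
                      start = sample.int(500, 60), strand = "+", score = 0)
  sites$end <- sites$start + sample(15, 60, replace = TRUE)
  peaks <- data.frame(chrom = sample(c("c1", "c2"), 25, TRUE),
                      start = sample.int(500, 25))
  peaks$end <- peaks$start + sample.int(40, 25)
  got <- filter_by_peaks(sites, peaks)$peak_supported
  want <- vapply(seq_len(nrow(sites)), function(i) {
    any(peaks$chrom == sites$chrom[i] &
          pmax(peaks$start, sites$start[i]) <
            pmin(peaks$end, sites$end[i]))
  }, logical(1))
  expect_equal(got, want)
})

test_that("zero retained sites means no proximal CpGs", {
  manifest <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "c",
                         pos = 0L, gene = "g")
  none <- data.frame(cpg_id = character(), chrom = character(),
                     start = integer(), end = integer(),
                     strand = character(), score = numeric())
  expect_false(any(annotate_cpg_proximity(manifest, none)$near_tfbs))
})
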