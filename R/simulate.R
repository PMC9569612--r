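#' Define a synthetic study scenario
#'
#' A scenario bundles every parameter of the synthetic cohort generator.
#' The two presets reproduce the published study's stated conditions:
#' 186 patients of whom 17 carry a RUNX1 mutation (9%) or 13 a CEBPA
#' mutation (7%); a mean beta-value gain of 0.18 at motif-proximal CpGs
#' versus 0.06 elsewhere for RUNX1, and 0.13 versus 0.09 for CEBPA; and
#' 12 (RUNX1) or 11 (CEBPA) planted strong-Traffic-Light genes.
#'
#' Parameters the study does not state (fraction of CpGs near a TFBS,
#' fraction of distal CpGs that respond, coupling strength, noise levels)
#' are free parameters with defaults documented in the methods vignette.
#'
#' @param preset "runx1", "cebpa" or "custom".
#' @param n_samples,n_mutated cohort size and mutated-group size.
#' @param n_cpgs number of array CpGs to simulate.
#' @param frac_near_tfbs fraction of CpGs with a planted motif within the
#'   scan window.
#' @param delta_near,delta_far beta shift added to mutated samples at
#'   motif-proximal CpGs and at the responding fraction of distal CpGs.
#' @param frac_far_affected fraction of distal CpGs that receive
#'   `delta_far`.
#' @param frac_tl fraction of CpGs with methylation-expression coupling.
#' @param tl_coupling target absolute Spearman correlation of coupled
#'   pairs (sign negative by default: methylation up, expression down).
#' @param tl_sign -1 (default) or +1, direction of the coupling.
#' @param n_strong_genes number of planted strong-Traffic-Light genes
#'   (motif-proximal, coupled, differentially expressed).
#' @param strong_gene_fc linear fold-change (wild-type / mutated) planted
#'   on strong genes' expression.
#' @param coverage_enrichment fold elevation of ChIP coverage at
#'   motif-proximal CpGs.
#' @param cell_fractions 2 x K matrix of mean cell-type mixing
#'   proportions, rows "wt" and "mut"; rows must sum to 1.
#' @param n_cell_markers marker CpGs per cell type in the reference
#'   atlas.
#' @param cell_noise_sd beta noise added to mixed marker profiles.
#' @param survival_hazard_ratio hazard ratio (hyper vs hypo methylation
#'   at the designated survival CpG) of the exponential survival times.
#' @param beta_noise_sd per-sample beta noise around the CpG baseline.
#' @param expr_sdlog per-sample log-normal expression noise (sd of log).
#' @param window_halfwidth scan-window half-width in bp.
#' @param rng_seed integer seed.
#' @return object of class `simulation_scenario` (validated list).
#' @export
simulation_scenario <- function(preset = c("runx1", "cebpa", "custom"),
                                n_samples = 186L,
                                n_mutated = NULL,
                                n_cpgs = 2000L,
                                frac_near_tfbs = 0.05,
                                delta_near = NULL,
                                delta_far = NULL,
                                frac_far_affected = 0.30,
                                frac_tl = 0.10,
                                tl_coupling = 0.7,
                                tl_sign = -1,
                                n_strong_genes = NULL,
                                strong_gene_fc = 3,
                                coverage_enrichment = 5,
                                cell_fractions = NULL,
                                n_cell_markers = 50L,
                                cell_noise_sd = 0.02,
                                survival_hazard_ratio = 2,
                                beta_noise_sd = 0.05,
                                expr_sdlog = 0.5,
                                window_halfwidth = 100L,
                                rng_seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    runx1 = list(n_mutated = 17L, delta_near = 0.18, delta_far = 0.06,
                 n_strong_genes = 12L),
    cebpa = list(n_mutated = 13L, delta_near = 0.13, delta_far = 0.09,
                 n_strong_genes = 11L),
    custom = list(n_mutated = 17L, delta_near = 0.18, delta_far = 0.06,
                  n_strong_genes = 12L))
  if (is.null(n_mutated)) n_mutated <- defaults$n_mutated
  if (is.null(delta_near)) delta_near <- defaults$delta_near
  if (is.null(delta_far)) delta_far <- defaults$delta_far
  if (is.null(n_strong_genes)) n_strong_genes <- defaults$n_strong_genes
  if (is.null(cell_fractions)) {
    cell_fractions <- rbind(
      wt  = c(granulocyte = 0.25, monocyte = 0.20, macrophage = 0.20,
              lymphocyte = 0.20, blast = 0.15),
      mut = c(granulocyte = 0.28, monocyte = 0.23, macrophage = 0.08,
              lymphocyte = 0.23, blast = 0.18))
  }
  stopifnot(
    n_mutated >= 1, n_mutated < n_samples,
    n_cpgs >= 10,
    delta_near >= 0, delta_near < 1, delta_far >= 0, delta_far < 1,
    frac_near_tfbs >= 0, frac_near_tfbs <= 1,
    frac_far_affected >= 0, frac_far_affected <= 1,
    frac_tl >= 0, frac_tl <= 1,
    tl_coupling >= 0, tl_coupling <= 1, tl_sign %in% c(-1, 1),
    n_strong_genes >= 0, strong_gene_fc >= 1,
    coverage_enrichment >= 1,
    is.matrix(cell_fractions), nrow(cell_fractions) == 2L,
    all(abs(rowSums(cell_fractions) - 1) < 1e-8),
    survival_hazard_ratio > 0, beta_noise_sd > 0
  )
  structure(list(
    preset = preset, n_samples = as.integer(n_samples),
    n_mutated = as.integer(n_mutated), n_cpgs = as.integer(n_cpgs),
    frac_near_tfbs = frac_near_tfbs, delta_near = delta_near,
    delta_far = delta_far, frac_far_affected = frac_far_affected,
    frac_tl = frac_tl, tl_coupling = tl_coupling, tl_sign = tl_sign,
    n_strong_genes = as.integer(n_strong_genes),
    strong_gene_fc = strong_gene_fc,
    coverage_enrichment = coverage_enrichment,
    cell_fractions = cell_fractions,
    n_cell_markers = as.integer(n_cell_markers),
    cell_noise_sd = cell_noise_sd,
    survival_hazard_ratio = survival_hazard_ratio,
    beta_noise_sd = beta_noise_sd, expr_sdlog = expr_sdlog,
    window_halfwidth = as.integer(window_halfwidth),
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_scenario")
}

# cpg / gene / sample id builders shared by all generator functions
sim_cpg_ids <- function(n) sprintf("cg%06d", seq_len(n))
sim_gene_ids <- function(n) sprintf("g%06d", seq_len(n))
sim_sample_ids <- function(n) sprintf("s%04d", seq_len(n))

#' Assign motif-proximity truth labels without sequences
#'
#' Draws which CpGs are motif-proximal. Used directly when downstream
#' stages only need the truth labels (no scanning), and by
#' [simulate_genome_with_motifs()] when sequences are generated.
#'
#' @param n_cpgs number of CpGs.
#' @param frac_near_tfbs fraction of motif-proximal CpGs.
#' @param seed integer seed.
#' @return data.frame with columns cpg_id, gene, near_tfbs.
#' @export
simulate_truth_table <- function(n_cpgs, frac_near_tfbs, seed = 1L) {
  set.seed(seed)
  n_near <- round(frac_near_tfbs * n_cpgs)
  near <- rep(FALSE, n_cpgs)
  near[sample.int(n_cpgs, n_near)] <- TRUE
  stopifnot(sum(near) == n_near)
  data.frame(cpg_id = sim_cpg_ids(n_cpgs), gene = sim_gene_ids(n_cpgs),
             near_tfbs = near, stringsAsFactors = FALSE)
}

# sample one sequence of length n from base probabilities
sample_bases <- function(n, probs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
}

# score of a character vector under the motif's forward log-odds
instance_score <- function(chars, lo) {
  sum(lo[cbind(seq_len(nrow(lo)), match(chars, c("A", "C", "G", "T")))])
}

#' Generate a genome of CpG-centered loci with planted motifs
#'
#' Every CpG gets its own contig of 2 x `window_halfwidth` bp with the
#' CpG dinucleotide at the center. For the motif-proximal fraction, one
#' motif instance (drawn from the PWM; the consensus if the draw scores
#' below threshold) is embedded within the window on a random strand;
#' background sequence is rejection-sampled so that it contains no match
#' at the motif's threshold.
#'
#' @param motif a `motif_model`.
#' @param n_cpgs number of CpG loci.
#' @param frac_near_tfbs fraction of loci with a planted motif.
#' @param window_halfwidth half-width of the locus (default 100 bp).
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per locus.
#' @return list with `genome` (DNAStringSet), `manifest` (cpg_id, chrom,
#'   pos, gene) and `truth` (cpg_id, gene, near_tfbs, motif_start,
#'   motif_strand).
#' @export
simulate_genome_with_motifs <- function(motif, n_cpgs, frac_near_tfbs,
                                        window_halfwidth = 100L,
                                        seed = 1L, max_tries = 200L) {
  L <- nrow(motif$log_odds)
  if (L >= 2L * window_halfwidth) stop("motif is longer than the window")
  truth <- simulate_truth_table(n_cpgs, frac_near_tfbs, seed)
  hw <- as.integer(window_halfwidth)
  clen <- 2L * hw
  consensus <- c("A", "C", "G", "T")[apply(motif$log_odds, 1, which.max)]
  seqs <- character(n_cpgs)
  motif_start <- rep(NA_integer_, n_cpgs)
  motif_strand <- rep(NA_character_, n_cpgs)
  for (i in seq_len(n_cpgs)) {
    for (try in seq_len(max_tries)) {
      chars <- sample_bases(clen, motif$background)
      chars[hw + 1L] <- "C"; chars[hw + 2L] <- "G"
      if (truth$near_tfbs[i]) {
        inst <- sample_motif_instance(motif, consensus)
        strand <- sample(c("+", "-"), 1L)
        placed <- if (strand == "+") inst else
          rev(c(T = "A", G = "C", C = "G", A = "T")[inst])
        # offsets that keep the instance off the central CpG dinucleotide
        starts <- setdiff(0:(clen - L), (hw - L + 1L):(hw + 1L))
        if (!length(starts)) stop("no room to place the motif instance")
        s0 <- starts[sample.int(length(starts), 1L)]
        chars[(s0 + 1L):(s0 + L)] <- placed
        hits <- scan_sequence(paste(chars, collapse = ""), motif)
        extra <- hits[hits$start != s0, , drop = FALSE]
        if (nrow(extra) == 0L && nrow(hits) >= 1L) {
          motif_start[i] <- s0
          motif_strand[i] <- strand
          break
        }
      } else {
        hits <- scan_sequence(paste(chars, collapse = ""), motif)
        if (nrow(hits) == 0L) break
      }
      if (try == max_tries) stop("rejection sampling failed for a locus")
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  chroms <- sprintf("locus%06d", seq_len(n_cpgs))
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  manifest <- data.frame(cpg_id = truth$cpg_id, chrom = chroms,
                         pos = hw, gene = truth$gene,
                         stringsAsFactors = FALSE)
  truth$motif_start <- motif_start
  truth$motif_strand <- motif_strand
  list(genome = genome, manifest = manifest, truth = truth)
}

# draw a motif instance from the PWM probabilities; fall back to the
# consensus when the draw itself would not pass the scan threshold
sample_motif_instance <- function(motif, consensus) {
  probs <- motif$background * 2^motif$log_odds  # recover base probabilities
  probs <- probs / rowSums(probs)
  inst <- vapply(seq_len(nrow(probs)), function(j) {
    sample(c("A", "C", "G", "T"), 1L, prob = probs[j, ])
  }, "")
  if (instance_score(inst, motif$log_odds) >= motif$threshold_score) inst
  else consensus
}

# Dirichlet draws via gamma normalization
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a full cohort with planted effects
#'
#' Generates aligned beta and expression matrices, sample metadata with
#' survival, cell-type mixtures with a reference atlas, and a complete
#' truth table. Effects planted in the mutated group: `delta_near` beta
#' gain at motif-proximal CpGs, `delta_far` at a fraction of distal
#' CpGs, monotone methylation-expression coupling at Traffic-Light CpGs,
#' an expression fold change at the designated strong genes, a cell-type
#' composition shift, and methylation-linked exponential survival.
#'
#' Wild-type beta baselines follow a bimodal Beta(2,10)/Beta(10,2)
#' mixture; CpGs that receive a gain start from non-saturated baselines
#' (motif-proximal from the unmethylated mode) so the planted shift is
#' realized without clipping distortion. Shifted values are clipped to
#' \[0,1\] and the realized per-CpG delta is recorded as truth.
#'
#' @param scenario a `simulation_scenario`.
#' @param truth motif-proximity truth table (from
#'   [simulate_truth_table()] or [simulate_genome_with_motifs()]).
#' @return list with `cohort` (a `cohort_matrices`), `truth` (per-CpG
#'   labels incl. realized delta), `atlas`, `marker_beta`,
#'   `cell_fractions` (per-sample truth), `survival_cpg`.
#' @export
simulate_cohort <- function(scenario, truth) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  if (nrow(truth) != sc$n_cpgs) {
    stop("truth table size does not match scenario n_cpgs")
  }
  set.seed(sc$rng_seed)
  n <- sc$n_samples; m <- sc$n_mutated; p <- sc$n_cpgs
  samples <- sim_sample_ids(n)
  mutated <- c(rep(TRUE, m), rep(FALSE, n - m))

  near <- truth$near_tfbs
  idx_far <- which(!near)
  far_affected <- rep(FALSE, p)
  n_fa <- round(sc$frac_far_affected * length(idx_far))
  far_affected[idx_far[sample.int(length(idx_far), n_fa)]] <- TRUE

  # strong genes sit at motif-proximal CpGs; the remaining TL CpGs are
  # planted on unshifted CpGs so group shifts cannot fake a coupling
  if (sc$n_strong_genes > sum(near)) {
    stop("n_strong_genes exceeds the number of motif-proximal CpGs")
  }
  strong <- rep(FALSE, p)
  idx_near <- which(near)
  strong[idx_near[sample.int(length(idx_near), sc$n_strong_genes)]] <- TRUE
  n_tl <- round(sc$frac_tl * p)
  is_tl <- strong
  pool <- which(!near & !far_affected)
  extra <- max(0L, n_tl - sum(is_tl))
  if (extra > length(pool)) stop("frac_tl too large for the unshifted pool")
  is_tl[pool[sample.int(length(pool), extra)]] <- TRUE

  # baselines: bimodal array-like mixture; shifted CpGs keep headroom
  lo_mode <- stats::rbeta(p, 2, 10)
  hi_mode <- stats::rbeta(p, 10, 2)
  mu <- ifelse(stats::runif(p) < 0.5, lo_mode, hi_mode)
  mu[near] <- lo_mode[near]
  redo <- which(far_affected & mu > 0.75)
  while (length(redo)) {
    mu[redo] <- ifelse(stats::runif(length(redo)) < 0.5,
                       stats::rbeta(length(redo), 2, 10),
                       stats::rbeta(length(redo), 10, 2))
    redo <- redo[mu[redo] > 0.75]
  }

  shift <- ifelse(near, sc$delta_near, ifelse(far_affected, sc$delta_far, 0))
  beta <- matrix(stats::rnorm(p * n, mean = mu, sd = sc$beta_noise_sd),
                 nrow = p, ncol = n)
  beta[, mutated] <- beta[, mutated] + shift
  beta <- clip01(beta)
  dimnames(beta) <- list(truth$cpg_id, samples)

  # expression: log-normal around a gene base mean; coupled genes get a
  # Gaussian-copula link to their CpG's beta ranks
  base_mean <- exp(stats::rnorm(p, mean = 1.0, sd = 1.0))
  base_mean[strong] <- exp(stats::rnorm(sum(strong), mean = 1.5, sd = 0.3))
  expr <- matrix(NA_real_, p, n, dimnames = list(truth$gene, samples))
  # Pearson rho hitting the target Spearman on the Gaussian copula;
  # exact 1 at full coupling so the no-noise branch is truly monotone
  rho <- if (sc$tl_coupling >= 1) 1 else 2 * sin(pi * sc$tl_coupling / 6)
  for (j in seq_len(p)) {
    if (is_tl[j]) {
      zb <- stats::qnorm(rank(beta[j, ], ties.method = "average") / (n + 1))
      z <- sc$tl_sign * rho * zb + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    } else {
      z <- stats::rnorm(n)
    }
    expr[j, ] <- base_mean[j] * exp(sc$expr_sdlog * z)
  }
  expr[strong, mutated] <- expr[strong, mutated] / sc$strong_gene_fc

  # cell mixtures over a synthetic marker atlas
  types <- colnames(sc$cell_fractions)
  K <- length(types)
  marker_ids <- sprintf("mk_%s_%02d", rep(types, each = sc$n_cell_markers),
                        rep(seq_len(sc$n_cell_markers), K))
  atlas <- matrix(0.1, length(marker_ids), K,
                  dimnames = list(marker_ids, types))
  for (k in seq_len(K)) {
    atlas[(k - 1L) * sc$n_cell_markers + seq_len(sc$n_cell_markers), k] <- 0.85
  }
  atlas <- clip01(atlas + stats::rnorm(length(atlas), sd = 0.03))
  w_true <- matrix(NA_real_, n, K, dimnames = list(samples, types))
  w_true[mutated, ] <- rdirichlet(m, 60 * sc$cell_fractions["mut", ])
  w_true[!mutated, ] <- rdirichlet(n - m, 60 * sc$cell_fractions["wt", ])
  marker_beta <- clip01(atlas %*% t(w_true) +
    stats::rnorm(length(marker_ids) * n, sd = sc$cell_noise_sd))

  # survival: exponential, hazard ratio between hyper/hypo halves at a
  # designated CpG (the first strong gene's CpG, else the first CpG)
  survival_cpg <- if (any(strong)) truth$cpg_id[which(strong)[1]] else
    truth$cpg_id[1]
  b <- beta[survival_cpg, ]
  hyper <- b > stats::median(b)
  rate0 <- log(2) / 700  # wild-type-like median survival ~700 days
  rate <- ifelse(hyper, rate0 * sc$survival_hazard_ratio, rate0)
  t_raw <- stats::rexp(n, rate)
  censor <- 2500
  surv_days <- pmin(t_raw, censor)
  event <- t_raw <= censor

  sheet <- data.frame(
    sample_id = samples,
    runx1_mutated = if (sc$preset == "cebpa") FALSE else mutated,
    cebpa_mutated = if (sc$preset == "cebpa") mutated else FALSE,
    survival_days = surv_days, death_observed = event,
    stringsAsFactors = FALSE)

  delta_realized <- rowMeans(beta[, mutated, drop = FALSE]) -
    rowMeans(beta[, !mutated, drop = FALSE])
  truth_out <- data.frame(
    cpg_id = truth$cpg_id, gene = truth$gene, near_tfbs = near,
    far_affected = far_affected, shifted = near | far_affected,
    is_tl = is_tl, is_strong_gene = strong,
    delta_planted = shift, delta_realized = delta_realized,
    stringsAsFactors = FALSE)

  list(cohort = cohort_matrices(beta, expr, sheet),
       truth = truth_out, atlas = atlas, marker_beta = marker_beta,
       cell_fractions = w_true, survival_cpg = survival_cpg)
}

#' Simulate a ChIP-seq coverage track over the CpG loci
#'
#' Poisson coverage in fixed-width bins, flat at `baseline` everywhere
#' and multiplied by a Gaussian bump (peak fold `coverage_enrichment`,
#' sd `kernel_sd` bp) centered on the CpG of motif-proximal loci.
#'
#' @param manifest CpG manifest (cpg_id, chrom, pos); one contig per CpG.
#' @param truth truth table with `near_tfbs`.
#' @param coverage_enrichment peak fold change over baseline (1 = flat).
#' @param contig_length contig length in bp.
#' @param baseline mean baseline coverage depth.
#' @param bin_width bedGraph bin width in bp.
#' @param kernel_sd Gaussian kernel sd in bp.
#' @param seed integer seed.
#' @param noise "poisson" or "none" (exact expected coverage).
#' @return a `coverage_track`.
#' @export
simulate_coverage <- function(manifest, truth, coverage_enrichment,
                              contig_length = 200L, baseline = 20,
                              bin_width = 10L, kernel_sd = 30,
                              seed = 1L, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  set.seed(seed)
  near <- stats::setNames(truth$near_tfbs, truth$cpg_id)
  starts <- seq(0L, contig_length - bin_width, by = bin_width)
  centers <- starts + bin_width / 2
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    fold <- if (near[[manifest$cpg_id[i]]]) {
      1 + (coverage_enrichment - 1) *
        exp(-(centers - manifest$pos[i])^2 / (2 * kernel_sd^2))
    } else rep(1, length(centers))
    lambda <- baseline * fold
    value <- if (noise == "poisson") stats::rpois(length(lambda), lambda)
             else lambda
    rows[[i]] <- data.frame(chrom = manifest$chrom[i], start = starts,
                            end = starts + bin_width, value = value,
                            stringsAsFactors = FALSE)
  }
  coverage_track(do.call(rbind, rows))
}

#' Simulate hematopoiesis-stage methylation profiles
#'
#' Beta values per CpG for a series of maturation stages: motif-proximal
#' CpGs carry a monotone demethylation gradient (high in immature cells,
#' low in mature cells); distal CpGs stay flat.
#'
#' @param truth truth table with `near_tfbs`.
#' @param n_stages number of maturation stages (immature to mature).
#' @param beta_immature,beta_mature gradient endpoints for proximal CpGs.
#' @param noise_sd per-entry beta noise.
#' @param seed integer seed.
#' @return CpG x stage beta matrix (columns stage01..stageNN).
#' @export
simulate_stage_profiles <- function(truth, n_stages = 5L,
                                    beta_immature = 0.75,
                                    beta_mature = 0.15,
                                    noise_sd = 0.03, seed = 1L) {
  set.seed(seed)
  grad <- seq(beta_immature, beta_mature, length.out = n_stages)
  p <- nrow(truth)
  mat <- matrix(NA_real_, p, n_stages,
                dimnames = list(truth$cpg_id,
                                sprintf("stage%02d", seq_len(n_stages))))
  for (s in seq_len(n_stages)) {
    mean_s <- ifelse(truth$near_tfbs, grad[s], 0.5)
    mat[, s] <- clip01(stats::rnorm(p, mean_s, noise_sd))
  }
  mat
}

#' Simulate a late-divergence survival cohort
#'
#' Piecewise-exponential survival for two groups: a common baseline
#' hazard before the changepoint (hazard ratio `hr_before`) and a
#' divergent hazard after it (`hr_after` for the hyper group).
#'
#' @param n total patients (split as evenly as possible).
#' @param hr_before,hr_after hazard ratios (hyper vs hypo) before/after
#'   the changepoint.
#' @param changepoint divergence time in days.
#' @param median_survival hypo-group median survival in days (sets the
#'   baseline rate).
#' @param censor_time administrative censoring time in days.
#' @param seed integer seed.
#' @return data.frame with sample_id, time, event, group.
#' @export
simulate_survival_landmark <- function(n = 186L, hr_before = 1,
                                       hr_after = 3, changepoint = 500,
                                       median_survival = 365,
                                       censor_time = 1000, seed = 1L) {
  set.seed(seed)
  rate0 <- log(2) / median_survival
  group <- rep(c("hypo", "hyper"), length.out = n)
  r1 <- ifelse(group == "hyper", rate0 * hr_before, rate0)
  r2 <- ifelse(group == "hyper", rate0 * hr_after, rate0)
  u <- stats::rexp(n)  # cumulative hazard draw
  h_break <- r1 * changepoint
  t_raw <- ifelse(u <= h_break, u / r1, changepoint + (u - h_break) / r2)
  time <- pmin(t_raw, censor_time)
  data.frame(sample_id = sim_sample_ids(n), time = time,
             event = t_raw <= censor_time, group = group,
             stringsAsFactors = FALSE)
}
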