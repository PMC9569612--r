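#' Stratify methylation deltas by TFBS proximity
#'
#' Splits per-CpG group mean differences (delta = mutated minus
#' wild-type) into a motif-proximal stratum and the rest, reports the
#' stratum means and sizes, and tests the difference of the two delta
#' distributions with a two-sided Mann-Whitney rank test. By default the
#' stratification is computed over differentially methylated CpGs (the
#' population the published figure plots); `restrict` can widen it to
#' all CpGs or narrow it to Traffic Lights.
#'
#' @param dm per-CpG differential table from [call_dm_dhm()].
#' @param proximity per-CpG proximity table (cpg_id, near_tfbs).
#' @param restrict "dm" (default), "all", or "tl".
#' @param tls Traffic-Light table, required when `restrict = "tl"`.
#' @return list with `summary` (two-row data.frame: stratum, n,
#'   mean_delta, prop_hyper) and `test_p`.
#' @export
stratify_delta <- function(dm, proximity, restrict = c("dm", "all", "tl"),
                           tls = NULL) {
  restrict <- match.arg(restrict)
  near <- proximity$near_tfbs[match(dm$feature_id, proximity$cpg_id)]
  keep <- switch(restrict,
    all = rep(TRUE, nrow(dm)),
    dm = dm$is_dm,
    tl = {
      if (is.null(tls)) stop("restrict = 'tl' needs the TL table")
      dm$feature_id %in% tls$cpg_id[tls$is_tl]
    })
  keep <- keep & !is.na(near) & !is.na(dm$delta)
  d_near <- dm$delta[keep & near]
  d_rest <- dm$delta[keep & !near]
  summ <- data.frame(
    stratum = c("near_tfbs", "rest"),
    n = c(length(d_near), length(d_rest)),
    mean_delta = c(mean(d_near), mean(d_rest)),
    prop_hyper = c(mean(d_near > 0), mean(d_rest > 0)),
    stringsAsFactors = FALSE)
  test_p <- if (length(d_near) && length(d_rest)) {
    p <- suppressWarnings(stats::wilcox.test(d_near, d_rest)$p.value)
    if (is.nan(p)) 1 else p  # complete ties carry no evidence
  } else NA_real_
  list(summary = summ, test_p = test_p)
}

#' Compare hypermethylated-CpG proportions near TFBS vs the rest
#'
#' Two-sided Fisher exact test on the 2x2 table of hypermethylation
#' calls (DHM yes/no) by stratum (near TFBS / rest).
#'
#' @param dhm_flags_near,dhm_flags_rest logical vectors of DHM calls in
#'   the two strata.
#' @return list with prop_near, prop_rest, p, and the 2x2 `table`.
#' @export
proportion_test <- function(dhm_flags_near, dhm_flags_rest) {
  dhm_flags_near <- dhm_flags_near[!is.na(dhm_flags_near)]
  dhm_flags_rest <- dhm_flags_rest[!is.na(dhm_flags_rest)]
  tab <- rbind(near = c(hyper = sum(dhm_flags_near),
                        not = sum(!dhm_flags_near)),
               rest = c(hyper = sum(dhm_flags_rest),
                        not = sum(!dhm_flags_rest)))
  if (any(rowSums(tab) == 0)) {
    return(list(prop_near = NA_real_, prop_rest = NA_real_,
                p = NA_real_, table = tab))
  }
  list(prop_near = mean(dhm_flags_near), prop_rest = mean(dhm_flags_rest),
       p = stats::fisher.test(tab)$p.value, table = tab)
}

#' Coverage metaprofile around anchor positions
#'
#' Average coverage in equal-width bins of a symmetric window around a
#' set of anchor positions (e.g. CpGs of one class), strand-agnostic.
#' Bins extending past a contig end are missing for that anchor and are
#' dropped from the class mean.
#'
#' @param track a `coverage_track`.
#' @param anchors data.frame with chrom and pos (0-based anchor
#'   position).
#' @param flank_bp half-width of the profiled window.
#' @param n_bins number of equal-width bins (even, so bins are symmetric
#'   about the anchor).
#' @return list with `bin_mid` (bp relative to anchor), `mean` (per-bin
#'   class mean), `n_regions`, and the per-anchor `matrix`.
#' @export
metaprofile <- function(track, anchors, flank_bp = 2000L, n_bins = 50L) {
  stopifnot(n_bins %% 2L == 0L, flank_bp > 0L,
            (2L * flank_bp) %% n_bins == 0L)
  if (!all(anchors$chrom %in% unique(track$chrom))) {
    stop("anchor chromosome absent from the coverage track")
  }
  cov <- track_rle(track)
  bin_w <- (2L * flank_bp) %/% n_bins
  edges <- seq(-flank_bp, flank_bp, by = bin_w)
  contig_end <- tapply(track$end, track$chrom, max)
  prof <- matrix(NA_real_, nrow(anchors), n_bins)
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]; pos <- anchors$pos[i]
    rle_c <- cov[[chrom]]
    cend <- contig_end[[chrom]]
    for (b in seq_len(n_bins)) {
      s <- pos + edges[b]; e <- pos + edges[b + 1L]
      if (s < 0 || e > cend) next  # off-contig bin stays missing
      v <- IRanges::Views(rle_c, start = s + 1L, end = e)
      prof[i, b] <- IRanges::viewMeans(v)[1]
    }
  }
  list(bin_mid = (edges[-1L] + edges[-length(edges)]) / 2,
       mean = colMeans(prof, na.rm = TRUE),
       n_regions = nrow(anchors), matrix = prof)
}

#' Metaprofiles for two CpG classes
#'
#' Convenience wrapper computing [metaprofile()] for motif-proximal and
#' distal anchors on the same track.
#'
#' @param track a `coverage_track`.
#' @param manifest CpG manifest (cpg_id, chrom, pos).
#' @param proximity per-CpG proximity table (cpg_id, near_tfbs).
#' @inheritParams metaprofile
#' @return list with elements `near` and `rest`, each a metaprofile.
#' @export
metaprofile_by_class <- function(track, manifest, proximity,
                                 flank_bp = 2000L, n_bins = 50L) {
  near_ids <- proximity$cpg_id[proximity$near_tfbs]
  mf <- manifest[!duplicated(manifest$cpg_id), , drop = FALSE]
  a_near <- mf[mf$cpg_id %in% near_ids, c("chrom", "pos")]
  a_rest <- mf[!mf$cpg_id %in% near_ids, c("chrom", "pos")]
  list(near = metaprofile(track, a_near, flank_bp, n_bins),
       rest = metaprofile(track, a_rest, flank_bp, n_bins))
}

#' Mean methylation of strong Traffic Lights across hematopoiesis stages
#'
#' Averages beta values over a set of strong-Traffic-Light CpGs for each
#' normal-maturation stage and for the mutated and wild-type patient
#' groups, with bootstrap confidence intervals over CpGs.
#'
#' @param cpg_ids CpGs to average over (typically strong TLs near the
#'   factor's TFBS).
#' @param stage_beta CpG x stage beta matrix of normal maturation
#'   stages.
#' @param cohort a `cohort_matrices`.
#' @param mutation_flag logical vector or sample-sheet column name.
#' @param n_boot bootstrap resamples over CpGs (default 1000).
#' @param conf confidence level.
#' @return data.frame with group, mean_beta, ci_lo, ci_hi; stages in
#'   column order, then "aml_mut" and "aml_wt".
#' @export
stage_profile <- function(cpg_ids, stage_beta, cohort, mutation_flag,
                          n_boot = 1000L, conf = 0.95) {
  flag <- resolve_flag(cohort, mutation_flag)
  cpg_ids <- intersect(cpg_ids, rownames(stage_beta))
  cpg_ids <- intersect(cpg_ids, rownames(cohort$beta))
  if (!length(cpg_ids)) stop("no usable CpGs for the stage profile")
  stages <- stage_beta[cpg_ids, , drop = FALSE]
  mut_mean <- rowMeans(cohort$beta[cpg_ids, flag, drop = FALSE],
                       na.rm = TRUE)
  wt_mean <- rowMeans(cohort$beta[cpg_ids, !flag, drop = FALSE],
                      na.rm = TRUE)
  vals <- cbind(stages, aml_mut = mut_mean, aml_wt = wt_mean)
  alpha <- (1 - conf) / 2
  boot_ci <- function(v) {
    if (length(v) == 1L) return(c(v, v))
    bm <- vapply(seq_len(n_boot), function(k) {
      mean(v[sample.int(length(v), replace = TRUE)])
    }, numeric(1))
    stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
  }
  cis <- apply(vals, 2, boot_ci)
  data.frame(group = colnames(vals), mean_beta = colMeans(vals),
             ci_lo = cis[1, ], ci_hi = cis[2, ],
             n_cpgs = length(cpg_ids), row.names = NULL,
             stringsAsFactors = FALSE)
}
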