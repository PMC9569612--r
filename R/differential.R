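#' Pooled-variance two-sample t-test for one feature
#'
#' Classical Student's t with pooled variance (a Welch option is
#' available for robustness). Missing values are dropped per group.
#' Degenerate conventions: zero pooled variance with equal means gives
#' t = 0, p = 1; zero pooled variance with unequal means gives
#' t = +/-Inf, p = 0 and `degenerate = TRUE`.
#'
#' @param values_mut,values_wt numeric vectors (mutated / wild-type).
#' @param welch use the Welch unequal-variance test instead.
#' @return list with t, p, mean_mut, mean_wt, delta, degenerate.
#' @export
ttest_two_groups <- function(values_mut, values_wt, welch = FALSE) {
  x <- values_mut[!is.na(values_mut)]
  y <- values_wt[!is.na(values_wt)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 non-missing values")
  }
  res <- row_ttest(matrix(x, 1), matrix(y, 1), welch = welch)
  list(t = res$t[1], p = res$p[1], mean_mut = res$mean_mut[1],
       mean_wt = res$mean_wt[1], delta = res$delta[1],
       degenerate = res$degenerate[1])
}

# Vectorized row-wise two-sample t-test on matrices (features x samples).
# NA handled per row; rows with < 2 values in either group get NA.
row_ttest <- function(mat_mut, mat_wt, welch = FALSE) {
  n1 <- rowSums(!is.na(mat_mut))
  n2 <- rowSums(!is.na(mat_wt))
  m1 <- rowMeans(mat_mut, na.rm = TRUE)
  m2 <- rowMeans(mat_wt, na.rm = TRUE)
  v1 <- rowSums((mat_mut - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((mat_wt - m2)^2, na.rm = TRUE) / (n2 - 1)
  delta <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  t <- delta / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  t[degenerate & delta == 0] <- 0
  p[degenerate & delta == 0] <- 1
  t[degenerate & delta != 0] <- sign(delta[degenerate & delta != 0]) * Inf
  p[degenerate & delta != 0] <- 0
  bad <- n1 < 2L | n2 < 2L
  t[bad] <- NA; p[bad] <- NA
  list(t = t, p = p, mean_mut = m1, mean_wt = m2, delta = delta,
       degenerate = degenerate & delta != 0)
}

#' Call differentially (hyper)methylated CpGs
#'
#' Per-CpG pooled-variance t-test between mutated and wild-type samples,
#' BH adjustment over all tested CpGs. A CpG is differentially
#' methylated (DM) at q < `dm_fdr`, and differentially hypermethylated
#' (DHM) when additionally the group mean difference (mutated minus
#' wild-type) is strictly greater than `dhm_delta`.
#'
#' @param cohort a `cohort_matrices`.
#' @param mutation_flag logical vector aligned to the cohort samples, or
#'   the name of a logical sample-sheet column ("runx1_mutated" /
#'   "cebpa_mutated").
#' @param config a `pipeline_config`.
#' @param welch use the Welch test instead of pooled variance.
#' @return data.frame: feature_id, mean_mut, mean_wt, delta, t_stat,
#'   p_value, q_value, is_dm, is_dhm.
#' @export
call_dm_dhm <- function(cohort, mutation_flag, config = pipeline_config(),
                        welch = FALSE) {
  flag <- resolve_flag(cohort, mutation_flag)
  res <- differential_table(cohort$beta, flag, config, welch)
  res$is_dhm <- res$is_dm & !is.na(res$delta) & res$delta > config$dhm_delta
  res
}

#' Call differentially expressed genes
#'
#' Same machinery as [call_dm_dhm()] applied to the expression matrix;
#' additionally reports the linear-scale fold change of group means,
#' FC = mean_mut / (mean_wt + 0.01) (the stabilizer keeps FC defined for
#' silent genes).
#'
#' @inheritParams call_dm_dhm
#' @return data.frame as in [call_dm_dhm()] plus `fc` and `log2_fc`
#'   (no `is_dhm` column).
#' @export
call_deg <- function(cohort, mutation_flag, config = pipeline_config(),
                     welch = FALSE) {
  flag <- resolve_flag(cohort, mutation_flag)
  res <- differential_table(cohort$expression, flag, config, welch)
  res$fc <- res$mean_mut / (res$mean_wt + 0.01)
  res$log2_fc <- log2(res$fc)
  res
}

resolve_flag <- function(cohort, mutation_flag) {
  if (is.character(mutation_flag) && length(mutation_flag) == 1L) {
    if (!mutation_flag %in% names(cohort$samples)) {
      stopf("no sample-sheet column '%s'", mutation_flag)
    }
    mutation_flag <- cohort$samples[[mutation_flag]]
  }
  stopifnot(is.logical(mutation_flag),
            length(mutation_flag) == nrow(cohort$samples))
  if (sum(mutation_flag) < 2L || sum(!mutation_flag) < 2L) {
    stop("each mutation group needs at least 2 samples")
  }
  mutation_flag
}

differential_table <- function(mat, flag, config, welch) {
  res <- row_ttest(mat[, flag, drop = FALSE],
                   mat[, !flag, drop = FALSE], welch = welch)
  q <- bh_adjust(res$p)
  data.frame(feature_id = rownames(mat), mean_mut = res$mean_mut,
             mean_wt = res$mean_wt, delta = res$delta,
             t_stat = res$t, p_value = res$p, q_value = q,
             is_dm = !is.na(q) & q < config$dm_fdr,
             stringsAsFactors = FALSE)
}

#' Identify strong CpG Traffic Lights
#'
#' A strong Traffic Light is a CpG TL whose CpG is differentially
#' methylated and whose associated gene is differentially expressed in
#' the mutated-vs-wild-type comparison.
#'
#' @param tls Traffic-Light table from [call_traffic_lights()].
#' @param dm per-CpG differential table from [call_dm_dhm()].
#' @param deg per-gene differential table from [call_deg()].
#' @param require_dhm demand DHM (hypermethylation) rather than plain DM
#'   for the methylation arm.
#' @return the TL rows that qualify, annotated with meth/expr deltas and
#'   q-values.
#' @export
strong_traffic_lights <- function(tls, dm, deg, require_dhm = FALSE) {
  meth_ok <- if (require_dhm) dm$is_dhm else dm$is_dm
  meth <- data.frame(cpg_id = dm$feature_id, meth_ok = meth_ok,
                     meth_delta = dm$delta, meth_q = dm$q_value,
                     stringsAsFactors = FALSE)
  ex <- data.frame(gene = deg$feature_id, expr_ok = deg$is_dm,
                   expr_log2_fc = deg$log2_fc, expr_q = deg$q_value,
                   stringsAsFactors = FALSE)
  out <- merge(merge(tls, meth, by = "cpg_id"), ex, by = "gene")
  out <- out[out$is_tl & out$meth_ok & out$expr_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prioritize genes with strong Traffic Lights
#'
#' Applies the published gene gates on top of the strong-Traffic-Light
#' requirement: the gene carries at least one strong CpG TL (optionally
#' restricted to motif-proximal CpGs), |log2 FC| > log2(`gene_fc`),
#' expression q < `dm_fdr`, and the larger group mean expression exceeds
#' `gene_min_expr` (the "expressed at all" gate, linear scale).
#'
#' @param tls,dm,deg result tables of the three upstream calls.
#' @param proximity per-CpG proximity table (cpg_id, near_tfbs) from
#'   [annotate_cpg_proximity()] or generator truth; NULL disables the
#'   proximity restriction.
#' @param config a `pipeline_config`.
#' @param require_near keep only strong TLs at motif-proximal CpGs.
#' @param require_dhm see [strong_traffic_lights()].
#' @return data.frame of retained genes with gate values, one row per
#'   gene.
#' @export
select_strong_tl_genes <- function(tls, dm, deg, proximity = NULL,
                                   config = pipeline_config(),
                                   require_near = FALSE,
                                   require_dhm = FALSE) {
  st <- strong_traffic_lights(tls, dm, deg, require_dhm = require_dhm)
  if (!is.null(proximity)) {
    st$near_tfbs <- proximity$near_tfbs[match(st$cpg_id, proximity$cpg_id)]
    if (require_near) st <- st[st$near_tfbs %in% TRUE, , drop = FALSE]
  }
  if (!nrow(st)) return(empty_gene_table())
  deg_sub <- deg[match(unique(st$gene), deg$feature_id), , drop = FALSE]
  keep <- abs(deg_sub$log2_fc) > log2(config$gene_fc) &
    !is.na(deg_sub$q_value) & deg_sub$q_value < config$dm_fdr &
    pmax(deg_sub$mean_mut, deg_sub$mean_wt) > config$gene_min_expr
  genes <- deg_sub[keep, , drop = FALSE]
  if (!nrow(genes)) return(empty_gene_table())
  n_tl <- vapply(genes$feature_id,
                 function(g) sum(st$gene == g), integer(1))
  out <- data.frame(gene = genes$feature_id, n_strong_tl = n_tl,
                    fc = genes$fc, log2_fc = genes$log2_fc,
                    expr_q = genes$q_value, mean_mut = genes$mean_mut,
                    mean_wt = genes$mean_wt, stringsAsFactors = FALSE)
  out[order(out$expr_q), , drop = FALSE]
}

empty_gene_table <- function() {
  data.frame(gene = character(), n_strong_tl = integer(),
             fc = numeric(), log2_fc = numeric(), expr_q = numeric(),
             mean_mut = numeric(), mean_wt = numeric(),
             stringsAsFactors = FALSE)
}
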