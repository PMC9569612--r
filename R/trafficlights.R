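#' Call CpG Traffic Lights
#'
#' For every manifest CpG-gene pair with the gene present in the
#' expression matrix, the Spearman correlation between the CpG's beta
#' values and the gene's expression across samples is computed
#' (pairwise-complete, average ranks for ties, p from the
#' t-approximation). P-values are BH-adjusted over all testable pairs of
#' the run, and a pair with q below the Traffic-Light FDR threshold
#' (default 0.005) is called a CpG Traffic Light. Pairs whose correlation
#' is undefined (too few complete pairs, or a constant vector) are kept
#' in the output with NA statistics but excluded from the BH family.
#'
#' Both correlation signs qualify; the sign is retained for downstream
#' interpretation (negative: methylation up, expression down).
#'
#' @param cohort a `cohort_matrices`.
#' @param manifest CpG manifest data.frame (cpg_id, gene, ...).
#' @param config a `pipeline_config` (uses `tl_fdr`, `min_pairs`).
#' @return data.frame with one row per testable pair: cpg_id, gene, rho,
#'   n_used, p_value, q_value, is_tl.
#' @export
call_traffic_lights <- function(cohort, manifest, config = pipeline_config()) {
  beta <- cohort$beta
  expr <- cohort$expression
  pairs <- manifest[manifest$cpg_id %in% rownames(beta), , drop = FALSE]
  skipped <- sum(!(pairs$gene %in% rownames(expr)))
  if (skipped > 0L) {
    message(sprintf("call_traffic_lights: %d pairs skipped (gene not in expression matrix)",
                    skipped))
  }
  pairs <- pairs[pairs$gene %in% rownames(expr), , drop = FALSE]
  if (!nrow(pairs)) stop("no CpG-gene pair is testable")
  if (!length(intersect(colnames(beta), colnames(expr)))) {
    stop("beta and expression matrices share no samples")
  }
  n <- nrow(pairs)
  rho <- p <- rep(NA_real_, n)
  n_used <- integer(n)
  for (i in seq_len(n)) {
    st <- spearman_test(beta[pairs$cpg_id[i], ], expr[pairs$gene[i], ],
                        min_pairs = config$min_pairs)
    rho[i] <- st$rho; p[i] <- st$p; n_used[i] <- st$n_used
  }
  q <- bh_adjust(p)
  data.frame(cpg_id = pairs$cpg_id, gene = pairs$gene, rho = rho,
             n_used = n_used, p_value = p, q_value = q,
             is_tl = !is.na(q) & q < config$tl_fdr,
             stringsAsFactors = FALSE)
}
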