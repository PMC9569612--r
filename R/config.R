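#' Pipeline configuration
#'
#' Collects every statistical threshold used by the pipeline in one
#' auditable object. Defaults are the thresholds of the published analysis:
#' PWM match p-value < 0.001, Traffic-Light FDR < 0.005, differential
#' methylation/expression FDR < 0.05, hypermethylation delta > 0.15,
#' CpG-centered windows of +/- 100 bp, gene gates FC > 2 and group mean
#' expression > 0.5, and a 500-day survival landmark.
#'
#' @param pwm_pvalue exact tail probability defining the PWM match
#'   threshold, in (0,1).
#' @param tl_fdr Benjamini-Hochberg FDR threshold for calling a CpG
#'   Traffic Light.
#' @param dm_fdr BH FDR threshold for differential methylation and
#'   differential expression.
#' @param dhm_delta minimum group mean beta difference (strict) for a DM
#'   CpG to be called differentially hypermethylated.
#' @param window_halfwidth half-width in bp of the CpG-centered scan
#'   window.
#' @param gene_fc fold-change gate for the prioritized gene list.
#' @param gene_min_expr minimum group-mean expression (linear RPKM-like
#'   scale) for a gene to count as expressed.
#' @param landmark_days landmark time in days for conditional survival
#'   comparison.
#' @param min_pairs minimum number of complete sample pairs for a Spearman
#'   correlation to be computed.
#' @param rng_seed integer seed recorded with the run.
#'
#' @return An object of class `pipeline_config` (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$dhm_delta
#' @export
pipeline_config <- function(pwm_pvalue = 0.001,
                            tl_fdr = 0.005,
                            dm_fdr = 0.05,
                            dhm_delta = 0.15,
                            window_halfwidth = 100L,
                            gene_fc = 2,
                            gene_min_expr = 0.5,
                            landmark_days = 500,
                            min_pairs = 8L,
                            rng_seed = 1L) {
  stopifnot(
    is.numeric(pwm_pvalue), pwm_pvalue > 0, pwm_pvalue < 1,
    is.numeric(tl_fdr), tl_fdr > 0, tl_fdr < 1,
    is.numeric(dm_fdr), dm_fdr > 0, dm_fdr < 1,
    is.numeric(dhm_delta), dhm_delta > 0, dhm_delta < 1,
    is.numeric(window_halfwidth), window_halfwidth > 0,
    is.numeric(gene_fc), gene_fc > 0,
    is.numeric(gene_min_expr), gene_min_expr >= 0,
    is.numeric(landmark_days), landmark_days >= 0,
    is.numeric(min_pairs), min_pairs >= 3
  )
  structure(list(
    pwm_pvalue = pwm_pvalue,
    tl_fdr = tl_fdr,
    dm_fdr = dm_fdr,
    dhm_delta = dhm_delta,
    window_halfwidth = as.integer(window_halfwidth),
    gene_fc = gene_fc,
    gene_min_expr = gene_min_expr,
    landmark_days = landmark_days,
    min_pairs = as.integer(min_pairs),
    rng_seed = as.integer(rng_seed)
  ), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
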