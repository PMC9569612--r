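#' Dichotomize patients by methylation at one CpG
#'
#' Median rule: samples with beta strictly above the cohort median are
#' 'hyper', the rest (ties included) 'hypo'. Threshold rule: fixed beta
#' cutoff, strictly above = 'hyper'.
#'
#' @param beta_row named beta values for one CpG across samples.
#' @param rule "median" or "threshold".
#' @param threshold beta cutoff for the threshold rule.
#' @return character vector of "hyper"/"hypo" labels (NA beta -> NA).
#' @export
dichotomize_by_methylation <- function(beta_row,
                                       rule = c("median", "threshold"),
                                       threshold = 0.5) {
  rule <- match.arg(rule)
  cut <- if (rule == "median") stats::median(beta_row, na.rm = TRUE)
         else threshold
  out <- ifelse(beta_row > cut, "hyper", "hypo")
  out[is.na(beta_row)] <- NA_character_
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times in days.
#' @param event logical, death observed.
#' @return data.frame with time (distinct event times), n_risk, n_event,
#'   survival (step values after each event time).
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0, na.rm = TRUE))
  ok <- !is.na(time) & !is.na(event)
  time <- time[ok]; event <- as.logical(event[ok])
  times <- sort(unique(time[event]))
  if (!length(times)) {
    return(data.frame(time = numeric(), n_risk = integer(),
                      n_event = integer(), survival = numeric()))
  }
  n_risk <- vapply(times, function(t) sum(time >= t), integer(1))
  n_event <- vapply(times, function(t) sum(time == t & event), integer(1))
  data.frame(time = times, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test, with optional landmark conditioning
#'
#' Standard log-rank chi-square between two groups. With a landmark L,
#' only subjects still under observation past L are retained and their
#' clocks are reset to time - L (conditional survival); landmark = 0 (or
#' NULL) is the overall test.
#'
#' @param time,event,group aligned vectors; `group` must have exactly
#'   two levels.
#' @param landmark_days landmark time L, or NULL for the overall test.
#' @return list with chi2, p, observed, expected (per group), n, and
#'   `flag` ("ok", or the reason the test is undefined).
#' @export
logrank <- function(time, event, group, landmark_days = NULL) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- as.logical(event[ok])
  group <- as.character(group[ok])
  if (!is.null(landmark_days) && landmark_days > 0) {
    keep <- time > landmark_days
    time <- time[keep] - landmark_days
    event <- event[keep]
    group <- group[keep]
  }
  levels <- sort(unique(group))
  if (length(levels) != 2L) {
    return(list(chi2 = NA_real_, p = NA_real_,
                observed = NA, expected = NA, n = length(time),
                flag = "a group is empty"))
  }
  g1 <- group == levels[1]
  times <- sort(unique(time[event]))
  if (!length(times)) {
    return(list(chi2 = NA_real_, p = NA_real_, observed = NA,
                expected = NA, n = length(time), flag = "no events"))
  }
  O1 <- E1 <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (V <= 0) {
    return(list(chi2 = NA_real_, p = NA_real_,
                observed = stats::setNames(c(O1, sum(event) - O1), levels),
                expected = stats::setNames(c(E1, sum(event) - E1), levels),
                n = length(time), flag = "zero variance"))
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = stats::setNames(c(O1, sum(event) - O1), levels),
       expected = stats::setNames(c(E1, sum(event) - E1), levels),
       n = length(time), flag = "ok")
}

#' Survival comparison for one CpG's methylation groups
#'
#' Dichotomizes the cohort at the given CpG and runs both the overall
#' and the landmark log-rank test.
#'
#' @param cohort a `cohort_matrices` with survival fields in the sample
#'   sheet.
#' @param cpg_id CpG to dichotomize on.
#' @param config a `pipeline_config` (uses `landmark_days`).
#' @param rule,threshold see [dichotomize_by_methylation()].
#' @return list with `groups`, `overall`, `landmark`, and the two
#'   Kaplan-Meier tables.
#' @export
survival_by_cpg <- function(cohort, cpg_id, config = pipeline_config(),
                            rule = "median", threshold = 0.5) {
  if (!cpg_id %in% rownames(cohort$beta)) {
    stopf("CpG '%s' not in the beta matrix", cpg_id)
  }
  groups <- dichotomize_by_methylation(cohort$beta[cpg_id, ],
                                       rule = rule, threshold = threshold)
  s <- cohort$samples
  list(groups = groups,
       overall = logrank(s$survival_days, s$death_observed, groups),
       landmark = logrank(s$survival_days, s$death_observed, groups,
                          landmark_days = config$landmark_days),
       km = lapply(split(seq_len(nrow(s)), groups), function(i) {
         kaplan_meier(s$survival_days[i], s$death_observed[i])
       }))
}
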