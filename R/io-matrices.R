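#' Read a CpG manifest
#'
#' Tab-separated manifest with columns `cpg_id`, `chrom`, `pos`, `gene`.
#' `pos` is the 0-based forward-strand position of the C of the CpG.
#' A CpG may appear on several rows when it is associated with several
#' genes; the (cpg_id, gene) pair must be unique.
#'
#' @param path path to the manifest TSV.
#' @return data.frame with columns cpg_id, chrom, pos (integer), gene.
#' @export
read_cpg_manifest <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  need <- c("cpg_id", "chrom", "pos", "gene")
  if (!all(need %in% names(df))) {
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(df$pos) || any(df$pos < 0)) {
    stop("manifest positions must be non-negative integers")
  }
  key <- paste(df$cpg_id, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("duplicate (cpg_id, gene) pair in manifest: %s",
          df$cpg_id[duplicated(key)][1])
  }
  df
}

#' @rdname read_cpg_manifest
#' @param manifest data.frame as returned by `read_cpg_manifest`.
#' @export
write_cpg_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Shared TSV matrix reader: first column = row id, header = sample ids.
# Unparseable cells become NA; values violating `check` are an error that
# names the offending row and column.
read_value_matrix <- function(path, kind, check, check_msg) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 2L) stopf("%s matrix needs an id column plus samples", kind)
  samples <- names(df)[-1]
  if (any(!nzchar(samples))) stopf("%s matrix has an empty sample header", kind)
  if (anyDuplicated(samples)) stopf("%s matrix has duplicate sample ids", kind)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate %s id in matrix: %s", kind, ids[duplicated(ids)][1])
  }
  mat <- matrix(NA_real_, nrow(df), length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(val) & !check(val))
    if (length(bad)) {
      stopf("%s at row '%s', column '%s': value %s %s",
            kind, ids[bad[1]], samples[j], raw[bad[1]], check_msg)
    }
    mat[, j] <- val
  }
  mat
}

#' Read a beta-value matrix (CpG x sample)
#'
#' TSV with a header row of sample ids and CpG ids in the first column.
#' Rows are restricted to the manifest's CpGs and returned in manifest
#' order; unparseable cells become NA; values outside \[0,1\] are rejected
#' with an error naming the row and column.
#'
#' @param path path to the TSV.
#' @param manifest optional manifest data.frame; when supplied, rows are
#'   subset and ordered by the manifest's (unique) cpg_id order, and CpGs
#'   absent from the file become all-NA rows.
#' @return numeric matrix, CpGs in rows, samples in columns.
#' @export
read_beta_matrix <- function(path, manifest = NULL) {
  mat <- read_value_matrix(path, "beta",
                           function(v) v >= 0 & v <= 1,
                           "is outside [0, 1]")
  if (!is.null(manifest)) {
    ids <- unique(manifest$cpg_id)
    out <- matrix(NA_real_, length(ids), ncol(mat),
                  dimnames = list(ids, colnames(mat)))
    hit <- intersect(ids, rownames(mat))
    out[hit, ] <- mat[hit, , drop = FALSE]
    mat <- out
  }
  mat
}

#' Read an expression matrix (gene x sample)
#'
#' Same format as [read_beta_matrix()] but values must be non-negative
#' (RPKM-like scale).
#' @inheritParams read_beta_matrix
#' @export
read_expression_matrix <- function(path) {
  read_value_matrix(path, "expression", function(v) v >= 0,
                    "is negative")
}

#' Write a value matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param id_col name of the first (row id) column.
#' @export
write_value_matrix <- function(mat, path, id_col = "cpg_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `runx1_mutated`, `cebpa_mutated` and
#' optionally `survival_days`, `death_observed`. A missing survival time
#' forces the event indicator to missing as well.
#'
#' @param path path to the TSV.
#' @return data.frame of per-sample metadata.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("sample_id", "runx1_mutated", "cebpa_mutated")
  if (!all(need %in% names(df))) {
    stopf("sample sheet must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  df$sample_id <- as.character(df$sample_id)
  df$runx1_mutated <- as.logical(df$runx1_mutated)
  df$cebpa_mutated <- as.logical(df$cebpa_mutated)
  if (!"survival_days" %in% names(df)) df$survival_days <- NA_real_
  if (!"death_observed" %in% names(df)) df$death_observed <- NA
  df$survival_days <- suppressWarnings(as.numeric(df$survival_days))
  if (any(df$survival_days < 0, na.rm = TRUE)) {
    stop("survival_days must be non-negative")
  }
  df$death_observed <- as.logical(df$death_observed)
  df$death_observed[is.na(df$survival_days)] <- NA
  df
}

#' Bundle cohort matrices and sample metadata
#'
#' Aligns the beta and expression matrices to the sample sheet's sample
#' order and validates value ranges. Samples absent from either matrix are
#' an error: the pipeline operates on the common cohort.
#'
#' @param beta CpG x sample beta-value matrix (values in \[0,1\] or NA).
#' @param expression gene x sample non-negative expression matrix.
#' @param samples sample sheet data.frame (see [read_sample_sheet()]).
#' @return object of class `cohort_matrices`.
#' @export
cohort_matrices <- function(beta, expression, samples) {
  stopifnot(is.matrix(beta), is.matrix(expression),
            is.data.frame(samples))
  ids <- samples$sample_id
  if (!all(ids %in% colnames(beta)) || !all(ids %in% colnames(expression))) {
    stop("every sample in the sheet must be a column of both matrices")
  }
  beta <- beta[, ids, drop = FALSE]
  expression <- expression[, ids, drop = FALSE]
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  if (any(expression < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative")
  }
  structure(list(beta = beta, expression = expression, samples = samples),
            class = "cohort_matrices")
}

#' @export
print.cohort_matrices <- function(x, ...) {
  cat(sprintf("Cohort: %d samples, %d CpGs, %d genes\n",
              nrow(x$samples), nrow(x$beta), nrow(x$expression)))
  cat(sprintf("  RUNX1-mutated: %d, CEBPA-mutated: %d\n",
              sum(x$samples$runx1_mutated, na.rm = TRUE),
              sum(x$samples$cebpa_mutated, na.rm = TRUE)))
  invisible(x)
}
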