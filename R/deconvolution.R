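#' Estimate cell-type proportions by constrained least squares
#'
#' Solves min ||A w - b||^2 subject to w >= 0 and sum(w) = 1, where A is
#' the reference atlas (marker CpG x cell type beta values) and b the
#' sample's marker betas. The non-negativity is handled by a
#' Lawson-Hanson active-set solve; the sum-to-one constraint enters as a
#' heavily weighted penalty row and the solution is renormalized, so the
#' returned weights sum to 1 within 1e-6. Missing marker betas are
#' dropped.
#'
#' @param beta_sample named numeric vector of beta values covering the
#'   atlas marker CpGs (extra entries ignored).
#' @param atlas marker x cell-type reference matrix, values in \[0,1\].
#' @return list with `proportions` (named vector) and `residual` (the
#'   residual norm on the marker system).
#' @export
estimate_proportions <- function(beta_sample, atlas) {
  stopifnot(is.matrix(atlas), ncol(atlas) >= 2L)
  markers <- intersect(rownames(atlas), names(beta_sample))
  b <- beta_sample[markers]
  ok <- !is.na(b)
  A <- atlas[markers[ok], , drop = FALSE]
  b <- b[ok]
  if (nrow(A) < ncol(A)) {
    stop("fewer usable marker CpGs than cell types")
  }
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    dep <- colnames(A)[qrA$pivot[(qrA$rank + 1L):ncol(A)]]
    stopf("reference atlas is rank-deficient; collinear columns: %s",
          paste(dep, collapse = ", "))
  }
  lambda <- 100 * max(1, sqrt(nrow(A)))
  A_aug <- rbind(A, lambda)
  b_aug <- c(b, lambda)
  w <- nnls_solve(A_aug, b_aug)
  if (sum(w) <= 0) stop("degenerate deconvolution solution")
  w <- w / sum(w)
  list(proportions = stats::setNames(w, colnames(atlas)),
       residual = sqrt(sum((A %*% w - b)^2)))
}

# Non-negative least squares. For small systems (<= `enum_max` columns)
# the optimum is found exactly by active-set enumeration: the NNLS
# solution is the best-objective unconstrained solve over a support set
# whose coefficients are all non-negative. Larger systems fall back to
# a Lawson-Hanson iteration with hard caps.
nnls_solve <- function(A, b, enum_max = 12L) {
  n <- ncol(A)
  if (n <= enum_max) return(nnls_enumerate(A, b))
  nnls_lawson_hanson(A, b)
}

nnls_enumerate <- function(A, b) {
  n <- ncol(A)
  best <- NULL
  best_obj <- Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    s <- tryCatch(qr.solve(A[, idx, drop = FALSE], b),
                  error = function(e) NULL)
    if (is.null(s) || any(s < 0)) next
    r <- b - A[, idx, drop = FALSE] %*% s
    obj <- sum(r^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- numeric(n)
      best[idx] <- s
    }
  }
  if (is.null(best)) numeric(n) else best
}

nnls_lawson_hanson <- function(A, b, tol = NULL, max_outer = NULL) {
  n <- ncol(A)
  if (is.null(max_outer)) max_outer <- 20L * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(crossprod(A, b))))
  for (outer in seq_len(max_outer)) {
    w <- drop(crossprod(A, b - A %*% x))
    cand <- !passive & w > tol
    if (!any(cand)) break
    j <- which.max(replace(w, !cand, -Inf))
    passive[j] <- TRUE
    for (inner in seq_len(n + 1L)) {
      s <- numeric(n)
      s[passive] <- drop(qr.solve(A[, passive, drop = FALSE], b))
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg] + 1e-300))
      alpha <- min(max(alpha, 0), 1)
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (alpha == 0) break  # numerical stall: drop and re-enter outer
    }
    if (all(s[passive] > tol)) x <- s
  }
  pmax(x, 0)
}

#' Estimate proportions for every sample of a matrix
#'
#' @param beta marker x sample beta matrix (rows covering the atlas
#'   markers).
#' @param atlas reference atlas.
#' @return list with `proportions` (sample x cell-type matrix) and
#'   `residuals`.
#' @export
estimate_proportions_matrix <- function(beta, atlas) {
  samples <- colnames(beta)
  props <- matrix(NA_real_, length(samples), ncol(atlas),
                  dimnames = list(samples, colnames(atlas)))
  resid <- stats::setNames(numeric(length(samples)), samples)
  for (i in seq_along(samples)) {
    est <- estimate_proportions(beta[, i], atlas)
    props[i, ] <- est$proportions
    resid[i] <- est$residual
  }
  list(proportions = props, residuals = resid)
}

#' Compare estimated cell-type proportions between mutation groups
#'
#' Per cell type, a two-sided Mann-Whitney test of the estimated
#' proportions between mutated and wild-type samples, BH-adjusted across
#' cell types.
#'
#' @param proportions sample x cell-type matrix from
#'   [estimate_proportions_matrix()].
#' @param mutation_flag logical vector aligned to the rows.
#' @return data.frame: cell_type, median_mut, median_wt, delta_median,
#'   p_value, q_value.
#' @export
compare_cell_proportions <- function(proportions, mutation_flag) {
  stopifnot(is.logical(mutation_flag),
            length(mutation_flag) == nrow(proportions))
  if (sum(mutation_flag) < 2L || sum(!mutation_flag) < 2L) {
    stop("each group needs at least 2 samples")
  }
  types <- colnames(proportions)
  p <- med_m <- med_w <- numeric(length(types))
  for (k in seq_along(types)) {
    x <- proportions[mutation_flag, k]
    y <- proportions[!mutation_flag, k]
    med_m[k] <- stats::median(x)
    med_w[k] <- stats::median(y)
    p[k] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  data.frame(cell_type = types, median_mut = med_m, median_wt = med_w,
             delta_median = med_m - med_w, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}
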