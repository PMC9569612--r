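#' Benjamini-Hochberg adjustment over the non-missing family
#'
#' Step-up adjusted q-values with the family restricted to the non-missing
#' p-values (a test that could not be performed is not part of the family).
#' Missing entries stay missing in the output.
#'
#' @param p numeric vector of p-values in \[0,1\]; NA allowed.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Spearman correlation with t-approximation p-value
#'
#' Pairwise-complete Spearman rank correlation (average ranks for ties)
#' with the two-sided p-value from the t-approximation of rho. Pairs with
#' a missing value in either vector are dropped; if fewer than `min_pairs`
#' complete pairs remain, or either vector is constant after deletion, the
#' correlation is undefined and both rho and p are returned as NA.
#'
#' @param x,y paired numeric vectors.
#' @param min_pairs minimum number of complete pairs (default 8).
#' @return list with `rho`, `p`, and `n_used`.
#' @export
spearman_test <- function(x, y, min_pairs = 8L) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(list(rho = NA_real_, p = NA_real_, n_used = n))
  }
  xs <- x[ok]; ys <- y[ok]
  if (length(unique(xs)) < 2L || length(unique(ys)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n_used = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(xs, ys, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = n)
}

# clip to [lo, hi] preserving dims; used wherever beta shifts could
# leave the unit interval
clip01 <- function(x, lo = 0, hi = 1) {
  x[] <- pmin(hi, pmax(lo, x))
  x
}

# stop() with a sprintf-style message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
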