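#' Build a log-odds motif model with an exact p-value threshold
#'
#' Converts a position count matrix into a log2-odds scoring matrix
#' against a background base composition, and derives the score threshold
#' corresponding to an exact match p-value: the smallest achievable score
#' s such that a random background sequence of motif length scores >= s
#' with probability <= `target_pvalue`.
#'
#' The score distribution is computed by dynamic programming, convolving
#' the per-position score distributions under the background model. For
#' motifs up to `exact_max_len` positions the convolution keeps exact
#' partial sums (accumulated in scan order), so the threshold is exact to
#' the last bit; longer motifs use a discretized convolution over
#' `n_bins` bins with per-position scores snapped upwards to the grid, so
#' the reported threshold is conservative (its true tail probability is
#' <= `target_pvalue`).
#'
#' @param counts L x 4 non-negative count (or frequency) matrix in
#'   A, C, G, T column order.
#' @param background base probabilities (A, C, G, T); must sum to 1.
#' @param pseudocount added to every cell before normalization
#'   (default 0.01).
#' @param target_pvalue match p-value defining the threshold
#'   (default 0.001).
#' @param name motif name.
#' @param method "auto" (exact for length <= `exact_max_len`, else
#'   binned), "exact" or "binned".
#' @param n_bins number of discretization bins for the binned method.
#' @param exact_max_len maximum motif length for the exact convolution.
#' @return object of class `motif_model` with elements `name`,
#'   `log_odds`, `background`, `threshold_score`, `threshold_pvalue`,
#'   `target_pvalue`.
#' @export
build_motif <- function(counts, background = rep(0.25, 4),
                        pseudocount = 0.01, target_pvalue = 0.001,
                        name = "motif",
                        method = c("auto", "exact", "binned"),
                        n_bins = 1000L, exact_max_len = 12L) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("count matrix must have 4 columns (A,C,G,T)")
  if (nrow(counts) < 1L) stop("count matrix must have at least one row")
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(length(background) == 4L, all(background >= 0),
            abs(sum(background) - 1) < 1e-8)
  if (any(background == 0 & colSums(counts) > 0)) {
    stop("background has a zero entry at a base with non-zero counts")
  }
  if (target_pvalue <= 0 || target_pvalue > 1) {
    stop("target_pvalue must be in (0, 1]")
  }
  probs <- counts + pseudocount
  probs <- probs / rowSums(probs)
  lo <- log2(sweep(probs, 2, background, "/"))
  colnames(lo) <- c("A", "C", "G", "T")
  L <- nrow(lo)
  if (method == "auto") method <- if (L <= exact_max_len) "exact" else "binned"
  thr <- if (method == "exact") {
    exact_score_threshold(lo, background, target_pvalue)
  } else {
    binned_score_threshold(lo, background, target_pvalue, n_bins)
  }
  structure(list(name = name, log_odds = lo, background = background,
                 threshold_score = thr$score,
                 threshold_pvalue = thr$pvalue,
                 target_pvalue = target_pvalue,
                 method = method),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("Motif '%s': length %d, threshold %.4f (p = %.3g <= %.3g, %s DP)\n",
              x$name, nrow(x$log_odds), x$threshold_score,
              x$threshold_pvalue, x$target_pvalue, x$method))
  invisible(x)
}

# Exact DP: the score distribution's support is built with the same
# left-to-right accumulation as the scanner, so support values are
# bit-identical to scanner path sums. Partial sums within `merge_tol`
# are merged (keeping the cluster minimum, so a `>=` comparison against
# the threshold never loses a mathematically tied sequence); distinct
# achievable scores sit far above that tolerance.
exact_score_threshold <- function(lo, background, target_pvalue,
                                  merge_tol = 1e-12) {
  sums <- 0
  probs <- 1
  for (j in seq_len(nrow(lo))) {
    s <- as.vector(outer(sums, lo[j, ], "+"))
    p <- as.vector(outer(probs, background))
    o <- order(s)
    s <- s[o]; p <- p[o]
    grp <- cumsum(c(TRUE, diff(s) > merge_tol))
    sums <- s[!duplicated(grp)]  # cluster minimum
    probs <- as.vector(rowsum(p, grp))
  }
  # group achievable scores that are ties up to accumulation noise
  o <- order(sums)
  sums <- sums[o]; probs <- probs[o]
  grp <- cumsum(c(TRUE, diff(sums) > 1e-9))
  g_min <- sums[!duplicated(grp)]
  g_prob <- as.vector(rowsum(probs, grp))
  tail <- rev(cumsum(rev(g_prob)))  # tail[i] = P(score >= group i)
  ok <- which(tail <= target_pvalue)
  if (!length(ok)) {
    return(list(score = Inf, pvalue = 0))
  }
  i <- min(ok)
  list(score = g_min[i], pvalue = tail[i])
}

# Binned DP: per-position scores snapped upwards to a uniform grid, so
# the snapped total dominates the true total and the threshold errs on
# the conservative side.
binned_score_threshold <- function(lo, background, target_pvalue, n_bins) {
  L <- nrow(lo)
  lo_min <- sum(apply(lo, 1, min))
  lo_max <- sum(apply(lo, 1, max))
  w <- (lo_max - lo_min) / n_bins
  if (w <= 0) {  # degenerate: single achievable score
    return(list(score = lo_max, pvalue = 1))
  }
  k <- ceiling(lo / w)  # integer grid indices, ceil-snap
  kmin <- apply(k, 1, min)
  dist <- 1  # probability vector over (ksum - cumulative kmin), offset 0
  for (j in seq_len(L)) {
    shifts <- k[j, ] - kmin[j]
    span <- length(dist) + max(shifts)
    nd <- numeric(span)
    for (b in 1:4) {
      idx <- seq_along(dist) + shifts[b]
      nd[idx] <- nd[idx] + dist * background[b]
    }
    dist <- nd
  }
  base <- sum(kmin)  # dist[i] is P(ksum == base + i - 1)
  tail <- rev(cumsum(rev(dist)))
  ok <- which(tail <= target_pvalue)
  if (!length(ok)) {
    return(list(score = Inf, pvalue = 0))
  }
  i <- min(ok)
  list(score = (base + i - 1) * w, pvalue = tail[i])
}

# DNA string -> integer codes 1..4 (A,C,G,T); anything else (N) -> NA
dna_codes <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  match(chars, c("A", "C", "G", "T"))
}

# Score every offset of `codes` on one strand; ambiguous bases score -Inf.
score_offsets <- function(codes, lo) {
  L <- nrow(lo)
  n_off <- length(codes) - L + 1L
  if (n_off < 1L) return(numeric(0))
  acc <- numeric(n_off)
  for (j in seq_len(L)) {
    s <- lo[j, ][codes[seq_len(n_off) + j - 1L]]
    s[is.na(s)] <- -Inf
    acc <- acc + s
  }
  acc
}

#' Scan one sequence for motif matches on both strands
#'
#' Every offset whose log-odds score reaches the motif's threshold is
#' reported. Coordinates are 0-based half-open within the sequence; a
#' minus-strand site's interval covers the forward-strand bases whose
#' reverse complement matches.
#'
#' @param seq character or DNAString-like sequence.
#' @param motif a `motif_model`.
#' @param min_score override for the score threshold (default the
#'   motif's exact-p threshold).
#' @return data.frame with columns start, end, strand, score.
#' @export
scan_sequence <- function(seq, motif, min_score = motif$threshold_score) {
  codes <- dna_codes(seq)
  L <- nrow(motif$log_odds)
  len <- length(codes)
  fwd <- score_offsets(codes, motif$log_odds)
  rc <- rev(5L - codes)
  rev_sc <- score_offsets(rc, motif$log_odds)
  hits_f <- which(fwd >= min_score)
  hits_r <- which(rev_sc >= min_score)
  data.frame(
    start = c(hits_f - 1L, len - (hits_r - 1L) - L),
    end = c(hits_f - 1L + L, len - (hits_r - 1L)),
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    score = c(fwd[hits_f], rev_sc[hits_r]),
    stringsAsFactors = FALSE
  )
}

#' Scan CpG-centered windows of a genome for motif sites
#'
#' For every manifest CpG, the window of +/- `window_halfwidth` bp around
#' the CpG position is scanned on both strands at the motif's exact
#' p-value threshold. Windows are truncated at contig edges.
#'
#' @param genome `DNAStringSet` covering the manifest chromosomes.
#' @param manifest CpG manifest data.frame (cpg_id, chrom, pos, gene).
#' @param motif a `motif_model`.
#' @param window_halfwidth window half-width in bp (default 100).
#' @return data.frame of predicted sites: cpg_id, chrom, start, end,
#'   strand, score (genome coordinates, 0-based half-open).
#' @export
scan_windows <- function(genome, manifest, motif, window_halfwidth = 100L) {
  mf <- manifest[!duplicated(manifest$cpg_id), , drop = FALSE]
  if (!all(mf$chrom %in% names(genome))) {
    stopf("manifest chromosome '%s' absent from genome",
          setdiff(mf$chrom, names(genome))[1])
  }
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    chrom <- mf$chrom[i]; pos <- mf$pos[i]
    clen <- lens[[chrom]]
    if (pos >= clen) {
      stopf("CpG %s at position %d exceeds contig %s length %d",
            mf$cpg_id[i], pos, chrom, clen)
    }
    w_start <- max(0L, pos - window_halfwidth)
    w_end <- min(clen, pos + window_halfwidth)
    win <- Biostrings::subseq(genome[[chrom]], w_start + 1L, w_end)
    hits <- scan_sequence(win, motif)
    if (nrow(hits)) {
      out[[i]] <- data.frame(cpg_id = mf$cpg_id[i], chrom = chrom,
                             start = w_start + hits$start,
                             end = w_start + hits$end,
                             strand = hits$strand, score = hits$score,
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(cpg_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  }
  do.call(rbind, out)
}

#' Flag predicted sites by ChIP-seq peak support
#'
#' A site is peak-supported when its interval overlaps a peak by at least
#' one base (half-open arithmetic).
#'
#' @param sites data.frame of predicted sites from [scan_windows()].
#' @param peaks data.frame of peak intervals (chrom, start, end).
#' @param require_peak drop unsupported sites instead of flagging them.
#' @return `sites` with a logical `peak_supported` column.
#' @export
filter_by_peaks <- function(sites, peaks, require_peak = FALSE) {
  if (!nrow(sites)) {
    sites$peak_supported <- logical(0)
    return(sites)
  }
  if (is.null(peaks) || !nrow(peaks)) {
    sites$peak_supported <- FALSE
  } else {
    site_gr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end))
    peak_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
    sites$peak_supported <-
      GenomicRanges::countOverlaps(site_gr, peak_gr, minoverlap = 1L) > 0L
  }
  if (require_peak) sites <- sites[sites$peak_supported, , drop = FALSE]
  sites
}

#' Annotate CpGs with TFBS proximity
#'
#' A CpG is motif-proximal when at least one retained predicted site lies
#' within its own scan window.
#'
#' @param manifest CpG manifest data.frame.
#' @param sites retained predicted sites (after any peak filtering).
#' @return data.frame with columns cpg_id, near_tfbs.
#' @export
annotate_cpg_proximity <- function(manifest, sites) {
  ids <- unique(manifest$cpg_id)
  data.frame(cpg_id = ids,
             near_tfbs = ids %in% unique(sites$cpg_id),
             stringsAsFactors = FALSE)
}
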