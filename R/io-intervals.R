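#' Read a BED file of genomic intervals
#'
#' 3- or 6-column BED, 0-based half-open. Output is sorted by chromosome
#' then start; strand is '.' when column 6 is absent.
#'
#' @param path path to the BED file.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stopf("BED line %d has fewer than 3 columns", which(n < 3L)[1])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stopf("BED line %d has a non-integer coordinate",
          which(is.na(start) | is.na(end))[1])
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stopf("BED line %d: start >= end (%d >= %d)",
          bad[1], start[bad[1]], end[bad[1]])
  }
  strand <- rep(".", length(lines))
  has6 <- n >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  if (!all(strand %in% c("+", "-", "."))) {
    stop("BED strand column must be '+', '-' or '.'")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Write intervals as BED
#'
#' @param intervals data.frame with chrom, start, end and optionally
#'   strand and score columns.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  score <- if ("score" %in% names(intervals)) intervals$score else 0
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  out <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' 4-column bedGraph (chrom, start, end, value), 0-based half-open.
#' Overlapping intervals are an error; gaps are read as coverage 0 when
#' queried.
#'
#' @param path path to the bedGraph file.
#' @return object of class `coverage_track`: a sorted data.frame with
#'   columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 4L) stop("bedGraph needs 4 columns")
  out <- data.frame(chrom = df[[1]],
                    start = suppressWarnings(as.integer(df[[2]])),
                    end = suppressWarnings(as.integer(df[[3]])),
                    value = suppressWarnings(as.numeric(df[[4]])),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    stop("bedGraph has a non-integer coordinate")
  }
  if (anyNA(out$value) | any(!is.finite(out$value))) {
    stop("bedGraph value column must be finite and numeric")
  }
  if (any(out$start >= out$end)) stop("bedGraph interval with start >= end")
  coverage_track(out)
}

#' Construct a coverage track from an interval data.frame
#'
#' @param df data.frame with chrom, start, end, value.
#' @return `coverage_track` object (sorted, non-overlap checked).
#' @export
coverage_track <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (nrow(df) > 1L && any(same & df$start[-1] < df$end[-nrow(df)])) {
    stop("coverage track has overlapping intervals")
  }
  structure(df, class = c("coverage_track", "data.frame"))
}

#' @rdname coverage_track
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Run-length view of a track for fast binned queries; positions beyond
# the last interval of a chromosome are implicit zeros.
track_rle <- function(track) {
  gr <- GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(start = track$start + 1L, end = track$end)
  )
  GenomicRanges::coverage(gr, weight = track$value)
}

#' Length-weighted mean coverage over an interval
#'
#' Gaps between bedGraph intervals count as 0.
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return mean coverage (numeric scalar).
#' @export
track_mean <- function(track, chrom, start, end) {
  stopifnot(start < end)
  sub <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(sub)) return(0)
  s <- pmax(sub$start, start)
  e <- pmin(sub$end, end)
  w <- pmax(0L, e - s)
  sum(w * sub$value) / (end - start)
}

#' Read a plain-text position count/weight matrix
#'
#' One row per motif position, four whitespace-separated numbers in
#' A, C, G, T order; an optional leading '>' header line carries the
#' motif name (HOCOMOCO PCM style).
#'
#' @param path path to the matrix file.
#' @return list with `counts` (L x 4 matrix, columns A,C,G,T) and `name`.
#' @export
read_pwm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  name <- NA_character_
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (!length(lines)) stop("PWM file has no matrix rows")
  rows <- lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (length(vals) != 4L || anyNA(vals)) {
      stopf("PWM row %d does not contain exactly 4 numbers", i)
    }
    if (any(vals < 0)) stopf("PWM row %d has a negative count", i)
    vals
  })
  counts <- do.call(rbind, rows)
  colnames(counts) <- c("A", "C", "G", "T")
  list(counts = counts, name = name)
}

#' @rdname read_pwm
#' @param counts L x 4 count matrix.
#' @param name motif name written as a '>' header.
#' @export
write_pwm <- function(counts, path, name = "MOTIF") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", name), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers around Biostrings so every module handles genomes as
#' `DNAStringSet` objects.
#' @param path FASTA path.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome
#' @param genome a `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
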