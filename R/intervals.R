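# Stranded genomic intervals as plain data frames, 0-based half-open.
# Columns: chrom (character), start, end (integer-like), strand in {+,-,*}.

#' Construct a stranded interval table
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive start coordinates.
#' @param end exclusive end coordinates.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @param ... further columns, recycled by `data.frame()`.
#' @return a data frame with at least columns chrom/start/end/strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", ...) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    ...,
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval table against optional chromosome sizes
#'
#' Checks `0 <= start < end`, strand vocabulary, and (when `chrom_sizes` is
#' given) that every chromosome is known and `end` does not exceed its length.
#'
#' @param x interval data frame.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("invalid interval: need 0 <= start < end")
  }
  if (!all(x$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
    if (any(x$end > chrom_sizes[x$chrom])) {
      stop("interval end beyond chromosome length")
    }
  }
  invisible(x)
}

#' Validate a chromosome-size table
#' @param chrom_sizes named numeric vector of lengths.
#' @return the sizes, invisibly.
#' @export
validate_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || anyDuplicated(names(chrom_sizes))) {
    stop("chrom sizes must be a uniquely named vector")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  invisible(chrom_sizes)
}

# IRanges view of an interval table for one chromosome (1-based closed).
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

# For each row of `query`, does it overlap (>= 1 base) any row of `subject`?
# same_strand: require equal strand, with "*" matching anything.
overlaps_any <- function(query, subject, same_strand = FALSE) {
  hit <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(hit)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (!length(si)) next
    ov <- IRanges::overlapsAny(as_iranges0(query[qi, , drop = FALSE]),
                               as_iranges0(subject[si, , drop = FALSE]))
    if (same_strand) {
      h <- IRanges::findOverlaps(as_iranges0(query[qi, , drop = FALSE]),
                                 as_iranges0(subject[si, , drop = FALSE]))
      qs <- query$strand[qi][S4Vectors::queryHits(h)]
      ss <- subject$strand[si][S4Vectors::subjectHits(h)]
      ok <- qs == ss | qs == "*" | ss == "*"
      ov <- tabulate(S4Vectors::queryHits(h)[ok], nbins = length(qi)) > 0
    }
    hit[qi] <- hit[qi] | ov
  }
  hit
}

# --- Coverage tracks -------------------------------------------------------

#' Create an empty per-base coverage track
#'
#' A coverage track stores one dense non-negative vector per
#' (chromosome, strand).  `signal_kind` records whether the values are
#' fragment coverage (integers) or read-end counts (possibly fractional,
#' e.g. proportionally distributed multi-mappers).
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param strands track strands, `c("+", "-")` or `"*"` for unstranded.
#' @param signal_kind `"fragment_coverage"` or `"read_end_counts"`.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_sizes, strands = c("+", "-"),
                           signal_kind = c("fragment_coverage", "read_end_counts")) {
  validate_chrom_sizes(chrom_sizes)
  signal_kind <- match.arg(signal_kind)
  data <- lapply(chrom_sizes, function(n) {
    stats::setNames(lapply(strands, function(s) numeric(n)), strands)
  })
  structure(list(chrom_sizes = chrom_sizes, strands = strands,
                 signal_kind = signal_kind, data = data),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", x$signal_kind, "\n")
  cat("  chromosomes:", length(x$chrom_sizes),
      sprintf("(%s bases)", format(sum(x$chrom_sizes), big.mark = ",")), "\n")
  cat("  strands:", paste(x$strands, collapse = " "), "\n")
  tot <- sum(vapply(x$data, function(ch) sum(vapply(ch, sum, 0)), 0))
  cat("  total signal:", format(tot), "\n")
  invisible(x)
}

#' All per-base values of a coverage track as one vector
#' @param track a [coverage_track()].
#' @return numeric vector pooling every chromosome and strand.
#' @export
track_values <- function(track) {
  unlist(lapply(track$data, function(ch) unlist(ch, use.names = FALSE)),
         use.names = FALSE)
}

# Signal on the given strand; unstranded tracks serve every strand request.
track_vector <- function(track, chrom, strand) {
  ch <- track$data[[chrom]]
  if (is.null(ch)) stop("unknown chromosome: ", chrom)
  if (!is.null(ch[[strand]])) return(ch[[strand]])
  if (!is.null(ch[["*"]])) return(ch[["*"]])
  stop("track has no strand '", strand, "'")
}
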