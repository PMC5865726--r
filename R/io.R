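# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are always 0-based half-open; GFF3 (1-based closed)
# is converted at this boundary: internal = (gff_start - 1, gff_end).

# --- chromosome sizes ------------------------------------------------------

#' Read a two-column chromosome-size TSV
#' @param path file with columns chrom, length.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  sizes <- stats::setNames(df$length, df$chrom)
  validate_chrom_sizes(sizes)
  sizes
}

#' Write chromosome sizes as a two-column TSV
#' @param chrom_sizes named vector of lengths.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  validate_chrom_sizes(chrom_sizes)
  utils::write.table(data.frame(names(chrom_sizes), as.integer(chrom_sizes)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- BEDPE mate pairs ------------------------------------------------------

#' Read SELEX mate pairs from a BEDPE file
#'
#' The 5' end of a mate is its start coordinate on "+" and `end - 1` on "-";
#' the pair's transcribed strand is taken from the strand1 column (the
#' library's fixed primer orientation encodes the RNA strand).  Records whose
#' mates map to different chromosomes are kept but flagged
#' `cross_chromosome` so the filter stage can count them.
#'
#' @param path BEDPE file (10 whitespace-separated columns).
#' @return data frame with columns chrom, end5_a, end5_b, strand, name,
#'   cross_chromosome.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), end5_a = integer(),
                      end5_b = integer(), strand = character(),
                      name = character(), cross_chromosome = logical(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 10)) {
    stop("malformed BEDPE line ", which(nf < 10)[1], ": expected 10 fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:10)), ncol = 10, byrow = TRUE)
  suppressWarnings({
    s1 <- as.integer(m[, 2]); e1 <- as.integer(m[, 3])
    s2 <- as.integer(m[, 5]); e2 <- as.integer(m[, 6])
  })
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad)) stop("malformed BEDPE line ", bad[1], ": non-numeric coordinate")
  st1 <- m[, 9]; st2 <- m[, 10]
  if (!all(c(st1, st2) %in% c("+", "-", "."))) {
    stop("malformed BEDPE strand field")
  }
  end5 <- function(s, e, st) ifelse(st == "-", e - 1L, s)
  data.frame(
    chrom = m[, 1],
    end5_a = end5(s1, e1, st1),
    end5_b = end5(s2, e2, st2),
    strand = ifelse(st1 == ".", "*", st1),
    name = m[, 7],
    cross_chromosome = m[, 1] != m[, 4],
    stringsAsFactors = FALSE
  )
}

#' Write mate pairs as BEDPE
#'
#' Inverse of [read_bedpe()] under the package's mate-orientation
#' convention: mate 1 is written on the pair's strand, mate 2 on the
#' opposite strand, each as a `read_len` interval anchored at its 5' end
#' (clipped to the fragment).
#'
#' @param pairs mate-pair data frame (chrom, end5_a, end5_b, strand, name).
#' @param path output path.
#' @param read_len nominal read length used to draw the mate intervals.
#' @export
write_bedpe <- function(pairs, path, read_len = 76L) {
  if (nrow(pairs) == 0) { file.create(path); return(invisible(path)) }
  lo <- pmin(pairs$end5_a, pairs$end5_b)
  hi <- pmax(pairs$end5_a, pairs$end5_b)
  len <- pmin(read_len, hi - lo + 1L)
  st <- ifelse(pairs$strand == "-", "-", "+")
  # interval holding a 5' end at coordinate p: [p, p+len) on "+", (p-len, p] on "-"
  iv <- function(p, s) {
    start <- ifelse(s == "+", p, p - len + 1L)
    cbind(start, start + len)
  }
  p1 <- ifelse(st == "+", lo, hi)     # mate 1 carries the pair strand
  p2 <- ifelse(st == "+", hi, lo)
  st2 <- ifelse(st == "+", "-", "+")
  m1 <- iv(p1, st); m2 <- iv(p2, st2)
  out <- data.frame(pairs$chrom, m1[, 1], m1[, 2], pairs$chrom, m2[, 1], m2[, 2],
                    pairs$name %||% sprintf("pair%06d", seq_len(nrow(pairs))),
                    ".", st, st2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- annotation ------------------------------------------------------------

.known_classes <- c("gene", "ORF", "ncRNA", "rRNA", "tRNA", "snoRNA",
                    "telomere", "telomeric_repeat", "X_element", "Y_prime",
                    "LTR", "ARS")

#' Read genome annotation from GFF3 or BED
#'
#' GFF3 1-based closed coordinates are converted to internal 0-based
#' half-open.  The feature class is the GFF3 type column, or the prefix of
#' the BED name field (`CLASS:ID`).  Classes outside the controlled
#' vocabulary are kept verbatim with a warning.
#'
#' @param path `.gff3`/`.gff` or `.bed` file.
#' @param chrom_sizes named vector of chromosome lengths; features beyond a
#'   chromosome end are an error.
#' @return data frame with columns chrom, start, end, strand, feature_class,
#'   feature_id.
#' @export
read_annotation <- function(path, chrom_sizes) {
  validate_chrom_sizes(chrom_sizes)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    id <- as.character(gr$ID %||% gr$Name %||% rep(NA_character_, length(gr)))
    id[is.na(id)] <- sprintf("feat%05d", which(is.na(id)))
    feats <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("^\\.$", "*", as.character(GenomicRanges::strand(gr))),
      feature_class = as.character(gr$type),
      feature_id = id,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED annotation needs 6 columns")
    cls <- sub(":.*$", "", df[[4]])
    id <- sub("^[^:]*:", "", df[[4]])
    feats <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                        strand = ifelse(df[[6]] == ".", "*", df[[6]]),
                        feature_class = cls, feature_id = id,
                        stringsAsFactors = FALSE)
  }
  feats$strand[feats$strand == ""] <- "*"
  validate_intervals(feats, chrom_sizes)
  unknown <- setdiff(unique(feats$feature_class), .known_classes)
  if (length(unknown)) {
    warning("unknown feature class(es) kept verbatim: ",
            paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(feats$feature_id)) {
    feats$feature_id <- make.unique(feats$feature_id, sep = "_")
  }
  feats
}

#' Write annotation features as GFF3
#' @param features feature data frame (chrom, start, end, strand,
#'   feature_class, feature_id).
#' @param path output path.
#' @export
write_annotation <- function(features, path) {
  validate_intervals(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  gr$type <- features$feature_class
  gr$ID <- features$feature_id
  gr$Name <- features$feature_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# --- RAP peaks (BED6 + stats sidecar) -------------------------------------

#' Write called RAP peaks as BED6 (plus optional statistics sidecar)
#'
#' The BED score column carries `support_reads`; the remaining per-peak
#' statistics go to a TSV sidecar when `stats_path` is given.
#'
#' @param peaks RAP peak data frame from [call_raps()].
#' @param path BED6 output path.
#' @param stats_path optional TSV with the full per-peak statistics.
#' @export
write_raps <- function(peaks, path, stats_path = NULL) {
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    peaks$support_reads %||% 0L,
                    ifelse(peaks$strand == "*", ".", peaks$strand))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(stats_path)) {
    utils::write.table(peaks, stats_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read RAP peaks from BED6 (plus optional statistics sidecar)
#' @param path BED6 file written by [write_raps()].
#' @param stats_path optional statistics sidecar; when given, the full peak
#'   table is restored.
#' @return RAP peak data frame.
#' @export
read_raps <- function(path, stats_path = NULL) {
  if (!is.null(stats_path)) {
    df <- utils::read.table(stats_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    return(df)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
             strand = ifelse(df[[6]] == ".", "*", df[[6]]),
             name = df[[4]], support_reads = df[[5]],
             stringsAsFactors = FALSE)
}

# --- bedGraph coverage tracks ---------------------------------------------

read_one_bedgraph <- function(path, chrom_sizes) {
  out <- lapply(chrom_sizes, numeric)
  if (file.size(path) == 0) return(out)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  if (any(df$value < 0)) stop("negative bedGraph value")
  validate_intervals(cbind(df[c("chrom", "start", "end")], strand = "*"),
                     chrom_sizes)
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping bedGraph intervals on ", ch)
    }
    v <- out[[ch]]
    for (i in seq_len(nrow(d))) {
      v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    }
    out[[ch]] <- v
  }
  out
}

#' Read a strand-specific bedGraph pair into a coverage track
#'
#' Runs of zero may be omitted in the files and are re-densified to 0.
#'
#' @param path_plus,path_minus bedGraph files for the + and - strand.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param signal_kind stored on the returned track.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path_plus, path_minus, chrom_sizes,
                          signal_kind = "read_end_counts") {
  track <- coverage_track(chrom_sizes, strands = c("+", "-"),
                          signal_kind = signal_kind)
  plus <- read_one_bedgraph(path_plus, chrom_sizes)
  minus <- read_one_bedgraph(path_minus, chrom_sizes)
  for (ch in names(chrom_sizes)) {
    track$data[[ch]][["+"]] <- plus[[ch]]
    track$data[[ch]][["-"]] <- minus[[ch]]
  }
  track
}

write_one_bedgraph <- function(vectors, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(vectors)) {
    v <- vectors[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         format(r$values[keep], trim = TRUE, digits = 15)),
                 con)
    }
  }
  invisible(path)
}

#' Write a coverage track as a strand-specific bedGraph pair
#'
#' Zero runs are omitted.  For unstranded tracks the single track is written
#' to `path_plus` and `path_minus` is left empty.
#'
#' @param track a [coverage_track()].
#' @param path_plus,path_minus output paths.
#' @export
write_bedgraph <- function(track, path_plus, path_minus) {
  get_strand <- function(s) {
    lapply(track$data, function(ch) ch[[s]] %||% ch[["*"]] %||% numeric(0))
  }
  if ("*" %in% track$strands) {
    write_one_bedgraph(get_strand("*"), path_plus)
    file.create(path_minus)
  } else {
    write_one_bedgraph(get_strand("+"), path_plus)
    write_one_bedgraph(get_strand("-"), path_minus)
  }
  invisible(c(path_plus, path_minus))
}

# --- expression ------------------------------------------------------------

#' Read a gene expression table (gene_id, TPM)
#' @param path TSV with columns gene_id and tpm (header optional).
#' @return data frame with columns gene_id, tpm.
#' @export
read_expression <- function(path) {
  first <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  df <- df[, 1:2]
  names(df) <- c("gene_id", "tpm")
  df$tpm <- as.numeric(df$tpm)
  if (any(is.na(df$tpm)) || any(df$tpm < 0)) stop("invalid TPM value")
  df
}

#' Write a gene expression table
#' @param expression data frame with columns gene_id, tpm.
#' @param path output TSV path.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression[c("gene_id", "tpm")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# --- simulation truth sidecar ---------------------------------------------

#' Write planted simulation truth as JSON
#' @param truth truth object (list/data frame) from the simulators.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a planted-truth JSON sidecar
#' @param path JSON written by [write_truth()].
#' @return the truth object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(x) && !is.null(x$raps)) x$raps <- as.data.frame(x$raps)
  x
}
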