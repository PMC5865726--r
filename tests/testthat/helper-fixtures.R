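# Small in-code fixtures shared by the tests.

# single-chromosome coverage track from a plain vector
make_track <- function(values, strand = "+", chrom = "chrT",
                       kind = "fragment_coverage") {
  tr <- coverage_track(stats::setNames(length(values), chrom),
                       strands = strand, signal_kind = kind)
  tr$data[[chrom]][[strand]] <- as.numeric(values)
  tr
}

# two-strand read-end track over the given chromosome sizes
make_occ_track <- function(chrom_sizes, plus = list(), minus = list()) {
  tr <- coverage_track(chrom_sizes, strands = c("+", "-"),
                       signal_kind = "read_end_counts")
  for (ch in names(plus)) tr$data[[ch]][["+"]] <- plus[[ch]]
  for (ch in names(minus)) tr$data[[ch]][["-"]] <- minus[[ch]]
  tr
}

# hand-built annotation: three genes and a couple of small features
tiny_features <- function() {
  data.frame(
    chrom = c("chrI", "chrI", "chrI", "chrI", "chrI"),
    start = c(1000L, 4000L, 7000L, 2900L, 2950L),
    end = c(2500L, 5500L, 8800L, 3000L, 2990L),
    strand = c("+", "-", "+", "+", "+"),
    feature_class = c("ORF", "ORF", "ORF", "tRNA", "snoRNA"),
    feature_id = c("G1", "G2", "G3", "T1", "S1"),
    stringsAsFactors = FALSE
  )
}

tiny_sizes <- c(chrI = 10000)

# one-row data frame helpers
rap_row <- function(chrom, start, end, strand, name = "R1", ...) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             name = name, ..., stringsAsFactors = FALSE)
}

gene_row <- function(chrom, start, end, strand, id = "G") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             feature_class = "ORF", feature_id = id, stringsAsFactors = FALSE)
}
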