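# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's interval machinery: correctness is defined on explicit
# per-base sets.

# union of half-open intervals as a logical base vector, read back as runs
oracle_merge <- function(start, end, limit = max(end) + 1L) {
  covered <- logical(limit)
  for (i in seq_along(start))
    if (end[i] > start[i]) covered[(start[i] + 1L):end[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths
  data.frame(start = starts[r$values], end = stops[r$values])
}

# classify each 5'-end position against a locus by explicit base membership
oracle_count <- function(pos, span_start, span_end, exon_start, exon_end) {
  in_locus <- pos >= span_start & pos < span_end
  in_exon <- vapply(pos, function(p)
    any(p >= exon_start & p < exon_end), TRUE)
  c(locus = sum(in_locus),
    exonic = sum(in_locus & in_exon),
    intronic = sum(in_locus & !in_exon))
}

random_interval_set <- function(n, coord_max = 1e4, max_len = 500) {
  s <- sample.int(coord_max - 2L, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  e <- pmin(s + len, coord_max)
  keep <- e > s
  list(start = s[keep], end = e[keep])
}

oracle_as_intervals <- function(df) {
  intervals(df$start, df$end)
}

empty_iv <- function() intervals(integer(0), integer(0))

# minimal GTF text for ad-hoc parsing tests
gtf_line <- function(chrom = "chr1", feature = "exon", start = 101,
                     end = 200, strand = "+",
                     attrs = 'gene_id "G1"; transcript_id "G1.T1";') {
  paste(chrom, "src", feature, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

write_gtf_lines <- function(lines) {
  p <- tempfile(fileext = ".gtf")
  writeLines(lines, p)
  p
}

# two-exon locus used across counting tests
toy_locus <- function(span = c(0L, 1000L), exons = cbind(c(0L, 600L),
                                                         c(400L, 1000L)),
                      strand = "+", chrom = "chr1", gene_id = "G1") {
  build_gene_locus(
    intervals(exons[, 1L], exons[, 2L], chrom = chrom, strand = strand),
    gene_id = gene_id)
}
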