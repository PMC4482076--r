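test_that("parse_gtf converts GTF 1-based inclusive to 0-based half-open", {
  p <- write_gtf_lines(gtf_line(start = 101, end = 200))
  ex <- parse_gtf(p)
  expect_equal(ex$start, 100L)
  expect_equal(ex$end, 200L)
  expect_equal(ex$biotype, "unknown")
})

test_that("parse_gtf groups transcripts by gene and keeps biotype labels", {
  p <- write_gtf_lines(c(
    gtf_line(start = 101, end = 200,
             attrs = 'gene_id "G1"; transcript_id "G1.T1"; transcript_biotype "protein_coding";'),
    gtf_line(start = 301, end = 400,
             attrs = 'gene_id "G1"; transcript_id "G1.T2"; transcript_biotype "protein_coding";'),
    gtf_line(chrom = "chr2", start = 51, end = 70,
             attrs = 'gene_id "G2"; transcript_id "G2.T1";'),
    gtf_line(feature = "CDS", start = 1, end = 10,
             attrs = 'gene_id "G9"; transcript_id "G9.T1";')))
  ex <- parse_gtf(p)
  expect_setequal(unique(ex$gene_id), c("G1", "G2"))  # CDS line ignored
  grp <- transcripts_by_gene(ex)
  expect_length(grp[["G1"]], 2L)
  expect_equal(grp[["G1"]][["G1.T1"]]$biotype, "protein_coding")
  expect_equal(grp[["G2"]][["G2.T1"]]$biotype, "unknown")
})

test_that("parse_gtf errors name the offending line", {
  p <- write_gtf_lines(c(
    gtf_line(),
    gtf_line(attrs = 'gene_id "G2";')))  # no transcript_id
  expect_error(parse_gtf(p), "line 2.*transcript_id")
  p2 <- write_gtf_lines(c(gtf_line(), gtf_line(start = 50, end = 10)))
  expect_error(parse_gtf(p2), "line 2")
  expect_error(parse_gtf(tempfile()), "cannot read")
})

test_that("parse_gtf agrees with rtracklayer on a fixture", {
  skip_if_not_installed("rtracklayer")
  p <- write_gtf_lines(c(
    gtf_line(start = 101, end = 200),
    gtf_line(start = 301, end = 450, strand = "-",
             attrs = 'gene_id "G2"; transcript_id "G2.T1";')))
  ex <- parse_gtf(p)
  ref <- rtracklayer::import(p)
  expect_equal(ex$start + 1L, GenomicRanges::start(ref))
  expect_equal(ex$end, GenomicRanges::end(ref))
  expect_equal(ex$gene_id, ref$gene_id)
})

test_that("merge_intervals merges overlap and distance-0 abutment", {
  m <- merge_intervals(intervals(c(10, 40, 90), c(50, 80, 100)))
  expect_equal(m[, c("start", "end")],
               data.frame(start = c(10L, 90L), end = c(80L, 100L)))
  # abutting half-open intervals are one contiguous base set
  ab <- merge_intervals(intervals(c(10, 50), c(50, 80)))
  expect_equal(ab[, c("start", "end")], data.frame(start = 10L, end = 80L))
  expect_equal(ab, oracle_as_intervals(oracle_merge(c(10L, 50L), c(50L, 80L))))
  expect_equal(nrow(merge_intervals(empty_iv())), 0L)
  expect_error(merge_intervals(intervals(c(1, 1), c(5, 5),
                                         chrom = c("chr1", "chr2"))),
               "single chromosome")
})

test_that("merge_intervals is idempotent and matches the per-base oracle", {
  set.seed(11)
  for (i in 1:50) {
    iv <- random_interval_set(sample(1:20, 1))
    m <- merge_intervals(intervals(iv$start, iv$end))
    expect_equal(m[, c("start", "end")],
                 oracle_merge(iv$start, iv$end),
                 ignore_attr = TRUE)
    expect_equal(merge_intervals(m), m)
  }
})

test_that("build_gene_locus derives span, super-exons and introns", {
  l <- build_gene_locus(intervals(c(100, 300), c(200, 400), chrom = "chr1",
                                  strand = "+"), gene_id = "G1")
  expect_equal(unname(l$span), c(100L, 400L))
  expect_equal(l$introns[, c("start", "end")],
               data.frame(start = 200L, end = 300L))
  # overlapping transcripts collapse to a single super-exon, no introns
  l2 <- build_gene_locus(intervals(c(0, 200, 50), c(100, 300, 250)),
                         gene_id = "G2")
  expect_equal(l2$super_exons[, c("start", "end")],
               data.frame(start = 0L, end = 300L))
  expect_equal(l2$super_exons[, c("start", "end")],
               oracle_merge(c(0L, 200L, 50L), c(100L, 300L, 250L)),
               ignore_attr = TRUE)
  expect_equal(nrow(l2$introns), 0L)
  # single-exon gene
  expect_equal(nrow(build_gene_locus(intervals(5, 50),
                                     gene_id = "G3")$introns), 0L)
})

test_that("locus base conservation and input-order invariance hold", {
  set.seed(42)
  for (i in 1:30) {
    iv <- random_interval_set(sample(2:15, 1))
    l <- build_gene_locus(intervals(iv$start, iv$end), gene_id = "g")
    expect_equal(sum(l$super_exons$end - l$super_exons$start) +
                   sum(l$introns$end - l$introns$start),
                 l$span[["end"]] - l$span[["start"]])
    perm <- sample(length(iv$start))
    l2 <- build_gene_locus(intervals(iv$start[perm], iv$end[perm]),
                           gene_id = "g")
    expect_equal(l2, l)
    expect_equal(l$super_exons$start[1L], l$span[["start"]])
    expect_equal(l$super_exons$end[nrow(l$super_exons)], l$span[["end"]])
  }
})

test_that("a gene spanning chromosomes is rejected unless told otherwise", {
  ex <- intervals(c(0, 0, 100), c(50, 60, 400),
                  chrom = c("chr1", "chr2", "chr2"))
  expect_error(build_gene_locus(ex, gene_id = "GX"), "GX")
  l <- build_gene_locus(ex, gene_id = "GX", multi_chrom = "largest")
  expect_equal(l$chrom, "chr2")
  expect_equal(unname(l$span), c(0L, 400L))
})

test_that("locus BED export writes 0-based half-open records per gene", {
  loci <- list(G1 = toy_locus())
  pe <- tempfile(fileext = ".bed"); pi <- tempfile(fileext = ".bed")
  write_locus_bed(loci, pe, pi)
  exon_bed <- read.table(pe, sep = "\t")
  expect_equal(exon_bed$V2, c(0L, 600L))
  expect_equal(exon_bed$V3, c(400L, 1000L))
  expect_equal(unique(exon_bed$V4), "G1")
  intron_bed <- read.table(pi, sep = "\t")
  expect_equal(intron_bed[, 2:3], data.frame(V2 = 400L, V3 = 600L))
})
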