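test_that("the 5' end is the leftmost base on +, rightmost on -", {
  expect_equal(five_prime_end(1000, 1075, "+"), 1000L)
  expect_equal(five_prime_end(1000, 1075, "-"), 1074L)
  expect_equal(five_prime_end(0, 1, "+"), 0L)
  expect_equal(five_prime_end(10, 20, "*"), 10L)
  expect_error(five_prime_end(5, 5, "+"), "start < end")
})

test_that("ends are counted half-open against locus and super-exons", {
  locus <- toy_locus(exons = cbind(c(0L, 600L), c(400L, 1000L)))
  ends <- data.frame(chrom = "chr1", pos = c(100L, 500L, 700L), strand = "+")
  cnt <- count_ends_for_gene(ends, locus)
  expect_equal(cnt$locus_count, 3L)
  expect_equal(cnt$exonic_count, 2L)
  expect_equal(cnt$intronic_count, 1L)
  # span end itself is outside under half-open coordinates
  cnt2 <- count_ends_for_gene(
    data.frame(chrom = "chr1", pos = c(999L, 1000L), strand = "+"), locus)
  expect_equal(cnt2$locus_count, 1L)
  # empty end list gives all zeros
  cnt0 <- count_ends_for_gene(
    data.frame(chrom = character(0), pos = integer(0),
               strand = character(0)), locus)
  expect_equal(unlist(cnt0[, 2:4], use.names = FALSE), c(0L, 0L, 0L))
})

test_that("counting matches the per-base membership oracle on random loci", {
  set.seed(99)
  for (i in 1:25) {
    n_ex <- sample(1:4, 1)
    st <- sort(sample(seq(0, 4000, by = 120), n_ex))
    en <- st + sample(20:100, n_ex, replace = TRUE)
    locus <- build_gene_locus(intervals(st, en, chrom = "c"), gene_id = "g")
    pos <- sample.int(5000L, 200L, replace = TRUE) - 1L
    cnt <- count_ends_for_gene(data.frame(chrom = "c", pos = pos,
                                          strand = "+"), locus)
    orc <- oracle_count(pos, locus$span[["start"]], locus$span[["end"]],
                        locus$super_exons$start, locus$super_exons$end)
    expect_equal(cnt$locus_count, unname(orc["locus"]))
    expect_equal(cnt$exonic_count, unname(orc["exonic"]))
    expect_equal(cnt$intronic_count, unname(orc["intronic"]))
    expect_equal(cnt$exonic_count + cnt$intronic_count, cnt$locus_count)
  }
})

test_that("counting is additive over end-list concatenation", {
  locus <- toy_locus()
  set.seed(5)
  e1 <- data.frame(chrom = "chr1", pos = sample.int(1200L, 80L) - 1L,
                   strand = "+")
  e2 <- data.frame(chrom = "chr1", pos = sample.int(1200L, 60L) - 1L,
                   strand = "-")
  c1 <- count_ends_for_gene(e1, locus)
  c2 <- count_ends_for_gene(e2, locus)
  c12 <- count_ends_for_gene(rbind(e1, e2), locus)
  for (col in c("locus_count", "exonic_count", "intronic_count"))
    expect_equal(c12[[col]], c1[[col]] + c2[[col]])
})

test_that("strict strand mode counts only orientation-matched ends", {
  locus <- toy_locus(strand = "+")
  ends <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     strand = c("+", "-", "*"))
  expect_equal(count_ends_for_gene(ends, locus)$locus_count, 3L)
  # unstranded ends match either orientation in strict mode
  expect_equal(count_ends_for_gene(ends, locus,
                                   strand_mode = "match")$locus_count, 2L)
})

test_that("count_all emits explicit zeros and multi-counts overlapping loci", {
  lociA <- toy_locus(gene_id = "GA")
  lociB <- build_gene_locus(intervals(c(200L, 900L), c(700L, 1200L),
                                      chrom = "chr1", strand = "-"),
                            gene_id = "GB")
  loci <- list(GA = lociA, GB = lociB)
  design <- sim_design()
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  aln <- setNames(rep(list(empty), 6), design$sample_id)
  z <- count_all(aln, loci, design)
  expect_equal(nrow(z), 12L)
  expect_true(all(z$locus_count == 0L))
  # an end inside both loci increments both genes
  one <- data.frame(chrom = "chr1", start = 300L, end = 375L, strand = "+")
  aln$cwc22_kd_1 <- one
  z2 <- count_all(aln, loci, design)
  hit <- z2[z2$sample_id == "cwc22_kd_1", ]
  expect_equal(hit$locus_count, c(1L, 1L))
  # design sample without an alignment source is a configuration error
  expect_error(count_all(aln[-1], loci, design), "configuration error")
})

test_that("ends on chromosomes absent from the annotation are tallied", {
  loci <- list(G1 = toy_locus())
  design <- sim_design()[1:2, ]
  aln <- list(
    cwc22_kd_1 = data.frame(chrom = c("chr1", "chrUn"), start = c(10L, 10L),
                            end = c(85L, 85L), strand = "+"),
    cwc22_kd_2 = data.frame(chrom = "chr1", start = 20L, end = 95L,
                            strand = "+"))
  expect_message(cnt <- count_all(aln, loci, design), "unassigned")
  expect_equal(attr(cnt, "unassigned"),
               c(cwc22_kd_1 = 1L, cwc22_kd_2 = 0L))
  expect_equal(cnt$locus_count, c(1L, 1L))
})

test_that("SAM input skips flagged records and honors first-mate mode", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:2000",
    # mapped first mate, plus strand, pos 101 (1-based), 75M
    "r1\t99\tchr1\t101\t60\t75M\t=\t301\t275\t*\t*",
    # its second mate, minus strand
    "r1\t147\tchr1\t301\t60\t75M\t=\t101\t-275\t*\t*",
    # unmapped record: must be skipped
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    # secondary alignment: must be skipped
    "r3\t256\tchr1\t501\t0\t75M\t*\t0\t0\t*\t*",
    # unpaired mapped read with a spliced CIGAR (ref width 30+100+45)
    "r4\t0\tchr1\t701\t60\t30M100N45M\t*\t0\t0\t*\t*"), sam)
  aln <- read_alignments(sam)
  expect_equal(nrow(aln), 3L)
  expect_equal(aln$start, c(100L, 300L, 700L))
  expect_equal(aln$end, c(175L, 375L, 875L))  # N gap spans the reference
  expect_equal(aln$strand, c("+", "-", "+"))
  first <- read_alignments(sam, mate_mode = "first")
  expect_equal(nrow(first), 2L)  # second mate dropped, unpaired kept
  expect_equal(first$start, c(100L, 700L))
  # 5' ends: minus-strand mate ends at its rightmost base
  ends <- ends_from_alignments(aln)
  expect_equal(ends$pos, c(100L, 374L, 700L))
})
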