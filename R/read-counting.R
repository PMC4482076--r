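#' 5' end position of an alignment
#'
#' The 5' end is the first transcribed base of the aligned read: the leftmost
#' aligned base for plus-strand (or unstranded) alignments and the rightmost
#' aligned base for minus-strand alignments. Positions are 0-based.
#'
#' @param start,end Alignment span, 0-based half-open; vectorized.
#' @param strand `"+"`, `"-"` or `"*"`; recycled.
#' @return Integer vector of 0-based 5'-end positions.
#' @examples
#' five_prime_end(1000, 1075, "+") # 1000
#' five_prime_end(1000, 1075, "-") # 1074
#' @export
five_prime_end <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end) | end <= start | start < 0L))
    stop("alignments must satisfy 0 <= start < end")
  strand <- rep_len(as.character(strand), length(start))
  ifelse(strand == "-", end - 1L, start)
}

#' Read alignments from BED6 or SAM/BAM
#'
#' BED input is taken at face value: one record per aligned mate, 0-based
#' half-open, strand in column 6. SAM/BAM input is read through Rsamtools;
#' unmapped, secondary and supplementary records are skipped, and the
#' reference span is derived from the CIGAR string.
#'
#' @param path Path to a `.bed`, `.sam` or `.bam` file.
#' @param mate_mode `"all"` counts every aligned mate; `"first"` keeps only
#'   first mates (and unpaired reads) for fragment-level counting. Only
#'   meaningful for SAM/BAM input, where mate flags exist.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_alignments <- function(path, mate_mode = c("all", "first")) {
  mate_mode <- match.arg(mate_mode)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") return(read_bed6(path))
  if (!ext %in% c("sam", "bam"))
    stop("unsupported alignment format '", ext, "' (use BED6, SAM or BAM)")
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("SAM/BAM input requires the Rsamtools and GenomicAlignments packages")
  bam <- path
  if (ext == "sam")
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "pos", "cigar", "strand", "flag"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  keep <- rep(TRUE, length(rec$pos))
  if (mate_mode == "first") {
    paired <- bitwAnd(rec$flag, 1L) > 0L
    first <- bitwAnd(rec$flag, 64L) > 0L
    keep <- !paired | first
  }
  rwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[keep])
  data.frame(chrom = as.character(rec$rname[keep]),
             start = rec$pos[keep] - 1L,
             end = rec$pos[keep] - 1L + rwidth,
             strand = as.character(rec$strand[keep]),
             stringsAsFactors = FALSE)
}

read_bed6 <- function(path) {
  bed <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                           colClasses = c("character", "integer", "integer",
                                          "character", "character", "character"),
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  bed[, c("chrom", "start", "end", "strand")]
}

#' Reduce alignments to 5'-end positions
#'
#' @param aln Alignment data frame (`chrom`, `start`, `end`, `strand`), e.g.
#'   from [read_alignments()].
#' @return Data frame with columns `chrom`, `pos` (0-based 5'-end position)
#'   and `strand`.
#' @export
ends_from_alignments <- function(aln) {
  data.frame(chrom = aln$chrom,
             pos = five_prime_end(aln$start, aln$end, aln$strand),
             strand = aln$strand, stringsAsFactors = FALSE)
}

# shared counting engine: read 5' ends vs a list of gene loci.
# Returns one row per locus: locus/exonic/intronic counts.
count_ends_batch <- function(ends, loci, strand_mode = c("ignore", "match")) {
  strand_mode <- match.arg(strand_mode)
  gene_ids <- vapply(loci, `[[`, "", "gene_id")
  if (nrow(ends) == 0L) {
    return(data.frame(gene_id = gene_ids, locus_count = 0L,
                      exonic_count = 0L, intronic_count = 0L,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  chroms <- sort(unique(c(ends$chrom,
                          vapply(loci, `[[`, "", "chrom"))))
  end_strand <- ends$strand
  end_strand[!end_strand %in% c("+", "-")] <- "*"
  pts <- GenomicRanges::GRanges(
    seqnames = factor(ends$chrom, levels = chroms),
    ranges = IRanges::IRanges(start = ends$pos + 1L, width = 1L),
    strand = end_strand)
  spans <- GenomicRanges::GRanges(
    seqnames = factor(vapply(loci, `[[`, "", "chrom"), levels = chroms),
    ranges = IRanges::IRanges(
      start = vapply(loci, function(l) l$span[["start"]], 0L) + 1L,
      end = vapply(loci, function(l) l$span[["end"]], 0L)),
    strand = vapply(loci, `[[`, "", "strand"))
  ignore <- strand_mode == "ignore"
  locus_count <- GenomicRanges::countOverlaps(spans, pts, ignore.strand = ignore)

  n_ex <- vapply(loci, function(l) nrow(l$super_exons), 0L)
  ex_gene <- rep(seq_along(loci), n_ex)
  ex <- do.call(rbind, lapply(loci, `[[`, "super_exons"))
  exgr <- GenomicRanges::GRanges(
    seqnames = factor(ex$chrom, levels = chroms),
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = vapply(loci, `[[`, "", "strand")[ex_gene])
  per_exon <- GenomicRanges::countOverlaps(exgr, pts, ignore.strand = ignore)
  exonic_count <- as.integer(rowsum(per_exon, ex_gene,
                                    reorder = FALSE)[, 1L])
  data.frame(gene_id = gene_ids,
             locus_count = as.integer(locus_count),
             exonic_count = exonic_count,
             intronic_count = as.integer(locus_count) - exonic_count,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count read 5' ends for one gene locus
#'
#' Counts how many 5'-end positions fall inside the gene locus span
#' (`locus_count`), how many of those fall inside a super-exon
#' (`exonic_count`), and the remainder (`intronic_count`). Boundaries are
#' half-open: a position equal to the span end is outside. By default the
#' read strand is ignored; `strand_mode = "match"` counts only ends whose
#' strand matches the gene strand (unstranded ends match either).
#'
#' @param ends Data frame of 5' ends (`chrom`, `pos`, optionally `strand`),
#'   see [ends_from_alignments()].
#' @param locus A `gene_locus` object.
#' @param strand_mode `"ignore"` (default) or `"match"`.
#' @return One-row data frame: `gene_id`, `locus_count`, `exonic_count`,
#'   `intronic_count`.
#' @export
count_ends_for_gene <- function(ends, locus,
                                strand_mode = c("ignore", "match")) {
  if (!"strand" %in% names(ends)) ends$strand <- "*"
  count_ends_batch(ends, list(locus), strand_mode = strand_mode)
}

#' Count read 5' ends per gene locus across all samples of a design
#'
#' Batch driver over an experimental design: every sample's alignments are
#' reduced to 5' ends and counted against every gene locus, producing one
#' count row per (gene, sample) pair, with explicit zeros. An end whose
#' position falls in several (overlapping) gene loci contributes to each;
#' ends on chromosomes absent from the annotation are tallied per sample in
#' the `"unassigned"` attribute and reported via a message.
#'
#' @param alignments Named list (by `sample_id`) of alignment file paths
#'   (BED6/SAM/BAM) or alignment data frames (`chrom`, `start`, `end`,
#'   `strand`).
#' @param loci List of `gene_locus` objects, e.g. [build_gene_loci()].
#' @param design Design data frame with columns `sample_id`, `condition`,
#'   `replicate`.
#' @param mate_mode,strand_mode See [read_alignments()] and
#'   [count_ends_for_gene()].
#' @return Data frame `gene_id`, `sample_id`, `locus_count`, `exonic_count`,
#'   `intronic_count` (genes nested within samples, design order), with an
#'   `"unassigned"` attribute naming per-sample out-of-annotation end counts.
#' @export
count_all <- function(alignments, loci, design,
                      mate_mode = c("all", "first"),
                      strand_mode = c("ignore", "match")) {
  mate_mode <- match.arg(mate_mode)
  strand_mode <- match.arg(strand_mode)
  missing <- setdiff(design$sample_id, names(alignments))
  if (length(missing))
    stop("configuration error: no alignment source for sample(s) ",
         paste(missing, collapse = ", "))
  ann_chroms <- unique(vapply(loci, `[[`, "", "chrom"))
  unassigned <- integer(0)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    src <- alignments[[sid]]
    aln <- if (is.character(src)) read_alignments(src, mate_mode) else src
    ends <- ends_from_alignments(aln)
    off <- !(ends$chrom %in% ann_chroms)
    unassigned[sid] <- sum(off)
    cnt <- count_ends_batch(ends[!off, , drop = FALSE], loci, strand_mode)
    cnt$sample_id <- sid
    out[[i]] <- cnt[, c("gene_id", "sample_id", "locus_count",
                        "exonic_count", "intronic_count")]
  }
  if (any(unassigned > 0L))
    message("unassigned 5' ends (chromosome absent from annotation): ",
            paste(names(unassigned)[unassigned > 0L],
                  unassigned[unassigned > 0L],
                  sep = "=", collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "unassigned") <- unassigned
  res
}
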