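#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames in 0-based half-open (BED) convention:
#' `start` is the first covered base, `end` is one past the last. All interval
#' arithmetic in the package uses this convention; GTF input is converted at
#' the parsing boundary.
#'
#' @param start,end Integer vectors; must satisfy `0 <= start < end`.
#' @param chrom Chromosome name(s); recycled.
#' @param strand Strand label(s), one of `"+"`, `"-"`, `"*"`; recycled.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' intervals(c(10, 40), c(50, 80))
#' @export
intervals <- function(start, end, chrom = "chr", strand = "*") {
  n <- length(start)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

empty_intervals <- function(chrom = character(0)) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$chrom) || any(!nzchar(x$chrom)))
    stop("interval chromosome names must be non-empty")
  bad <- which(is.na(x$start) | is.na(x$end) |
                 x$start < 0L | x$end <= x$start)
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(bad, collapse = ", "),
         ": need 0 <= start < end")
  invisible(x)
}

#' Merge overlapping or abutting intervals on one chromosome
#'
#' Collapses a set of intervals into the minimal sorted, pairwise disjoint,
#' non-abutting set covering exactly the same bases. Abutting intervals
#' (`end` of one equals `start` of the next under half-open coordinates) are
#' merged, matching the distance-0 default of the standard interval-merging
#' tools. This is the operation that turns a gene's exons into super-exons.
#'
#' @param x Interval data frame (see [intervals()]); all rows must share one
#'   chromosome.
#' @return A sorted, disjoint interval data frame covering the same base set.
#' @examples
#' merge_intervals(intervals(c(10, 40, 90), c(50, 80, 100)))
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0L) return(empty_intervals())
  chroms <- unique(x$chrom)
  if (length(chroms) > 1L)
    stop("merge_intervals() requires intervals on a single chromosome, got: ",
         paste(chroms, collapse = ", "))
  strand <- if ("strand" %in% names(x)) x$strand[1L] else "*"
  red <- IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end))
  intervals(start = IRanges::start(red) - 1L, end = IRanges::end(red),
            chrom = chroms, strand = strand)
}

# gaps between consecutive members of a sorted disjoint interval set,
# restricted to [span_start, span_end)
interval_gaps <- function(merged, span_start, span_end) {
  if (nrow(merged) < 2L) return(empty_intervals())
  gs <- merged$end[-nrow(merged)]
  ge <- merged$start[-1L]
  keep <- gs < ge & gs >= span_start & ge <= span_end
  if (!any(keep)) return(empty_intervals())
  intervals(start = gs[keep], end = ge[keep],
            chrom = merged$chrom[1L], strand = merged$strand[1L])
}
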