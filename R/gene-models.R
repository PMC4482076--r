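#' Parse exon features from a GTF annotation
#'
#' Reads `exon` features from a GTF file and returns them as one exon table.
#' GTF coordinates (1-based, end-inclusive) are converted to the package's
#' internal 0-based half-open convention at this boundary. The transcript
#' biotype is taken from the first of the `transcript_biotype`, `gene_biotype`
#' or `biotype` attributes present; records carrying none get `"unknown"`.
#'
#' @param path Path to a GTF file (plain text; tab-delimited, attribute
#'   column as `key "value";` pairs).
#' @return A data frame with one row per exon record and columns `gene_id`,
#'   `transcript_id`, `biotype`, `chrom`, `start`, `end`, `strand`
#'   (coordinates 0-based half-open).
#' @seealso [transcripts_by_gene()] to regroup the table into per-gene
#'   transcript lists, [build_gene_loci()] to derive super-exons and introns.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      biotype = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop("GTF parse error at line ", lineno[which(nf < 9L)[1L]],
         ": fewer than 9 tab-delimited columns")
  feat <- vapply(fields, `[`, "", 3L)
  is_exon <- feat == "exon"
  fields <- fields[is_exon]
  lineno <- lineno[is_exon]
  if (length(fields) == 0L) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      biotype = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  strand <- vapply(fields, `[`, "", 7L)
  attrs <- vapply(fields, `[`, "", 9L)

  bad <- which(is.na(start1) | is.na(end1) | end1 < start1 | start1 < 1L)
  if (length(bad))
    stop("GTF parse error at line ", lineno[bad[1L]],
         ": invalid exon coordinates")

  gene_id <- gtf_attribute(attrs, "gene_id")
  transcript_id <- gtf_attribute(attrs, "transcript_id")
  for (key in c("gene_id", "transcript_id")) {
    val <- if (key == "gene_id") gene_id else transcript_id
    if (anyNA(val))
      stop("GTF parse error at line ", lineno[which(is.na(val))[1L]],
           ": exon record lacks mandatory attribute ", key)
  }
  biotype <- gtf_attribute(attrs, "transcript_biotype")
  gb <- gtf_attribute(attrs, "gene_biotype")
  biotype[is.na(biotype)] <- gb[is.na(biotype)]
  bb <- gtf_attribute(attrs, "biotype")
  biotype[is.na(biotype)] <- bb[is.na(biotype)]
  biotype[is.na(biotype)] <- "unknown"

  strand[!strand %in% c("+", "-")] <- "*"
  data.frame(gene_id = gene_id, transcript_id = transcript_id,
             biotype = biotype, chrom = chrom,
             start = start1 - 1L, end = end1, strand = strand,
             stringsAsFactors = FALSE)
}

gtf_attribute <- function(attrs, key) {
  pat <- paste0('(^|; ?)', key, ' +"([^"]*)"')
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m),
         function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
}

#' Group an exon table into per-gene transcript lists
#'
#' @param exons Exon table from [parse_gtf()].
#' @return A named list (one element per `gene_id`) of transcript lists; each
#'   transcript is a list with `transcript_id`, `gene_id`, `biotype` and an
#'   `exons` interval data frame sorted by start.
#' @export
transcripts_by_gene <- function(exons) {
  out <- lapply(split(exons, exons$gene_id), function(g) {
    lapply(split(g, g$transcript_id), function(t) {
      t <- t[order(t$start), , drop = FALSE]
      list(transcript_id = t$transcript_id[1L], gene_id = t$gene_id[1L],
           biotype = t$biotype[1L],
           exons = intervals(t$start, t$end, chrom = t$chrom,
                             strand = t$strand))
    })
  })
  out[unique(exons$gene_id)]
}

#' Build a gene locus with merged super-exons and derived introns
#'
#' A gene locus spans from the gene's first to its last exonic base. All exons
#' of all the gene's transcripts are merged into disjoint super-exons; the
#' introns are the gaps between consecutive super-exons inside the span, so
#' that super-exons and introns partition the span exactly.
#'
#' @param exons Exon interval data frame for a single gene (columns `chrom`,
#'   `start`, `end`, `strand`, and `gene_id` unless given separately).
#' @param gene_id Gene identifier; defaults to the table's `gene_id` column.
#' @param multi_chrom How to treat a gene_id whose exons sit on more than one
#'   chromosome or strand: `"error"` (default) rejects it, `"largest"` keeps
#'   the chromosome/strand group with the most exonic bases.
#' @return An object of class `gene_locus`: a list with `gene_id`, `chrom`,
#'   `strand`, `span` (length-2 integer vector), `super_exons` and `introns`
#'   interval data frames, and `biotype` when the input carries one.
#' @examples
#' ex <- intervals(c(100, 300), c(200, 400), chrom = "chr1", strand = "+")
#' build_gene_locus(ex, gene_id = "G1")
#' @export
build_gene_locus <- function(exons, gene_id = NULL,
                             multi_chrom = c("error", "largest")) {
  multi_chrom <- match.arg(multi_chrom)
  if (nrow(exons) == 0L) stop("cannot build a locus from zero exons")
  if (is.null(gene_id)) {
    if (!"gene_id" %in% names(exons))
      stop("gene_id must be given or present as a column")
    gene_id <- unique(exons$gene_id)
    if (length(gene_id) > 1L)
      stop("exon table mixes gene_ids: ", paste(gene_id, collapse = ", "))
  }
  grp <- paste(exons$chrom, exons$strand)
  if (length(unique(grp)) > 1L) {
    if (multi_chrom == "error")
      stop("gene_id ", gene_id,
           " has exons on multiple chromosomes/strands: ",
           paste(unique(grp), collapse = "; "))
    sizes <- tapply(exons$end - exons$start, grp, sum)
    exons <- exons[grp == names(sizes)[which.max(sizes)], , drop = FALSE]
  }
  biotype <- if ("biotype" %in% names(exons)) exons$biotype[1L] else NA_character_
  super <- merge_intervals(exons[, c("chrom", "start", "end", "strand")])
  span <- c(start = super$start[1L], end = super$end[nrow(super)])
  introns <- interval_gaps(super, span[["start"]], span[["end"]])
  structure(list(gene_id = gene_id, chrom = super$chrom[1L],
                 strand = super$strand[1L], span = span,
                 super_exons = super, introns = introns, biotype = biotype),
            class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat("<gene_locus> ", x$gene_id, "  ", x$chrom, ":", x$span[["start"]], "-",
      x$span[["end"]], " (", x$strand, ")  ",
      nrow(x$super_exons), " super-exon(s), ", nrow(x$introns),
      " intron(s)\n", sep = "")
  invisible(x)
}

#' Build loci for every gene in an exon table
#'
#' @inheritParams build_gene_locus
#' @param exons Exon table with a `gene_id` column, e.g. from [parse_gtf()].
#' @return Named list of [build_gene_locus()] objects, in order of first
#'   appearance of each `gene_id`.
#' @export
build_gene_loci <- function(exons, multi_chrom = c("error", "largest")) {
  multi_chrom <- match.arg(multi_chrom)
  ids <- unique(exons$gene_id)
  loci <- lapply(split(exons, exons$gene_id)[ids], build_gene_locus,
                 multi_chrom = multi_chrom)
  names(loci) <- ids
  loci
}

#' Write super-exons and introns of a locus set as BED6
#'
#' Coordinates are written 0-based half-open; the BED name column carries the
#' gene_id, score is 0.
#'
#' @param loci List of `gene_locus` objects.
#' @param exon_path,intron_path Output file paths (either may be `NULL` to
#'   skip that file).
#' @return Invisibly, the paths written.
#' @export
write_locus_bed <- function(loci, exon_path = NULL, intron_path = NULL) {
  bed_of <- function(field) {
    rows <- lapply(loci, function(l) {
      iv <- l[[field]]
      if (nrow(iv) == 0L) return(NULL)
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                 name = l$gene_id, score = 0L, strand = l$strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  for (target in list(list(exon_path, "super_exons"),
                    list(intron_path, "introns"))) {
    if (is.null(target[[1L]])) next
    bed <- bed_of(target[[2L]])
    if (is.null(bed)) bed <- data.frame(chrom = character(0), start = integer(0),
                                        end = integer(0), name = character(0),
                                        score = integer(0), strand = character(0))
    utils::write.table(bed, target[[1L]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(exon_path, intron_path))
}
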