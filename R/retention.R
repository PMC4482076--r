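#' Intronic-read proportion of a gene
#'
#' The proportion of intronic reads is `1 - exonic_count / locus_count`,
#' computed from 5'-end counts over the gene locus and its super-exon union.
#' A gene/sample with no locus reads has no defined proportion and yields
#' `NA`: absence of evidence is not zero retention.
#'
#' @param locus_count,exonic_count Non-negative integer vectors (recycled).
#' @return Numeric vector of proportions in `[0, 1]`, `NA` where
#'   `locus_count` is zero.
#' @examples
#' intron_proportion(100, 80) # 0.2
#' @export
intron_proportion <- function(locus_count, exonic_count) {
  if (any(exonic_count > locus_count, na.rm = TRUE))
    stop("exonic_count cannot exceed locus_count")
  # algebraically 1 - exonic/locus; the subtract-first form is exact on
  # integer counts (no floating-point residue at clean ratios)
  ifelse(locus_count > 0, (locus_count - exonic_count) / locus_count,
         NA_real_)
}

#' Filter genes on a minimum summed intronic read count
#'
#' A gene is retained when the sum of its intronic 5'-end counts over all
#' samples reaches `threshold` (default 100, a strict `>=` boundary). With
#' `per_condition = TRUE` the replicates of each condition are first averaged
#' and the per-condition means summed, for users who prefer
#' replicate-collapsed filtering.
#'
#' @param counts Count table from [count_all()].
#' @param threshold Non-negative integer; minimum summed intronic count.
#' @param per_condition Collapse replicates within condition before summing.
#' @param design Required when `per_condition = TRUE`.
#' @return Character vector of retained gene_ids (input order).
#' @export
filter_min_intronic <- function(counts, threshold = 100,
                                per_condition = FALSE, design = NULL) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("configuration error: threshold must be a single non-negative number")
  if (nrow(counts) == 0L) return(character(0))
  if (per_condition) {
    if (is.null(design)) stop("per_condition filtering needs the design table")
    cond <- design$condition[match(counts$sample_id, design$sample_id)]
    per_gc <- tapply(counts$intronic_count,
                     list(counts$gene_id, cond), mean)
    totals <- rowSums(per_gc, na.rm = TRUE)
  } else {
    totals <- tapply(counts$intronic_count, counts$gene_id, sum)
  }
  keep <- names(totals)[totals >= threshold]
  intersect(unique(counts$gene_id), keep)
}

#' Max-normalize a gene's proportions across samples
#'
#' Because exon-to-intron size ratios differ between genes, raw intronic
#' proportions are not comparable across genes; each gene's proportions are
#' therefore rescaled so that the highest value across its samples becomes 1.
#' If the maximum defined value is 0, all defined values stay 0; `NA` entries
#' (no locus reads) stay `NA`. Ties at the maximum all map to 1.
#'
#' @param x Numeric vector of one gene's per-sample proportions (may contain
#'   `NA`).
#' @return Numeric vector of the same length in `[0, 1]` (or `NA`).
#' @examples
#' normalize_per_gene(c(0.10, 0.20, 0.40, 0.10, 0.05, 0.20))
#' @export
normalize_per_gene <- function(x) {
  defined <- !is.na(x)
  if (!any(defined)) {
    warning("gene has no defined proportions; normalized values all NA")
    return(x)
  }
  m <- max(x[defined])
  if (m == 0) return(x)
  x / m
}

#' Per-gene, per-sample retention table
#'
#' Combines counting, the intronic proportion, the minimum-intronic-count
#' filter and per-gene max-normalization into the analysis's central table.
#' The filter is applied before normalization; only genes passing it receive
#' normalized proportions.
#'
#' @param counts Count table from [count_all()].
#' @param threshold,per_condition,design See [filter_min_intronic()].
#' @return Data frame `gene_id`, `sample_id`, `locus_count`, `exonic_count`,
#'   `intronic_count`, `proportion`, `normalized_proportion`,
#'   `passed_filter`.
#' @export
retention_table <- function(counts, threshold = 100, design = NULL,
                            per_condition = FALSE) {
  res <- counts[, c("gene_id", "sample_id", "locus_count", "exonic_count",
                    "intronic_count")]
  res$proportion <- intron_proportion(res$locus_count, res$exonic_count)
  retained <- filter_min_intronic(counts, threshold = threshold,
                                  per_condition = per_condition,
                                  design = design)
  res$passed_filter <- res$gene_id %in% retained
  res$normalized_proportion <- NA_real_
  for (g in retained) {
    idx <- which(res$gene_id == g)
    res$normalized_proportion[idx] <-
      suppressWarnings(normalize_per_gene(res$proportion[idx]))
  }
  res[, c("gene_id", "sample_id", "locus_count", "exonic_count",
          "intronic_count", "proportion", "normalized_proportion",
          "passed_filter")]
}

#' Summarize one sample's normalized retention distribution
#'
#' Median and 5th/95th percentiles (linear-interpolation quantiles, R type 7)
#' of the normalized proportions of the retained genes in one sample,
#' matching box-plot whiskers drawn at percentiles 5-95.
#'
#' @param values Numeric vector of normalized proportions (NA allowed;
#'   excluded, and `n_genes` counts only defined values).
#' @param sample_id Label used in output and error messages.
#' @return One-row data frame: `sample_id`, `n_genes`, `median`, `p5`, `p95`.
#' @export
summarize_sample <- function(values, sample_id = NA_character_) {
  v <- values[!is.na(values)]
  if (length(v) == 0L)
    stop("no defined normalized proportions for sample ", sample_id)
  q <- stats::quantile(v, probs = c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  data.frame(sample_id = sample_id, n_genes = length(v),
             median = q[2L], p5 = q[1L], p95 = q[3L],
             stringsAsFactors = FALSE)
}

#' Summarize every sample of a design
#'
#' @param retention Table from [retention_table()].
#' @param design Design data frame (`sample_id`, `condition`, `replicate`).
#' @return Data frame `sample_id`, `condition`, `replicate`, `n_genes`,
#'   `median`, `p5`, `p95`, one row per design sample.
#' @export
summarize_samples <- function(retention, design) {
  kept <- retention[retention$passed_filter, , drop = FALSE]
  rows <- lapply(seq_len(nrow(design)), function(i) {
    sid <- design$sample_id[i]
    s <- summarize_sample(
      kept$normalized_proportion[kept$sample_id == sid], sid)
    cbind(s[, "sample_id", drop = FALSE],
          design[i, c("condition", "replicate")],
          s[, c("n_genes", "median", "p5", "p95")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast per-condition retention medians against the control
#'
#' Averages the per-replicate medians within each condition and reports the
#' difference to the control condition, quantifying the knockdown-versus-
#' control shift of the retention distributions.
#'
#' @param summaries Output of [summarize_samples()].
#' @param control Name of the control condition (must appear in
#'   `summaries$condition`).
#' @return Data frame `condition`, `mean_median`, `delta_vs_control`
#'   (control row has delta 0).
#' @export
condition_contrast <- function(summaries, control = "control") {
  if (!control %in% summaries$condition)
    stop("configuration error: control condition '", control,
         "' absent from summaries")
  conds <- unique(summaries$condition)
  mm <- vapply(conds, function(cc)
    mean(summaries$median[summaries$condition == cc]), 0)
  data.frame(condition = conds, mean_median = mm,
             delta_vs_control = mm - mm[[match(control, conds)]],
             row.names = NULL, stringsAsFactors = FALSE)
}
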