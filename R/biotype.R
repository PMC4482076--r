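#' Per-biotype transcript-abundance change matrix
#'
#' Summarizes global abundance shifts across transcript biotypes: per
#' isoform, replicate FPKM-like values are averaged within condition, a
#' pseudocount stabilizes ratios at low abundance, and the per-isoform
#' `log2((kd + pc) / (control + pc))` values are aggregated (mean by default,
#' median optionally) within each biotype for every knockdown-versus-control
#' contrast. The aggregation rule and pseudocount are reconstructions of an
#' otherwise unstated post-processing and are exposed as parameters.
#'
#' @param abundances Data frame with columns `isoform_id`, `biotype`, then
#'   one non-negative abundance column per sample of the design.
#' @param design Design data frame (`sample_id`, `condition`, `replicate`).
#' @param control Name of the control condition.
#' @param pseudocount Positive value added to both sides of each ratio.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return Object of class `biotype_matrix`: list with `log2fc` (biotype x
#'   contrast matrix), `n_isoforms` (per biotype), and the parameters used.
#' @examples
#' design <- sim_design()
#' ab <- data.frame(isoform_id = "I1", biotype = "protein_coding",
#'                  cwc22_kd_1 = 3.9, cwc22_kd_2 = 3.9,
#'                  eif4a3_kd_1 = 0.9, eif4a3_kd_2 = 0.9,
#'                  control_1 = 0.9, control_2 = 0.9)
#' biotype_change_matrix(ab, design)$log2fc
#' @export
biotype_change_matrix <- function(abundances, design, control = "control",
                                  pseudocount = 0.1,
                                  aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (!control %in% design$condition)
    stop("configuration error: control condition '", control,
         "' absent from design")
  miss <- setdiff(design$sample_id, names(abundances))
  if (length(miss))
    stop("abundance table lacks sample column(s): ",
         paste(miss, collapse = ", "))
  vals <- as.matrix(abundances[, design$sample_id, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE))
    stop("input error: negative abundance values")

  conds <- unique(design$condition)
  cond_mean <- vapply(conds, function(cc) {
    cols <- design$sample_id[design$condition == cc]
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  cond_mean <- matrix(cond_mean, nrow = nrow(vals),
                      dimnames = list(NULL, conds))

  contrasts <- setdiff(conds, control)
  agg_fun <- if (aggregator == "mean") mean else stats::median
  biotypes <- sort(unique(abundances$biotype))
  lfc <- matrix(NA_real_, length(biotypes), length(contrasts),
                dimnames = list(biotypes,
                                paste0(contrasts, "_vs_", control)))
  for (j in seq_along(contrasts)) {
    iso_lfc <- log2((cond_mean[, contrasts[j]] + pseudocount) /
                      (cond_mean[, control] + pseudocount))
    lfc[, j] <- vapply(biotypes, function(b)
      agg_fun(iso_lfc[abundances$biotype == b]), 0)
  }
  n_iso <- vapply(biotypes, function(b) sum(abundances$biotype == b), 0L)
  structure(list(log2fc = lfc, n_isoforms = n_iso, control = control,
                 pseudocount = pseudocount, aggregator = aggregator),
            class = "biotype_matrix")
}

#' @export
print.biotype_matrix <- function(x, ...) {
  cat("<biotype_matrix> ", nrow(x$log2fc), " biotype(s) x ",
      ncol(x$log2fc), " contrast(s); aggregator = ", x$aggregator,
      ", pseudocount = ", x$pseudocount, "\n", sep = "")
  m <- cbind(round(x$log2fc, 4), n_isoforms = x$n_isoforms)
  print(m, ...)
  invisible(x)
}

#' Read a per-isoform abundance table
#'
#' Expects a TSV with header `isoform_id`, `biotype`, then one numeric column
#' per sample.
#'
#' @param path Path to the TSV file.
#' @return Data frame as described.
#' @export
read_abundance_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a biotype change matrix as TSV
#'
#' @param x `biotype_matrix` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_biotype_matrix <- function(x, path) {
  df <- data.frame(biotype = rownames(x$log2fc), x$log2fc,
                   n_isoforms = x$n_isoforms, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
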