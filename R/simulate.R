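#' Default knockdown study design
#'
#' Two biological replicates for each of three siRNA conditions: CWC22
#' knockdown, eIF4A3 knockdown and a luciferase control — six samples total,
#' the design the whole pipeline assumes by default.
#'
#' @return Data frame `sample_id`, `condition`, `replicate`.
#' @export
sim_design <- function() {
  data.frame(
    sample_id = c("cwc22_kd_1", "cwc22_kd_2", "eif4a3_kd_1", "eif4a3_kd_2",
                  "control_1", "control_2"),
    condition = rep(c("cwc22_kd", "eif4a3_kd", "control"), each = 2L),
    replicate = rep(1:2, 3L),
    stringsAsFactors = FALSE
  )
}

# stable sub-seed for a named random stream: polynomial string hash folded
# with the master seed, kept below 2^31
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Simulate a gene annotation
#'
#' Places non-overlapping multi-exon genes along one synthetic chromosome
#' and emits them as an exon table, GTF file and built loci. Roughly half the
#' genes get a second transcript whose exon structure differs (a dropped
#' internal exon and/or an exon extended into its intron) so that super-exon
#' merging is exercised; the locus span is preserved. Optionally a fraction
#' of genes is placed overlapping its predecessor to create the multi-locus
#' counting edge case.
#'
#' @param n_genes Number of genes (>= 1).
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length Ranges of exon and intron lengths (bp).
#' @param intergenic_gap Range of gaps between consecutive genes (bp).
#' @param overlap_fraction Fraction of genes (after the first) placed so they
#'   overlap the previous gene.
#' @param biotype_freq Named probabilities used to draw each gene's biotype.
#' @param chrom Synthetic chromosome name.
#' @param chrom_length Optional chromosome length; simulation stops with an
#'   error suggesting a longer chromosome if the genes do not fit.
#' @param seed Integer seed; output is deterministic per seed.
#' @param gtf_path Optional path; when given, the annotation is written as
#'   GTF (1-based inclusive coordinates).
#' @return List with `exons` (exon table as from [parse_gtf()]), `loci`
#'   (from [build_gene_loci()]), `biotypes` (named by gene) and `gtf_path`.
#' @export
simulate_annotation <- function(n_genes = 500,
                                exons_per_gene = c(2L, 8L),
                                exon_length = c(80L, 400L),
                                intron_length = c(200L, 2000L),
                                intergenic_gap = c(500L, 5000L),
                                overlap_fraction = 0,
                                biotype_freq = c(protein_coding = 0.80,
                                                 retained_intron = 0.08,
                                                 lincRNA = 0.07,
                                                 snoRNA = 0.05),
                                chrom = "chrS", chrom_length = NULL,
                                seed = 1, gtf_path = NULL) {
  stopifnot(n_genes >= 1, all(exon_length > 0), all(intron_length > 0))
  set.seed(derive_seed(seed, "annotation"))
  rint <- function(rng) {
    if (rng[1L] == rng[2L]) return(as.integer(rng[1L]))
    rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
  }
  cursor <- 1000L
  prev_span <- NULL
  rows <- vector("list", n_genes)
  biotypes <- character(n_genes)
  for (i in seq_len(n_genes)) {
    gid <- sprintf("G%04d", i)
    n_ex <- rint(exons_per_gene)
    ex_len <- vapply(seq_len(n_ex), function(.) rint(exon_length), 0L)
    in_len <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(.) rint(intron_length), 0L)
    else integer(0)
    start0 <- cursor
    if (i > 1L && overlap_fraction > 0 && stats::runif(1) < overlap_fraction)
      start0 <- max(0L, prev_span[1L] +
                      as.integer((prev_span[2L] - prev_span[1L]) / 2L))
    st <- start0 + c(0L, cumsum(ex_len[-n_ex] + in_len))
    en <- st + ex_len
    strand <- sample(c("+", "-"), 1L)
    biotypes[i] <- sample(names(biotype_freq), 1L, prob = biotype_freq)
    tx <- data.frame(gene_id = gid, transcript_id = paste0(gid, ".T1"),
                     biotype = biotypes[i], chrom = chrom,
                     start = st, end = en, strand = strand,
                     stringsAsFactors = FALSE)
    gene_rows <- tx
    if (n_ex >= 3L && stats::runif(1) < 0.5) {
      # alternative transcript: drop one internal exon, extend another's
      # 3' boundary into the downstream intron (span endpoints untouched)
      drop <- sample(2:(n_ex - 1L), 1L)
      st2 <- st[-drop]; en2 <- en[-drop]
      k <- sample(seq_len(length(st2) - 1L), 1L)
      room <- st2[k + 1L] - en2[k] - 1L
      if (room > 0L) en2[k] <- en2[k] + min(room, 50L)
      gene_rows <- rbind(gene_rows, data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".T2"),
        biotype = biotypes[i], chrom = chrom,
        start = st2, end = en2, strand = strand, stringsAsFactors = FALSE))
    }
    rows[[i]] <- gene_rows
    prev_span <- c(st[1L], en[n_ex])
    cursor <- max(cursor, en[n_ex]) + rint(intergenic_gap)
    if (!is.null(chrom_length) && cursor > chrom_length)
      stop("synthetic chromosome too short for ", n_genes,
           " genes; increase chrom_length")
  }
  exons <- do.call(rbind, rows)
  rownames(exons) <- NULL
  names(biotypes) <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(gtf_path)) write_gtf(exons, gtf_path)
  list(exons = exons, loci = build_gene_loci(exons), biotypes = biotypes,
       gtf_path = gtf_path)
}

write_gtf <- function(exons, path) {
  lines <- sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id, exons$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Ground-truth retention fractions and expression weights
#'
#' By default, per-gene intron-retention is elevated only under CWC22
#' knockdown (r = 0.30) and stays at a basal 0.05 in the eIF4A3 knockdown
#' and the control, mirroring a splicing factor whose loss causes global
#' intron retention while the other knockdown does not. Expression weights
#' are log-normal and shared across conditions.
#'
#' @param annotation Output of [simulate_annotation()] (or a list with
#'   `loci` and `biotypes`).
#' @param conditions Condition labels.
#' @param retention Named per-condition retention fractions in `[0, 1]`.
#' @param w_sdlog Log-normal sd of the per-gene expression weight.
#' @param seed Integer seed.
#' @return Data frame `gene_id`, `condition`, `r`, `w`, `biotype` (one row
#'   per gene x condition).
#' @export
simulate_truth <- function(annotation,
                           conditions = c("cwc22_kd", "eif4a3_kd", "control"),
                           retention = c(cwc22_kd = 0.30, eif4a3_kd = 0.05,
                                         control = 0.05),
                           w_sdlog = 0.7, seed = 1) {
  stopifnot(all(conditions %in% names(retention)),
            all(retention >= 0 & retention <= 1))
  set.seed(derive_seed(seed, "truth"))
  gene_ids <- names(annotation$loci)
  w <- stats::rlnorm(length(gene_ids), meanlog = 0, sdlog = w_sdlog)
  out <- do.call(rbind, lapply(conditions, function(cc)
    data.frame(gene_id = gene_ids, condition = cc,
               r = unname(retention[[cc]]), w = w,
               biotype = unname(annotation$biotypes[gene_ids]),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# sample n positions uniformly over the base set of an interval data frame
sample_positions <- function(iv, n) {
  if (n == 0L) return(integer(0))
  w <- iv$end - iv$start
  idx <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  iv$start[idx] + as.integer(floor(stats::runif(n) * w[idx]))
}

#' Simulate read 5' ends for every sample of a design
#'
#' For each gene and sample, the number of locus reads is Poisson with mean
#' `depth * w * f`, where `w` is the gene's expression weight and `f` a
#' per-sample log-normal library factor (`replicate_noise` is its sd on the
#' log scale). Each read is intronic with probability `r` (the condition's
#' ground-truth retention fraction), placed uniformly over the intron base
#' set, otherwise uniformly over the super-exon base set. Reads are emitted
#' as BED6 records of `read_length` bases on the gene strand whose 5' end is
#' the sampled position; intronless genes receive only exonic ends (with a
#' warning if their `r` is positive). One named random stream per sample,
#' derived from `seed` and the sample id, makes every sample reproducible in
#' isolation.
#'
#' @param loci List of `gene_locus` objects.
#' @param truth Data frame from [simulate_truth()]; must cover every gene x
#'   condition of the design.
#' @param design Design data frame (`sample_id`, `condition`, `replicate`).
#' @param depth Mean locus reads per gene and sample at `w = 1`, `f = 1`.
#' @param replicate_noise Log-scale sd of the per-sample library factor.
#' @param read_length Emitted read length in bases.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, one `<sample_id>.bed` file per
#'   sample is written.
#' @return List with `reads` (named list of BED6 data frames), `bookkeeping`
#'   (data frame `gene_id`, `sample_id`, `locus_count`, `exonic_count`,
#'   `intronic_count` of the placements actually made) and `bed_paths`.
#' @export
simulate_read_ends <- function(loci, truth, design, depth = 200,
                               replicate_noise = 0.1, read_length = 75L,
                               seed = 1, dir = NULL) {
  stopifnot(depth >= 0)
  gene_ids <- names(loci)
  for (cc in unique(design$condition)) {
    miss <- setdiff(gene_ids,
                    truth$gene_id[truth$condition == cc])
    if (length(miss))
      stop("truth table lacks condition ", cc, " for gene(s) ",
           paste(utils::head(miss, 3L), collapse = ", "))
  }
  has_introns <- vapply(loci, function(l) nrow(l$introns) > 0L, TRUE)
  reads <- list()
  bed_paths <- character(0)
  book <- vector("list", nrow(design))
  warned <- FALSE
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    cond <- design$condition[i]
    set.seed(derive_seed(seed, sid))
    f <- stats::rlnorm(1L, meanlog = 0, sdlog = replicate_noise)
    tr <- truth[truth$condition == cond, ]
    tr <- tr[match(gene_ids, tr$gene_id), ]
    r_eff <- tr$r
    if (any(r_eff > 0 & !has_introns)) {
      if (!warned) {
        warning("retention fraction > 0 for intronless gene(s); treated as 0")
        warned <- TRUE
      }
      r_eff[!has_introns] <- 0
    }
    n_reads <- stats::rpois(length(gene_ids), depth * tr$w * f)
    n_intronic <- stats::rbinom(length(gene_ids), n_reads, r_eff)
    n_exonic <- n_reads - n_intronic
    per_gene <- vector("list", length(gene_ids))
    for (g in seq_along(gene_ids)) {
      l <- loci[[g]]
      pos <- c(sample_positions(l$super_exons, n_exonic[g]),
               sample_positions(l$introns, n_intronic[g]))
      if (length(pos) == 0L) next
      if (l$strand == "-") {
        st <- pmax(0L, pos + 1L - as.integer(read_length)); en <- pos + 1L
      } else {
        st <- pos; en <- pos + as.integer(read_length)
      }
      per_gene[[g]] <- data.frame(
        chrom = l$chrom, start = st, end = en,
        name = paste0(l$gene_id, "_", seq_along(pos)), score = 0L,
        strand = if (l$strand %in% c("+", "-")) l$strand else "+",
        stringsAsFactors = FALSE)
    }
    bed <- do.call(rbind, per_gene)
    if (is.null(bed))
      bed <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = integer(0), strand = character(0))
    rownames(bed) <- NULL
    reads[[sid]] <- bed
    book[[i]] <- data.frame(gene_id = gene_ids, sample_id = sid,
                            locus_count = n_reads, exonic_count = n_exonic,
                            intronic_count = n_intronic,
                            stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      p <- file.path(dir, paste0(sid, ".bed"))
      utils::write.table(bed, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      bed_paths[sid] <- p
    }
  }
  bookkeeping <- do.call(rbind, book)
  rownames(bookkeeping) <- NULL
  list(reads = reads, bookkeeping = bookkeeping,
       bed_paths = if (length(bed_paths)) bed_paths else NULL)
}

#' Simulate a per-isoform abundance table
#'
#' One isoform per gene, with log-normal FPKM-like abundances around
#' `base_fpkm * w * fold(biotype, condition)`. The default fold-change table
#' encodes the expected knockdown response: transcripts of the
#' retained_intron biotype rise and protein-coding transcripts fall modestly
#' under CWC22 knockdown, while the eIF4A3 knockdown and control stay flat.
#'
#' @param truth Data frame from [simulate_truth()].
#' @param design Design data frame.
#' @param dispersion Log-scale sd of the abundance noise (0 = exact folds).
#' @param fold Named list: `fold[[condition]][[biotype]]` multiplicative
#'   change (missing entries default to 1).
#' @param base_fpkm Baseline abundance scale.
#' @param seed Integer seed.
#' @return Data frame `isoform_id`, `biotype`, then one column per sample.
#' @export
simulate_abundances <- function(truth, design, dispersion = 0.2,
                                fold = list(cwc22_kd = c(protein_coding = 0.7,
                                                         retained_intron = 2.0)),
                                base_fpkm = 10, seed = 1) {
  stopifnot(dispersion >= 0)
  set.seed(derive_seed(seed, "abundance"))
  genes <- unique(truth[, c("gene_id", "biotype")])
  w <- truth$w[match(genes$gene_id, truth$gene_id)]
  out <- data.frame(isoform_id = paste0(genes$gene_id, ".1"),
                    biotype = genes$biotype, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(design))) {
    cond <- design$condition[i]
    fc <- rep(1, nrow(genes))
    if (!is.null(fold[[cond]])) {
      hit <- genes$biotype %in% names(fold[[cond]])
      fc[hit] <- fold[[cond]][genes$biotype[hit]]
    }
    noise <- if (dispersion > 0)
      stats::rlnorm(nrow(genes), 0, dispersion) else 1
    out[[design$sample_id[i]]] <- base_fpkm * w * fc * noise
  }
  out
}

#' Simulate a complete knockdown experiment on disk
#'
#' Runs annotation, truth, read and abundance simulation with one seed and
#' writes exactly the file set the pipeline consumes: `annotation.gtf`, one
#' `<sample_id>.bed` per sample, `truth.tsv`, `abundance.tsv`, `design.tsv`.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes,depth,seed Main size/seed knobs.
#' @param design Design data frame; defaults to [sim_design()].
#' @param ... Passed on to [simulate_annotation()], [simulate_truth()],
#'   [simulate_read_ends()] or [simulate_abundances()] by matching names.
#' @return List with the simulation objects (`annotation`, `truth`, `sim`,
#'   `abundances`, `design`) and `paths` to every written file.
#' @export
simulate_experiment <- function(dir, n_genes = 500, depth = 200, seed = 1,
                                design = sim_design(), ...) {
  dots <- list(...)
  pick <- function(fn, fixed) {
    ok <- intersect(names(dots), setdiff(names(formals(fn)), names(fixed)))
    c(fixed, dots[ok])
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "annotation.gtf")
  ann <- do.call(simulate_annotation,
                 pick(simulate_annotation,
                      list(n_genes = n_genes, seed = seed, gtf_path = gtf)))
  truth <- do.call(simulate_truth,
                   pick(simulate_truth,
                        list(annotation = ann,
                             conditions = unique(design$condition),
                             seed = seed)))
  sim <- do.call(simulate_read_ends,
                 pick(simulate_read_ends,
                      list(loci = ann$loci, truth = truth, design = design,
                           depth = depth, seed = seed, dir = dir)))
  ab <- do.call(simulate_abundances,
                pick(simulate_abundances,
                     list(truth = truth, design = design, seed = seed)))
  paths <- list(gtf = gtf, beds = sim$bed_paths,
                truth = file.path(dir, "truth.tsv"),
                abundance = file.path(dir, "abundance.tsv"),
                design = file.path(dir, "design.tsv"))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ab, paths$abundance, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design, paths$design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(annotation = ann, truth = truth, sim = sim, abundances = ab,
       design = design, paths = paths)
}
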