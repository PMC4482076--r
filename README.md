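# irprop — intron retention quantification from read 5' ends

`irprop` is for RNA-seq analysts who need to ask a blunt, global question:
*does knocking down this splicing factor leave introns in the
transcriptome?* It implements a deliberately simple per-gene retention
statistic for small knockdown designs (the assumed layout is two
biological replicates each of a CWC22 knockdown, an eIF4A3 knockdown and a
luciferase control), together with a per-biotype expression-change summary
and a seeded synthetic-data generator so the entire pipeline can be
exercised and validated without any sequencing data.

## The statistic

For each gene, all exons of all transcripts are merged into disjoint
**super-exons**; the **gene locus** spans from the first to the last
exonic base, and the introns are the gaps in between. Every aligned mate
is reduced to its 5'-end position (leftmost base on `+`, rightmost on
`-`), and with `n_locus` ends in the locus and `n_exonic` of them inside
super-exons, the **intronic-read proportion** is

```
p = 1 − n_exonic / n_locus .
```

Genes with fewer than 100 summed intronic ends across all samples are
discarded; each retained gene's proportions are then divided by their
maximum across samples (highest sample = 1), making the values comparable
between genes with very different exon/intron size ratios. Per sample, the
distribution is summarized by its median and percentiles 5/95; per
condition, by the mean of replicate medians and its difference to the
control. See `vignette source in vignettes/intron-retention-methods.Rmd`
for the full model, parameter meanings and design choices.

## Worked example

```r
library(irprop)
dir <- tempfile()
sim <- simulate_experiment(dir, n_genes = 60, depth = 200, seed = 7)
fit <- quantify_retention(sim$paths$gtf, as.list(sim$paths$beds),
                          sim$design, abundances = sim$paths$abundance)
fit
```

```
Intron retention analysis
  samples: 6 (cwc22_kd, eif4a3_kd, control)
  gene loci: 60; retained after >=100 summed intronic reads: 44
  condition contrast (mean of replicate medians of normalized proportions):
 condition mean_median delta_vs_control
  cwc22_kd      0.9712         0.812507
 eif4a3_kd      0.1575        -0.001177
   control      0.1587         0.000000
```

44 of 60 simulated genes clear the 100-read intronic filter. The CWC22
knockdown samples sit near the per-gene maximum (mean replicate median
0.97 of normalized proportion, +0.81 over control), while the eIF4A3
knockdown is indistinguishable from control — exactly the structure the
generator encodes (true retention fraction 0.30 under CWC22 knockdown,
0.05 elsewhere). The per-sample view:

```r
summary(fit)$summaries
```

```
   sample_id condition replicate n_genes median     p5   p95
  cwc22_kd_1  cwc22_kd         1      44  0.942 0.8056 1.000
  cwc22_kd_2  cwc22_kd         2      44  1.000 0.8024 1.000
 eif4a3_kd_1 eif4a3_kd         1      44  0.153 0.0703 0.215
 eif4a3_kd_2 eif4a3_kd         2      44  0.162 0.0780 0.219
   control_1   control         1      44  0.164 0.1058 0.210
   control_2   control         2      44  0.154 0.0967 0.227
```

`plot(fit)` draws the matching per-sample box plot (whiskers at
percentiles 5 and 95); `fit$biotype` holds the per-biotype log2
fold-change matrix versus control.

A command-line front end with the same stages lives at
`inst/exec/irprop` (subcommands `simulate`, `build-annotation`, `count`,
`stats`, `biotype`, `run`).

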