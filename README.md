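# circsca

Consensus circRNA quantification and X-chromosome dosage analysis for
sex-chromosome aneuploidy cohorts.

## The problem

Turner syndrome (45,X) and Klinefelter syndrome (47,XXY) change the copy
number of the sex chromosomes, and with it the expression of genes in the
pseudoautosomal regions (PAR1, PAR2) and of X-inactivation (XCI) escape
genes. Circular RNAs (circRNAs) — covalently closed transcripts defined by
a backsplice junction (BSJ) — arise from the same loci, but whether and how
strongly they track X dosage is not obvious from linear expression alone.
`circsca` implements the complete analysis a study of this question needs:

- **Consensus quantification.** BSJ calls are trusted only when a
  count-bearing primary caller and at least one detection-only secondary
  caller agree on the junction (exact coordinates by default). Counts are
  normalized to **circCPM** (backsplice reads per million circular reads
  per sample) and filtered at ≥ 25 circCPM in ≥ 7 samples.
- **Circular-to-linear ratio.** `CTL = 2c / (2c + l)` per junction and
  sample, where `c` counts backsplice reads and `l` linear junction reads;
  0 means no circular, 1 means no linear expression.
- **Dosage expectations.** PAR genes sit on every sex chromosome, so their
  copy number is `nX + nY`, giving the 1:2:2:3 stoichiometry for
  45,X : 46,XY : 46,XX : 47,XXY and the theoretical log2 fold changes
  `log2(3/2) = 0.585` (47,XXY vs 46,XY) and `log2(1/2) = -1`
  (45,X vs 46,XX). Collective PAR shifts are tested with a one-sample
  t-test of the per-circRNA log2 fold changes; circRNA-vs-mRNA dosage
  attenuation is the origin-constrained slope of paired PAR log2 fold
  changes.
- **Moderated differential expression.** A precision-weighted linear model
  with batch covariates: log2-CPM transform, lowess mean–variance trend
  weights plus iteratively estimated per-sample quality weights, and
  empirical-Bayes variance moderation (method-of-moments prior on
  `log s²`), with Benjamini–Hochberg control. circRNAs are called at
  adjusted p < 0.05 and |log2FC| > 1, genes at adjusted p < 0.05 after a
  ≥ 20 counts in > 3 samples prefilter.
- **ceRNA networks.** circRNA–miRNA edges supported by ≥ 2 AGO CLIP-seq
  experiments, targets restricted to differential genes and expressed PAR
  genes, a sponge sign-consistency rule (circRNA and mRNA directions must
  agree), hypergeometric over-representation tests, and Cytoscape-ready
  export (SIF, GraphML, node/edge tables).
- **Synthetic cohorts.** A generator that emulates the full study
  structure — karyotypes, tissues, batches, negative-binomial counts with a
  `(copies/2)^alpha` circRNA dosage response, caller false
  positives/negatives, CTL targets, known-circRNA catalogue, and planted
  sponge triplets — so every stage is validated against a known truth.

## Worked example

```r
library(circsca)

cfg    <- sim_config(n_per_group = 15, karyotypes = c("45X", "46XX"),
                     tissues = "blood", n_circ = 300, dispersion = 0.05,
                     circ_attenuation = 0.5, seed = 42)
ann    <- generate_annotation(cfg)
cohort <- generate_cohort(cfg)
truth  <- simulate_counts(ann, cohort, cfg)

cpm  <- circ_cpm(truth$true_circ_counts)
keep <- expression_filter(cpm, filter_thresholds())   # >=25 circCPM, >=7 samples
res  <- de_analysis(truth$true_circ_counts[keep, ], cohort,
                    contrast_spec("45X", "46XX", "blood"), "circ")
anno <- annotate_circ(keep, ann, truth$catalogue)
collective_par_shift(res, anno, tissue = "blood", contrast = "45X_vs_46XX")
#>   tissue    contrast region  n mean_log2fc     t        p stars degenerate
#> 1  blood 45X_vs_46XX   PAR1 30      -0.416 -16.4 3.19e-16   ***      FALSE

gres <- de_analysis(truth$true_gene_counts, cohort,
                    contrast_spec("45X", "46XX", "blood"), "gene")
at <- circ_mrna_attenuation(res, gres, anno)
round(c(slope = at$slope, correlation = at$correlation), 3)
#>       slope correlation
#>       0.463       0.215
```

The cohort was generated with an attenuation exponent of 0.5, so the
mRNA dosage effect for the missing X is the full `log2(1/2) = -1` while
PAR circRNAs carry about half of it: the collective PAR1 circRNA shift of
−0.42 (one-sample t-test, p ≈ 3e−16) sits between 0 and the mRNA line, and
the fitted circRNA-on-mRNA slope of 0.46 recovers the planted attenuation.

The same analysis runs end-to-end from a YAML config:

```sh
Rscript exec/circsca all --config inst/extdata/toy_config.yaml
```

which writes per-stage TSVs (consensus matrices, CTL table, annotation,
DE results, dosage shifts, networks, summary report) under the configured
output directory.

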