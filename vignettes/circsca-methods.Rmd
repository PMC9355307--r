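---
title: "Methods: consensus circRNA quantification and X-dosage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus circRNA quantification and X-dosage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsca)
```

# Scope and data model

`circsca` analyses circular RNA expression in cohorts that differ in sex
chromosome constitution (45,X; 46,XX; 46,XY; 47,XXY), across tissues and
processing batches. The atomic object is the backsplice junction (BSJ):
a circRNA is identified by `(chrom, start, end, strand)`, held internally
in 0-based half-open coordinates and serialized as the key
`"chrom:start-end:strand"`. All conversions to the 1-based inclusive
convention used by caller tables and printed genome coordinates happen at
I/O boundaries only, so exactly one convention exists in memory.

# Consensus quantification

Three filters are applied in a fixed order, each logged with
before/after counts by the pipeline:

1. **Consensus.** A junction reported by the count-bearing primary caller
   is kept only if at least `consensus_min_secondary` (default 1)
   detection-only secondary callers report a matching junction. Matching
   is exact key equality by default; `coord_slack_bp` relaxes both
   endpoints (same chromosome and strand required), and an unstranded
   mode collapses strands, since callers disagree on strand more often
   than on coordinates. The consensus output is always a subset of the
   primary key set.
2. **circCPM.** Counts are normalized per sample to circular counts per
   million: each column is divided by its own total backsplice read count
   and scaled by 1e6. The denominator is the *sum of backsplice reads*,
   not the number of distinct junctions; reads-per-million is the only
   reading under which the unit behaves like a CPM, and a
   species-count denominator is available for sensitivity analysis.
   circCPM is computed on the consensus set, i.e. after filter 1.
3. **Expression filter.** Keep a junction expressed at ≥ `min_circCPM`
   (default 25) in ≥ `min_samples` (default 7) samples. Both comparisons
   are inclusive; a junction at exactly 25 circCPM in exactly 7 samples
   passes.

The circular-to-linear ratio is `CTL = 2c/(2c + l)` with the convention
`CTL = 0` whenever `c = 0`; it is bounded in `[0, 1]`, increasing in `c`
and decreasing in `l`, and the endpoints mean "no circular" and "no
linear" expression over the junction.

# Annotation

A junction is **exonic** for a host gene when its start coincides with an
exon start and its end with an exon end (tolerance `boundary_tol`,
default 0 bp — the strictest reading; relax for annotations with fuzzy
exon ends); **intronic** when inside a gene without meeting the exon
rule; **intergenic** otherwise. The exon count is the number of host
exons fully inside the junction, using the union of exons over all
overlapping hosts for junctions that span two adjacent genes (which
report every host, and count once per host in isoform tallies). PAR
membership requires *both* endpoints inside the same printed interval —
PAR1 chrX:10,001–2,781,479, PAR2 chrX:155,701,383–156,030,895, evaluated
in the printed 1-based frame so the boundary numbers hold exactly.
Catalogue matching is exact on harmonized coordinates; the catalogue is
assumed to be on the same genome build.

# Differential expression

The paper-level analysis this package supports uses separate,
well-established tools for circRNA and gene differential expression. Here
both run through one internally implemented precision-weighted moderated
linear model, because a single code path keeps the two fold-change sets
numerically comparable for the attenuation analysis and makes the whole
stage testable against ground truth. No numerical equivalence with any
external package is claimed; the empirical-Bayes variance squeeze is,
however, cross-checked in the test suite against an independent
implementation on identical inputs.

The stages are:

- `log2 CPM`: `y = log2((count + 0.5)/(libsize + 1) * 1e6)`, library
  size being the column sum of the supplied matrix — for circRNAs that is
  the circular library (consistent with circCPM), not the whole-library
  total.
- **Precision weights**: per-feature residual SD from an ordinary fit is
  square-root-transformed and regressed on mean log2 CPM by lowess
  (span 0.5); per-observation SDs are predicted at the fitted values and
  the weight is SD^(−4). A floor of `sd_floor = 1e-6` guards degenerate
  all-equal input, and a constant trend is used when the mean values
  collapse to a point.
- **Sample quality weights**: per-sample relative variance factors,
  estimated as leverage-adjusted mean squared standardized residuals and
  refined by three reweighted iterations. The iteration matters: a
  one-pass estimate is biased towards 1 by cross-sample leverage when one
  sample is much noisier than the rest (the planted 4x-variance test in
  the suite fails without it). Weights are normalized to geometric mean 1
  and multiply the trend weights.
- **Moderated fit**: per-feature weighted least squares; residual
  variances are squeezed towards a prior estimated by closed-form method
  of moments on `log s²` (trigamma inversion by Newton iteration); the
  moderated t uses the posterior variance with
  `df_residual + df_prior` degrees of freedom. Setting the prior df to 0
  recovers the ordinary WLS t exactly; infinity pools all variances.
- **Design**: intercept + group indicator (case = 1) + reference-coded
  batch. Covariate columns are added one at a time and dropped (with a
  warning) if aliased, so the group column can never be sacrificed to a
  confounded batch. Paired subjects can enter as a fixed subject
  covariate when subjects appear in both groups; a random-effect
  within-subject correlation is out of scope.
- **Calls**: strict thresholds throughout — adjusted p *below* 0.05 and
  |log2FC| *above* 1 for circRNAs; adjusted p below 0.05 for genes, after
  keeping genes with ≥ 20 counts in *more than* three (i.e. ≥ 4) samples.
  "At least" thresholds (25 circCPM, 7 samples, 20 counts, 2 CLIP
  experiments) are inclusive.

# Dosage analysis

The copy model: PAR genes reside on every sex chromosome, so
`copies = nX + nY` (1:2:2:3 across 45,X : 46,XY : 46,XX : 47,XXY);
XCI-escape genes scale with `nX`; XCI-inactivated chrX genes have one
active copy in every karyotype and autosomes are copy-invariant. This is
the only copy model consistent with the theoretical lines
`log2(3/2) = 0.585` and `log2(1/2) = -1` for one extra or missing X.
Expectations are antisymmetric under contrast reversal.

The collective PAR shift is a two-sided one-sample t-test of the mean
PAR-circRNA log2 fold change against `mu = 0`. Testing against 0 (rather
than the theoretical line) matches the "is there any collective shift"
question; `mu` is configurable. All PAR-assigned circRNAs with estimates
enter the test, not only significant ones — sub-threshold features carry
most of the collective signal at realistic power. PAR2 features are
profiled but excluded from expectation-based tests by default, because
their XCI-escape annotation is unreliable. A zero-variance fold-change
vector is flagged degenerate rather than producing a spurious t.

Attenuation is the least-squares slope of PAR circRNA log2 fold changes
on their host-gene log2 fold changes, fitted through the origin: both
axes contrast the same groups, so a zero mRNA effect must imply a zero
circRNA effect. An intercept fit is available behind a flag. A slope
below 1 means the circRNA dosage response is attenuated relative to the
mRNA response.

# ceRNA networks

circRNA–miRNA edges need ≥ 2 AGO CLIP-seq experiments (inclusive) and a
known catalogue id; miRNA targets are restricted to the contrast's
differential genes plus PAR genes passing the expression prefilter
("expressed" is deliberately operationalized as the prefilter, the only
expression criterion already in the model). The sponge logic — an
upregulated circRNA sequesters its miRNAs and thereby derepresses their
targets — is codified as a deterministic sign-consistency rule: a
circ→miRNA→mRNA path survives only when the circRNA and mRNA directions
agree. The rule is an interpretation of manually curated networks and
can be toggled off by skipping the filter; miRNA direction is unobserved
(no miRNA-seq) and never consulted. The filter is idempotent and
construction is monotone in the DEC set. Over-representation of network
genes uses the one-sided hypergeometric tail with the expression-passing
genes of the tissue as universe.

# The synthetic cohort generator

The generator exists so that every stage can be validated against a known
truth; its defaults describe the study structure, not any real dataset.

- **Cohort**: `n_per_group` subjects per karyotype, each sampled in every
  tissue (stable subject ids enable paired designs); batches round-robin.
- **Counts**: negative binomial with log2-linear predictor — per-feature
  baseline `~ N(mean_log_expression = 4, sd = 1.5)` (genes offset +2),
  tissue effects `~ N(0, 0.5)`, batch effects `~ N(0, batch_sd = 0.1)`,
  per-sample library size drawn from `lib_size_range` (5e5–1e6), and the
  dosage multiplier `(copies/2)^alpha` for circRNAs and `(copies/2)` for
  mRNAs when `mrna_dosage_full` is set. `dispersion = 0.1` is a typical
  bulk RNA-seq value; 0 gives Poisson counts. Library scaling uses the
  dosage-free intensity sum, so it is karyotype-neutral and group mean
  ratios of dosed features converge to the copy ratio.
- **Attenuation** is one exponent `alpha` in `[0, 1]` shared by all
  dosed circRNA features (default 0.5): the minimal testable encoding of
  a qualitatively attenuated circRNA dosage response; 1 means circRNA
  dosage equals mRNA dosage, 0 means none.
- **CTL targets**: a Beta(1.5, 5) draw (mostly below 0.5, matching the
  predominance of linear transcription) with a 5% point mass at exactly 1
  (purely circular junctions); linear counts are drawn with mean
  `2c(1 - CTL)/CTL` so the target holds in expectation, and a target of 1
  yields zero linear counts deterministically.
- **Caller noise**: secondary callers drop each true key with probability
  `fn_rate_per_caller` and inject disjoint, recorded false keys at
  `fp_rate_per_caller` per true key (both default 0.05). The primary
  caller is emitted noise-free by default — under the consensus rule,
  primary-only errors are the interesting failure mode, and the option
  remains at the file level.
- **Genome**: compactly packed multi-exon genes on five autosomes, chrX
  (escape and inactivated), chrY, and inside the printed PAR intervals;
  region-class counts are the rounded configured fractions. Intronic and
  intergenic circRNAs are carved from autosomal slots only, so planted
  origin labels are exactly recoverable; intergenic PAR circRNAs, seen in
  real data, are not emulated.
- **Interactions**: planted sign-consistent sponge triplets with CLIP
  counts ≥ 2, sign-inconsistent decoys that pass the evidence filter but
  must die at the sign rule, and noise edges with CLIP counts 1–4.

Determinism: all stages draw from fixed-offset substreams of the single
config seed, so identical config + seed reproduces byte-identical files,
while stages remain independently reproducible.

What the generator does **not** emulate: per-tissue abundance profiles of
real tissues (tissue effects are free multipliers), sequence content and
read-level artefacts, miRNA expression, isoform families sharing a host
(one circRNA per host slot by default), and the composition of real
circRNA libraries. Passing recovery tests therefore demonstrates the
correctness of the algorithms under the stated statistical model, not
fidelity of any biological claim to a particular tissue.

# Numerical choices and test problem sizes

- circCPM of an all-zero sample is all-zero (no 0/0); negative input is
  an error, not a warning.
- Expression filtering with `min_samples` above the sample count warns
  and returns the empty set.
- The trigamma inversion uses Newton steps with closed-form guards at
  both tails; prior df is infinite when the observed `log s²` spread is
  below its sampling noise.
- Ties in the lowess trend are averaged; predictions outside the fitted
  range are clamped to the boundary values.
- The test suite validates parameter recovery at deliberately modest
  sizes — 1,000 junctions × 20 samples for consensus truth recovery,
  1,000 features at 6 vs 6 for null calibration and 10 vs 10 for power,
  50 PAR circRNA–host pairs at `dispersion = 0.05` for attenuation
  recovery across `alpha` ∈ {0, 0.25, 0.5, 0.75, 1}, and 200 label
  permutations for the uniformity of the collective-shift p — chosen so
  the whole suite runs in well under a minute per file while the
  tolerances (±0.05 on converged log2 ratios, ±0.1 on attenuation
  slopes, [0.03, 0.07] on type-I error) still bind.
- Recovery tests that isolate a single effect fix the nuisance terms the
  effect definition excludes (batch SD 0, constant library size,
  Poisson counts); tests of the full model keep them at defaults.

# Known limitations

- CPM-style normalization carries a composition effect: when dosed
  features make up a noticeable fraction of the circular library, part of
  their fold change is absorbed into the library total. With 10% of the
  library dosed this biases collective shifts by roughly 0.05 log2 units
  at `alpha = 0.5`; real circRNA libraries are far below that fraction.
- The sign-consistency rule drops genuinely regulated targets whose
  direction is dominated by pathways other than sponging.
- The moderated model treats features as independent; correlated
  features (isoforms of one host) share information only through the
  variance prior.
- Exact-coordinate consensus matching is strict; callers that shift
  junctions by a few bases require `coord_slack_bp > 0`, which has no
  default evidence behind it and should be set from caller documentation.
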