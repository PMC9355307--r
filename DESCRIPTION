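Package: circsca
Title: Consensus circRNA Quantification and X-Chromosome Dosage Analysis
    for Sex Chromosome Aneuploidies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for circular-transcriptome analysis of sex-chromosome
    aneuploidy cohorts (45,X; 46,XX; 46,XY; 47,XXY). Implements
    multi-caller consensus filtering of backsplice junctions, circular
    counts-per-million (circCPM) normalization, circular-to-linear ratios,
    genomic-origin and pseudoautosomal-region (PAR) annotation, a
    precision-weighted moderated linear model for differential expression
    with batch covariates, collective PAR dosage tests against theoretical
    copy-number expectations, circRNA/mRNA dosage-attenuation estimation,
    and evidence-filtered circRNA-miRNA-mRNA (ceRNA) network construction
    with hypergeometric over-representation tests. A synthetic cohort
    generator emulates the full data structure, including karyotype
    dosage effects, batch effects, and caller-specific detection noise,
    so every stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
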