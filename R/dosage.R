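#' Sex-chromosome copy counts of a karyotype
#'
#' Pseudoautosomal genes sit on every sex chromosome, so their copy
#' number is `nX + nY`, giving the classical 1:2:2:3 dosage
#' stoichiometry for 45,X : 46,XY : 46,XX : 47,XXY.
#'
#' @param karyotype Karyotype label(s); commas and spaces are ignored, so
#'   `"45,X"` and `"45X"` are equivalent.
#' @return A list with integer vectors `nX`, `nY`, `par_copies`.
#' @export
karyotype_copies <- function(karyotype) {
  k <- toupper(gsub("[ ,]", "", karyotype))
  tab <- list("45X" = c(1L, 0L), "46XX" = c(2L, 0L),
              "46XY" = c(1L, 1L), "47XXY" = c(2L, 1L))
  bad <- setdiff(unique(k), names(tab))
  if (length(bad)) stop("unknown karyotype: ", paste(bad, collapse = ", "))
  nX <- vapply(k, function(x) tab[[x]][1], integer(1), USE.NAMES = FALSE)
  nY <- vapply(k, function(x) tab[[x]][2], integer(1), USE.NAMES = FALSE)
  list(nX = nX, nY = nY, par_copies = nX + nY)
}

#' Theoretical dosage log2 fold change for a contrast
#'
#' The expected log2 fold change of a feature class under the
#' sex-chromosome copy-number model: `log2(copies_case / copies_control)`
#' with PAR copies `nX + nY`, XCI-escape copies `nX`, and copy-invariant
#' XCI-inactivated/autosomal features at 0. The two printed theoretical
#' lines follow: `log2(3/2) = 0.585` for 47,XXY vs 46,XY and
#' `log2(1/2) = -1` for 45,X vs 46,XX on PAR features.
#'
#' @param case,control Karyotype labels.
#' @param region_class One of `"PAR"`, `"PAR1"`, `"PAR2"`,
#'   `"chrX_escape"`, `"chrX_inactive"`, `"chrY"`, `"autosome"`.
#' @return The expected log2 fold change (case over control).
#' @export
expected_dosage_log2fc <- function(case, control, region_class) {
  region_class <- match.arg(region_class,
                            c("PAR", "PAR1", "PAR2", "chrX_escape",
                              "chrX_inactive", "chrY", "autosome"))
  if (region_class %in% c("chrX_inactive", "autosome")) return(0)
  a <- karyotype_copies(case)
  b <- karyotype_copies(control)
  copies <- function(x) switch(region_class,
                               PAR = , PAR1 = , PAR2 = x$par_copies,
                               chrX_escape = x$nX,
                               chrY = x$nY)
  cc <- copies(a); cb <- copies(b)
  if (cb == 0) stop("control karyotype ", control,
                    " carries zero copies for ", region_class)
  log2(cc / cb)
}

#' Collective dosage shift of PAR circRNAs
#'
#' One-sample two-sided t-test of the mean log2 fold change of
#' PAR-assigned circRNAs against `mu` (default 0): `t = (mean - mu) /
#' (sd / sqrt(n))` with `n - 1` degrees of freedom. PAR2 features are
#' excluded by default. A zero-variance vector is flagged degenerate
#' (p = 0 when the mean differs from `mu`, p = 1 otherwise).
#'
#' @param de_results A `"de_result"` data frame for the tissue/contrast.
#' @param circ_annotations Output of [annotate_circ()] for the same keys.
#' @param tissue,contrast Labels recorded in the result.
#' @param region PAR class(es) to test (default `"PAR1"`).
#' @param mu Null mean (default 0).
#' @return A one-row data frame of class `"collective_shift"`: `tissue`,
#'   `contrast`, `region`, `n`, `mean_log2fc`, `t`, `p`, `stars`,
#'   `degenerate`.
#' @export
collective_par_shift <- function(de_results, circ_annotations,
                                 tissue = NA_character_,
                                 contrast = NA_character_,
                                 region = "PAR1", mu = 0) {
  keys <- circ_annotations$key[circ_annotations$par %in% region]
  x <- de_results$log2FC[match(keys, de_results$feature)]
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2)
    stop("collective shift needs >= 2 PAR features with estimates (got ",
         n, ")")
  m <- mean(x); s <- stats::sd(x)
  degenerate <- s == 0
  if (degenerate) {
    tstat <- if (m == mu) 0 else Inf * sign(m - mu)
    p <- if (m == mu) 1 else 0
  } else {
    tstat <- (m - mu) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), n - 1)
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else ""
  structure(data.frame(tissue = tissue, contrast = contrast,
                       region = paste(region, collapse = "+"),
                       n = n, mean_log2fc = m, t = tstat, p = p,
                       stars = stars, degenerate = degenerate,
                       stringsAsFactors = FALSE),
            class = c("collective_shift", "data.frame"))
}

#' Per-karyotype stoichiometry profile of one circRNA
#'
#' Mean circCPM per karyotype, normalized so the 46,XY mean equals 2,
#' reported against the theoretical 1:2:2:3 profile for
#' 45,X : 46,XY : 46,XX : 47,XXY together with the root-mean-square
#' deviation from it. Karyotypes with no expression (or no samples)
#' report a mean of 0 and stay in the profile.
#'
#' @param mat circCPM matrix.
#' @param metadata Cohort data frame.
#' @param key Junction key to profile.
#' @return List with `means` (raw per-karyotype means), `profile`
#'   (normalized), `expected` (1,2,2,3), `rmsd`.
#' @export
stoichiometry_profile <- function(mat, metadata, key) {
  if (!key %in% rownames(mat)) stop("key not in matrix: ", key)
  order_k <- c("45X", "46XY", "46XX", "47XXY")
  expected <- c(`45X` = 1, `46XY` = 2, `46XX` = 2, `47XXY` = 3)
  md <- metadata[match(colnames(mat), metadata$sample_id), ]
  means <- vapply(order_k, function(k) {
    idx <- which(md$karyotype == k)
    if (!length(idx)) 0 else mean(mat[key, idx])
  }, numeric(1))
  ref <- means[["46XY"]]
  profile <- if (ref > 0) means / ref * 2 else means * 0
  list(means = means, profile = profile, expected = expected,
       rmsd = sqrt(mean((profile - expected)^2)))
}

#' circRNA vs mRNA dosage attenuation
#'
#' Pairs PAR circRNA log2 fold changes with their host-gene log2 fold
#' changes and reports the Pearson correlation and the least-squares
#' slope of the circRNA effect on the mRNA effect. The slope is fitted
#' through the origin by default (both axes contrast the same groups);
#' a slope below 1 indicates attenuation of the dosage response at the
#' circRNA level.
#'
#' @param circ_de circRNA `"de_result"` for a contrast.
#' @param gene_de Gene `"de_result"` for the same contrast.
#' @param circ_annotations Output of [annotate_circ()]; pairing uses the
#'   first host gene of each junction.
#' @param region PAR class(es) considered (default `"PAR1"`).
#' @param through_origin Fit the slope through the origin (default) or
#'   with an intercept.
#' @return List with `pairs` (key, gene, circ_log2fc, gene_log2fc),
#'   `correlation`, `slope`, `n`.
#' @export
circ_mrna_attenuation <- function(circ_de, gene_de, circ_annotations,
                                  region = "PAR1",
                                  through_origin = TRUE) {
  ca <- circ_annotations[circ_annotations$par %in% region &
                           nzchar(circ_annotations$host_gene_ids), ]
  host <- sub(",.*$", "", ca$host_gene_ids)
  y <- circ_de$log2FC[match(ca$key, circ_de$feature)]
  x <- gene_de$log2FC[match(host, gene_de$feature)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3)
    stop("attenuation estimate needs >= 3 circRNA-host pairs (got ",
         sum(ok), ")")
  x <- x[ok]; y <- y[ok]
  slope <- if (through_origin) sum(x * y) / sum(x^2)
    else stats::coef(stats::lm(y ~ x))[["x"]]
  list(pairs = data.frame(key = ca$key[ok], gene = host[ok],
                          circ_log2fc = y, gene_log2fc = x,
                          stringsAsFactors = FALSE),
       correlation = stats::cor(x, y),
       slope = unname(slope), n = sum(ok))
}
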