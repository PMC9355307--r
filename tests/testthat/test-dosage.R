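test_that("karyotype copy counts follow the 1:2:2:3 stoichiometry", {
  cp <- karyotype_copies(c("45X", "46XY", "46XX", "47XXY"))
  expect_equal(cp$par_copies, c(1L, 2L, 2L, 3L))
  expect_equal(cp$nX, c(1L, 1L, 2L, 2L))
  expect_equal(cp$nY, c(0L, 1L, 0L, 1L))
  # printed karyotype spellings normalize
  expect_equal(karyotype_copies("45,X")$par_copies, 1L)
  expect_equal(karyotype_copies("47, XXY")$par_copies, 3L)
  expect_error(karyotype_copies("46XYY"), "unknown")
})

test_that("dosage expectations reproduce the theoretical lines", {
  expect_equal(round(expected_dosage_log2fc("47XXY", "46XY", "PAR"), 3),
               0.585)
  expect_equal(expected_dosage_log2fc("45X", "46XX", "PAR"), -1)
  expect_equal(expected_dosage_log2fc("46XX", "46XY", "PAR"), 0)
  expect_equal(expected_dosage_log2fc("47XXY", "46XY", "chrX_escape"), 1)
  expect_equal(expected_dosage_log2fc("45X", "46XX", "chrX_inactive"), 0)
  expect_equal(expected_dosage_log2fc("45X", "46XX", "autosome"), 0)
  expect_error(expected_dosage_log2fc("46XX", "45X", "chrY"), "zero copies")
})

test_that("dosage expectation is antisymmetric under contrast reversal", {
  pairs <- list(c("45X", "46XX"), c("47XXY", "46XY"), c("46XX", "46XY"))
  for (rc in c("PAR", "PAR1", "PAR2", "chrX_escape", "chrX_inactive",
               "autosome")) {
    for (p in pairs) {
      f <- expected_dosage_log2fc(p[1], p[2], rc)
      r <- expected_dosage_log2fc(p[2], p[1], rc)
      expect_equal(f, -r)
    }
  }
})

test_that("collective shift matches the closed-form one-sample t", {
  de <- data.frame(feature = c("k1", "k2", "k3"), log2FC = c(1, 2, 3))
  ca <- data.frame(key = c("k1", "k2", "k3"), par = "PAR1")
  sh <- collective_par_shift(de, ca)
  expect_equal(sh$n, 3L)
  expect_equal(sh$mean_log2fc, 2)
  expect_equal(round(sh$t, 3), 3.464)
  expect_equal(round(sh$p, 4), 0.0742)
  expect_equal(sh$stars, "")
  expect_false(sh$degenerate)
  # zero-variance vector is flagged degenerate
  de0 <- data.frame(feature = c("k1", "k2"), log2FC = c(0, 0))
  sh0 <- collective_par_shift(de0, ca)
  expect_true(sh0$degenerate)
  expect_equal(sh0$p, 1)
  de1 <- data.frame(feature = c("k1", "k2"), log2FC = c(0.3, 0.3))
  sh1 <- collective_par_shift(de1, ca)
  expect_true(sh1$degenerate)
  expect_equal(sh1$p, 0)
  expect_error(collective_par_shift(de[1, ], ca), ">= 2")
})

test_that("attenuated cohorts recover the planted mean PAR shift", {
  cfg <- sim_config(n_per_group = 50, karyotypes = c("45X", "46XX"),
                    tissues = "blood", n_circ = 300, frac_par1 = 0.1,
                    dispersion = 0.05, circ_attenuation = 0.5, seed = 31)
  coh <- generate_cohort(cfg)
  truth <- simulate_counts(generate_annotation(cfg), coh, cfg)
  cd <- de_analysis(truth$true_circ_counts, coh,
                    contrast_spec("45X", "46XX", "blood"), "circ")
  ca <- annotate_circ(truth$circ_features$key, truth$annotation)
  sh <- collective_par_shift(cd, ca)
  # true circRNA effect is alpha * log2(1/2) = -0.5
  expect_lt(abs(sh$mean_log2fc - (-0.5)), 0.1)
  expect_lt(sh$p, 0.001)
})

test_that("permuted karyotype labels give uniform collective-shift p", {
  # exchangeable samples: no batch or library-size structure, no effect
  cfg <- sim_config(n_per_group = 10, karyotypes = c("45X", "46XX"),
                    tissues = "blood", n_circ = 80, frac_par1 = 0.25,
                    circ_attenuation = 0, batch_sd = 0,
                    lib_size_range = c(1e6, 1e6), seed = 17)
  coh <- generate_cohort(cfg)
  truth <- simulate_counts(generate_annotation(cfg), coh, cfg)
  y <- log_cpm_transform(truth$true_circ_counts)
  par1 <- truth$circ_features$region_class == "PAR1"
  set.seed(99)
  ps <- replicate(200, {
    lab <- sample(coh$karyotype)
    lfc <- rowMeans(y[par1, lab == "45X"]) -
      rowMeans(y[par1, lab == "46XX"])
    de <- data.frame(feature = rownames(y)[par1], log2FC = lfc)
    ca <- data.frame(key = rownames(y)[par1], par = "PAR1")
    collective_par_shift(de, ca)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("stoichiometry profiles match their planted structure", {
  # alpha = 1, near-zero noise: profile approaches 1:2:2:3
  cfg <- sim_config(n_per_group = 40, tissues = "blood", n_circ = 150,
                    frac_par1 = 0.1, dispersion = 0, batch_sd = 0,
                    circ_attenuation = 1, lib_size_range = c(1e6, 1e6),
                    seed = 13)
  coh <- generate_cohort(cfg)
  truth <- simulate_counts(generate_annotation(cfg), coh, cfg)
  cpm <- circ_cpm(truth$true_circ_counts)
  par1 <- truth$circ_features$key[truth$circ_features$region_class ==
                                    "PAR1"]
  top <- par1[which.max(rowMeans(cpm[par1, ]))]
  sp <- stoichiometry_profile(cpm, coh, top)
  expect_lt(sp$rmsd, 0.15)
  # a flat profile scores the hand-computed RMSD against 1:2:2:3
  flat <- matrix(10, 1, nrow(coh),
                 dimnames = list("k", coh$sample_id))
  spf <- stoichiometry_profile(circsca:::circ_matrix(flat, "circCPM"),
                               coh, "k")
  expect_equal(spf$profile, c(`45X` = 2, `46XY` = 2, `46XX` = 2,
                              `47XXY` = 2))
  expect_equal(spf$rmsd, sqrt(mean(c(1, 0, 0, 1))))
  # absent karyotype reports 0 and stays in the profile
  coh2 <- coh[coh$karyotype != "45X", ]
  flat2 <- flat[, coh2$sample_id, drop = FALSE]
  sp2 <- stoichiometry_profile(circsca:::circ_matrix(flat2, "circCPM"),
                               coh2, "k")
  expect_equal(unname(sp2$means["45X"]), 0)
})

test_that("attenuation slope recovers alpha across its range", {
  rec <- function(alpha) {
    cfg <- sim_config(n_per_group = 15, karyotypes = c("45X", "46XX"),
                      tissues = "blood", n_circ = 500, frac_par1 = 0.1,
                      frac_par2 = 0, frac_chrX_escape = 0,
                      frac_chrX_inactive = 0, frac_chrY = 0,
                      frac_intronic = 0, frac_intergenic = 0,
                      dispersion = 0.05, circ_attenuation = alpha,
                      seed = 21)
    coh <- generate_cohort(cfg)
    truth <- simulate_counts(generate_annotation(cfg), coh, cfg)
    ctr <- contrast_spec("45X", "46XX", "blood")
    cd <- de_analysis(truth$true_circ_counts, coh, ctr, "circ")
    gd <- de_analysis(truth$true_gene_counts, coh, ctr, "gene")
    ca <- annotate_circ(truth$circ_features$key, truth$annotation)
    circ_mrna_attenuation(cd, gd, ca)
  }
  for (alpha in c(0, 0.25, 0.5, 0.75, 1)) {
    at <- rec(alpha)
    expect_equal(at$n, 50L)
    expect_lt(abs(at$slope - alpha), 0.1)
  }
})

test_that("identical circ and gene tables give slope and correlation 1", {
  de <- data.frame(feature = c("k1", "k2", "k3", "GA", "GB", "GC"),
                   log2FC = c(-1, -0.5, -0.8, -1, -0.5, -0.8))
  ca <- data.frame(key = c("k1", "k2", "k3"),
                   host_gene_ids = c("GA", "GB", "GC"), par = "PAR1")
  at <- circ_mrna_attenuation(de, de, ca)
  expect_equal(at$slope, 1)
  expect_equal(at$correlation, 1)
  expect_error(circ_mrna_attenuation(de[1:4, ], de, ca[1, ]), ">= 3")
})
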