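test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_par1 = 0.8, frac_par2 = 0.3),
               "sum above 1")
  expect_error(sim_config(circ_attenuation = 1.5), "circ_attenuation")
  expect_error(sim_config(karyotypes = character(0)), "non-empty")
  expect_error(sim_config(karyotypes = "48XXXX"), "unknown karyotype")
  expect_error(sim_config(n_per_group = 0), "n_per_group")
})

test_that("annotation region-class counts equal the rounded fractions", {
  cfg <- sim_config(n_circ = 100, seed = 1)
  ann <- generate_annotation(cfg)
  tab <- table(ann$genes$region_class)
  expect_equal(unname(tab[["PAR1"]]), round(0.10 * 100))
  expect_equal(unname(tab[["PAR2"]]), round(0.04 * 100))
  expect_equal(unname(tab[["chrX_escape"]]), round(0.06 * 100))
  expect_equal(unname(tab[["chrY"]]), round(0.02 * 100))
  expect_equal(sum(tab), 100)
})

test_that("a zero PAR1 fraction yields no PAR1 genes", {
  ann <- generate_annotation(tiny_config(frac_par1 = 0))
  expect_false("PAR1" %in% ann$genes$region_class)
})

test_that("every PAR gene lies wholly inside the printed interval", {
  ann <- generate_annotation(sim_config(n_circ = 400, frac_par1 = 0.3,
                                        frac_par2 = 0.1, seed = 2))
  pr <- par_regions()
  for (cls in c("PAR1", "PAR2")) {
    g <- ann$genes[ann$genes$region_class == cls, ]
    expect_true(all(g$chrom == "chrX"))
    expect_true(all(g$start + 1 >= pr[[cls]][1]))   # printed 1-based start
    expect_true(all(g$end <= pr[[cls]][2]))
  }
  # exons sit within their gene bounds
  ex <- ann$exons
  g <- ann$genes[match(ex$gene_id, ann$genes$gene_id), ]
  expect_true(all(ex$start >= g$start & ex$end <= g$end))
})

test_that("cohort arithmetic, copy counts, and determinism hold", {
  cfg <- sim_config(n_per_group = 3, seed = 9)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 36)                       # 3 x 4 karyotypes x 3 tissues
  expect_equal(length(unique(coh$subject_id)), 12)
  xxy <- coh[coh$karyotype == "47XXY", ][1, ]
  expect_equal(c(xxy$nX, xxy$nY), c(2L, 1L))
  x45 <- coh[coh$karyotype == "45X", ][1, ]
  expect_equal(c(x45$nX, x45$nY), c(1L, 0L))
  expect_identical(coh, generate_cohort(cfg))
  expect_true(all(table(coh$batch) > 0))
})

test_that("identical config and seed reproduce identical truth", {
  cfg <- tiny_config()
  t1 <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg), cfg)
  t2 <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg), cfg)
  expect_identical(t1$true_circ_counts, t2$true_circ_counts)
  expect_identical(t1$catalogue, t2$catalogue)
})

test_that("PAR dosage converges to the copy ratio at large n", {
  # alpha = 1, Poisson noise, no batch effect, fixed library size:
  # 47,XXY / 46,XY group means of PAR1 circRNAs converge to 3/2
  cfg <- sim_config(n_per_group = 200, karyotypes = c("46XY", "47XXY"),
                    tissues = "blood", n_circ = 60, dispersion = 0,
                    batch_sd = 0, circ_attenuation = 1,
                    lib_size_range = c(1e6, 1e6), seed = 5)
  coh <- generate_cohort(cfg)
  truth <- simulate_counts(generate_annotation(cfg), coh, cfg)
  par1 <- truth$circ_features$key[truth$circ_features$region_class == "PAR1"]
  g1 <- coh$sample_id[coh$karyotype == "47XXY"]
  g0 <- coh$sample_id[coh$karyotype == "46XY"]
  lr <- log2(rowMeans(truth$true_circ_counts[par1, g1]) /
               rowMeans(truth$true_circ_counts[par1, g0]))
  expect_true(all(abs(lr - log2(1.5)) < 0.05))
  expect_true(all(abs(2^lr - 1.5) < 0.02 * 1.5))
})

test_that("alpha = 0 removes the circRNA dosage effect", {
  cfg <- sim_config(n_per_group = 100, karyotypes = c("46XY", "47XXY"),
                    tissues = "blood", n_circ = 60, dispersion = 0,
                    batch_sd = 0, circ_attenuation = 0,
                    lib_size_range = c(1e6, 1e6), seed = 6)
  coh <- generate_cohort(cfg)
  truth <- simulate_counts(generate_annotation(cfg), coh, cfg)
  par1 <- truth$circ_features$key[truth$circ_features$region_class == "PAR1"]
  g1 <- coh$sample_id[coh$karyotype == "47XXY"]
  g0 <- coh$sample_id[coh$karyotype == "46XY"]
  r <- rowMeans(truth$true_circ_counts[par1, g1]) /
    rowMeans(truth$true_circ_counts[par1, g0])
  expect_true(all(abs(r - 1) < 0.1))
})

test_that("a CTL target of 1 yields zero linear counts everywhere", {
  cfg <- tiny_config(frac_ctl_one = 1)
  truth <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg),
                           cfg)
  expect_true(all(truth$true_linear_counts == 0))
  expect_true(any(truth$true_circ_counts > 0))
})

test_that("planted truth accessor reproduces the copy-model effects", {
  cfg <- tiny_config(circ_attenuation = 0.5)
  truth <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg),
                           cfg)
  expect_equal(true_dosage_log2fc(truth, "47XXY", "46XY", "PAR1", "circ"),
               0.5 * log2(1.5))
  expect_equal(true_dosage_log2fc(truth, "45X", "46XX", "PAR1", "gene"),
               -1)
  expect_equal(true_dosage_log2fc(truth, "45X", "46XX", "autosome", "circ"),
               0)
})

test_that("caller outputs conserve counts and respect the noise model", {
  cfg <- tiny_config(fp_rate_per_caller = 0, fn_rate_per_caller = 0)
  truth <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg),
                           cfg)
  dir <- withr::local_tempdir()
  truth <- emit_caller_outputs(truth, dir)
  expect_equal(nrow(truth$injected_fp), 0)
  # zero noise: all three tables contain exactly the true key set
  s <- colnames(truth$true_circ_counts)[1]
  prim <- read_primary_caller(file.path(dir, paste0(s, ".primary.tsv")))
  expect_setequal(prim$key, truth$circ_features$key)
  for (cl in c("circexplorer2", "circrna_finder")) {
    sec <- read_secondary_caller(file.path(dir, paste0(s, ".", cl, ".bed")))
    expect_setequal(sec, truth$circ_features$key)
  }
  # conservation: per-sample emitted primary counts match the truth
  for (s in colnames(truth$true_circ_counts)[1:3]) {
    prim <- read_primary_caller(file.path(dir, paste0(s, ".primary.tsv")))
    expect_equal(sum(prim$bsj_reads),
                 sum(truth$true_circ_counts[, s]))
  }
})

test_that("false-positive injections match a direct Bernoulli tally", {
  cfg <- tiny_config(fp_rate_per_caller = 0.1, fn_rate_per_caller = 0)
  truth <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg),
                           cfg)
  dir <- withr::local_tempdir()
  truth <- emit_caller_outputs(truth, dir)
  # replay the generator's RNG stream: per sample and caller, one
  # dropout draw then one injection draw over the true keys
  set.seed(circsca:::sim_seed(cfg, "callers"))
  n <- nrow(truth$circ_features)
  expected <- 0L
  for (s in colnames(truth$true_circ_counts)) {
    for (cl in c("circexplorer2", "circrna_finder")) {
      invisible(runif(n))                 # dropout stream
      inj <- sum(runif(n) < 0.1)
      expected <- expected + inj
      if (inj > 0) {
        invisible(sample(200:800, inj, replace = TRUE))
        invisible(sample(c("+", "-"), inj, replace = TRUE))
      }
    }
  }
  expect_equal(nrow(truth$injected_fp), expected)
  # injected keys are disjoint from true keys
  expect_length(intersect(truth$injected_fp$key, truth$circ_features$key), 0)
})

test_that("interaction tables plant recoverable triplets", {
  cfg <- tiny_config(n_triplets = 5, n_decoy_triplets = 2)
  truth <- simulate_counts(generate_annotation(cfg), generate_cohort(cfg),
                           cfg)
  truth <- simulate_interaction_tables(truth)
  expect_true(all(truth$circ_mirna$n_experiments >= 1))
  pt <- truth$planted_triplets
  expect_equal(sum(pt$sign_consistent), 5)
  expect_equal(sum(!pt$sign_consistent), 2)
  # consistent triplets share direction between circRNA and target
  expect_true(all((pt$circ_direction == pt$gene_direction) ==
                    pt$sign_consistent))
  # zero planted triplets give an empty planted table
  cfg0 <- tiny_config(n_triplets = 0, n_decoy_triplets = 0)
  t0 <- simulate_interaction_tables(
    simulate_counts(generate_annotation(cfg0), generate_cohort(cfg0), cfg0))
  expect_equal(nrow(t0$planted_triplets), 0)
})
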