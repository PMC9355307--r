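test_that("design matrix encodes group and batch as specified", {
  md <- flat_metadata(3, n_batches = 1)
  X <- build_design(md, contrast_spec("45X", "46XX", "blood"))
  expect_equal(dim(X), c(6L, 2L))                       # single-batch collapse
  expect_equal(unname(X[, "group"]), rep(c(1, 0), each = 3))
  # two batches: hand-written indicator coding
  md2 <- flat_metadata(3, n_batches = 2)
  X2 <- build_design(md2, contrast_spec("45X", "46XX", "blood"))
  expect_equal(unname(X2[, 3]), as.numeric(md2$batch == 2))
  expect_equal(attr(X2, "group_col"), 2L)
  # batch confounded with group is dropped with a warning
  md3 <- flat_metadata(3)
  md3$batch <- as.integer(md3$karyotype == "45X") + 1L
  expect_warning(X3 <- build_design(md3, contrast_spec("45X", "46XX",
                                                       "blood")),
                 "aliased")
  expect_equal(ncol(X3), 2L)
  expect_true("group" %in% colnames(X3))
  md4 <- flat_metadata(1)
  expect_error(build_design(md4, contrast_spec("45X", "46XX", "blood")),
               ">= 2 samples")
})

test_that("log2 CPM transform matches hand evaluation", {
  counts <- matrix(c(0, 999999), 2, 1,
                   dimnames = list(c("a", "b"), "s1"))
  y <- log_cpm_transform(counts)
  # count 0, libsize 999,999: log2(0.5 / 1e6 * 1e6) = -1
  expect_equal(y["a", 1], -1)
  expect_equal(y["b", 1], log2((999999 + 0.5) / (999999 + 1) * 1e6))
  # doubling a sample's counts leaves y unchanged up to the offsets
  c2 <- matrix(rpois(200, 50), 20, 10)
  y1 <- log_cpm_transform(c2)
  c3 <- c2; c3[, 1] <- c3[, 1] * 2
  y2 <- log_cpm_transform(c3)
  expect_true(max(abs(y2[, 1] - y1[, 1])) < 0.01)
})

test_that("precision weights are flat on homoscedastic data", {
  set.seed(101)
  md <- flat_metadata(6)
  X <- build_design(md, contrast_spec("45X", "46XX", "blood"))
  y <- matrix(rnorm(2000 * 12, mean = 8, sd = 1), 2000, 12,
              dimnames = list(paste0("f", 1:2000), md$sample_id))
  w <- estimate_precision_weights(y, X)
  expect_true(all(w > 0) && all(is.finite(w)))
  expect_lt(sd(w) / mean(w), 0.2)
  # all-equal input hits the SD floor instead of failing
  y0 <- matrix(5, 30, 12, dimnames = list(paste0("g", 1:30),
                                          md$sample_id))
  w0 <- estimate_precision_weights(y0, X)
  expect_true(all(is.finite(w0)) && all(w0 > 0))
})

test_that("a high-variance sample earns a proportionally low quality weight", {
  set.seed(102)
  md <- flat_metadata(6)
  X <- build_design(md, contrast_spec("45X", "46XX", "blood"))
  sds <- c(2, rep(1, 11))                       # sample 1 has 4x variance
  y <- sapply(seq_len(12), function(j) rnorm(2000, 8, sds[j]))
  dimnames(y) <- list(paste0("f", 1:2000), md$sample_id)
  w <- estimate_precision_weights(y, X)
  q <- attr(w, "sample_weights")
  ratio <- q[1] / mean(q[-1])
  expect_lt(abs(ratio - 0.25), 0.3 * 0.25)
})

test_that("with moderation off the statistic is the ordinary WLS t", {
  set.seed(103)
  md <- flat_metadata(5)
  X <- build_design(md, contrast_spec("45X", "46XX", "blood"))
  y <- matrix(rnorm(50 * 10, 8), 50, 10,
              dimnames = list(paste0("f", 1:50), md$sample_id))
  w <- matrix(runif(500, 0.5, 2), 50, 10)
  res <- fit_moderated(y, w, X, df_prior = 0)
  for (i in c(1, 17, 50)) {
    fit <- lm(y[i, ] ~ 0 + X, weights = w[i, ])
    sm <- summary(fit)$coefficients
    expect_equal(res$log2FC[i], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res$t[i], unname(sm[2, "t value"]), tolerance = 1e-8)
    expect_equal(res$p[i], unname(sm[2, "Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("infinite prior df pools every variance to the prior", {
  set.seed(104)
  md <- flat_metadata(4)
  X <- build_design(md, contrast_spec("45X", "46XX", "blood"))
  y <- matrix(rnorm(40 * 8, 8), 40, 8,
              dimnames = list(paste0("f", 1:40), md$sample_id))
  res <- fit_moderated(y, NULL, X, df_prior = Inf)
  expect_true(is.infinite(attr(res, "df_prior")))
  # all moderated variances equal: t / beta * sqrt(v) constant across
  # features with the same design and weights
  relvar <- (res$log2FC / res$t)^2
  expect_lt(diff(range(relvar)) / mean(relvar), 1e-8)
})

test_that("variance squeezing agrees with the reference empirical Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(105)
  s2 <- exp(rnorm(500, 0, 0.7))
  sq <- squeeze_var(s2, df = 10)
  ref <- limma::squeezeVar(s2, df = 10)
  expect_equal(sq$df_prior, ref$df.prior, tolerance = 1e-4)
  expect_equal(sq$var_prior, ref$var.prior, tolerance = 1e-4)
  expect_equal(sq$var_post, ref$var.post, tolerance = 1e-4)
})

test_that("BH adjustment reproduces the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  # hand step-up on an unsorted vector
  p <- c(0.04, 0.001, 0.02, 0.5, 0.009)
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  hand <- numeric(m); hand[o] <- pmin(q_sorted, 1)
  expect_equal(bh_adjust(p), hand)
  set.seed(1)
  pr <- runif(100)
  expect_true(all(bh_adjust(pr) >= pr))
  expect_true(all(bh_adjust(pr) <= 1))
})

test_that("gene prefilter reads 'more than three samples' strictly", {
  counts <- rbind(
    keep4 = c(rep(20, 4), rep(0, 6)),
    drop3 = c(rep(20, 3), rep(0, 7)),
    drop19 = rep(19, 10),
    keepall = rep(100, 10),
    drop0 = rep(0, 10))
  colnames(counts) <- paste0("s", 1:10)
  expect_setequal(prefilter_genes(counts), c("keep4", "keepall"))
})

test_that("significance calls are strict on both criteria", {
  res <- data.frame(feature = letters[1:4],
                    log2FC = c(1.01, 1.2, -1.2, 0.9),
                    p = c(0.001, 0.01, 0.001, 0.0001),
                    adj_p = c(0.049, 0.05, 0.01, 0.01))
  out <- call_decs(res)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("swapping case and control negates log2FC and keeps p", {
  set.seed(106)
  md <- flat_metadata(5)
  counts <- nb_counts(200, md, lfc = 1.5, n_planted = 40)
  a <- de_analysis(counts, md, contrast_spec("45X", "46XX", "blood"),
                   "circ")
  b <- de_analysis(counts, md, contrast_spec("46XX", "45X", "blood"),
                   "circ")
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("a constant batch shift is absorbed by the batch covariate", {
  set.seed(107)
  md <- flat_metadata(6, n_batches = 2)
  counts <- nb_counts(300, md)
  shifted <- counts
  shifted[, md$batch == 2] <- round(shifted[, md$batch == 2] * 4)
  a <- de_analysis(counts, md, contrast_spec("45X", "46XX", "blood"),
                   "circ")
  b <- de_analysis(shifted, md, contrast_spec("45X", "46XX", "blood"),
                   "circ")
  expect_lt(max(abs(a$log2FC - b$log2FC)), 0.2)
  expect_lt(mean(abs(a$log2FC - b$log2FC)), 0.05)
})

test_that("type-I error is calibrated on a null simulation", {
  set.seed(42)
  md <- flat_metadata(6, n_batches = 2)
  counts <- nb_counts(1000, md)
  res <- de_analysis(counts, md, contrast_spec("45X", "46XX", "blood"),
                     "circ")
  expect_gte(mean(res$p < 0.05), 0.03)
  expect_lte(mean(res$p < 0.05), 0.07)
})

test_that("planted two-fold-log2 effects are recovered with high power", {
  set.seed(43)
  md <- flat_metadata(10, case = "47XXY", control = "46XY")
  counts <- nb_counts(1000, md, lfc = 2, n_planted = 100, case = "47XXY")
  res <- de_analysis(counts, md, contrast_spec("47XXY", "46XY", "blood"),
                     "circ")
  expect_gte(mean(res$significant[1:100]), 0.8)
  expect_lte(mean(res$significant[-(1:100)]), 0.02)
})
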