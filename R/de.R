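#' Differential-expression contrast and settings
#'
#' @param case,control Karyotype labels (case minus control on the log2
#'   scale).
#' @param tissue Tissue the contrast is restricted to.
#' @return A list of class `"contrast_spec"`.
#' @export
contrast_spec <- function(case, control, tissue) {
  if (identical(case, control)) stop("case and control must differ")
  structure(list(case = case, control = control, tissue = tissue),
            class = "contrast_spec")
}

#' @rdname contrast_spec
#' @param gene_min_count Minimum count for the gene prefilter (inclusive;
#'   default 20).
#' @param gene_min_samples_strict Gene prefilter sample threshold, read
#'   strictly ("more than"; default 3, i.e. >= 4 samples).
#' @param lowess_span Span of the lowess mean-variance trend.
#' @param sd_floor Lower bound on predicted residual SD.
#' @param subject_covariate Add a fixed subject covariate when subjects
#'   appear in both groups of the contrast.
#' @export
de_settings <- function(gene_min_count = 20, gene_min_samples_strict = 3,
                        lowess_span = 0.5, sd_floor = 1e-6,
                        subject_covariate = FALSE) {
  stopifnot(gene_min_count >= 0, gene_min_samples_strict >= 0,
            lowess_span > 0, sd_floor > 0)
  structure(list(gene_min_count = gene_min_count,
                 gene_min_samples_strict = gene_min_samples_strict,
                 lowess_span = lowess_span, sd_floor = sd_floor,
                 subject_covariate = isTRUE(subject_covariate)),
            class = "de_settings")
}

#' Build the design matrix for a contrast
#'
#' Restricts the metadata to the contrast's tissue and karyotypes and
#' returns an intercept + group-indicator (case = 1) + reference-coded
#' batch design. Batch columns aliased with the group indicator (or with
#' each other) are dropped with a warning, so the returned matrix has
#' full column rank.
#'
#' @param metadata Cohort data frame (needs `sample_id`, `karyotype`,
#'   `tissue`, `batch`).
#' @param contrast A [contrast_spec()].
#' @return Design matrix with rownames = sample ids and attributes
#'   `group_col` (coefficient index of the group effect) and `samples`.
#' @export
build_design <- function(metadata, contrast) {
  md <- metadata[metadata$tissue == contrast$tissue &
                   metadata$karyotype %in% c(contrast$case,
                                             contrast$control), ]
  n_case <- sum(md$karyotype == contrast$case)
  n_ctl <- sum(md$karyotype == contrast$control)
  if (n_case < 2 || n_ctl < 2)
    stop("each group needs >= 2 samples in tissue ", contrast$tissue,
         " (case ", n_case, ", control ", n_ctl, ")")
  group <- as.integer(md$karyotype == contrast$case)
  X <- cbind("(Intercept)" = 1, group = group)
  batch <- factor(md$batch)
  if (nlevels(batch) > 1) {
    B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
    X <- add_full_rank(X, B)
  }
  rownames(X) <- md$sample_id
  attr(X, "group_col") <- match("group", colnames(X))
  attr(X, "samples") <- md$sample_id
  X
}

# append columns of B to X one at a time, keeping only those that raise
# the rank; protects the columns already in X (e.g. the group indicator)
# from being sacrificed to an aliased covariate
add_full_rank <- function(X, B) {
  dropped <- character(0)
  for (j in seq_len(ncol(B))) {
    cand <- cbind(X, B[, j, drop = FALSE])
    if (qr(cand)$rank == ncol(cand)) X <- cand
    else dropped <- c(dropped, colnames(B)[j])
  }
  if (length(dropped))
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
  X
}

#' Log2 counts-per-million transform
#'
#' `y = log2((count + offset) / (libsize + 2 * offset) * 1e6)` with
#' library size the per-sample column sum of the input matrix (the
#' standard offset transform underlying precision-weighted linear
#' modelling of counts).
#'
#' @param counts Non-negative count matrix (features x samples).
#' @param offset Pseudo-count (default 0.5, giving the `+0.5 / +1`
#'   convention).
#' @return Matrix of log2 CPM values.
#' @export
log_cpm_transform <- function(counts, offset = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  t(log2(t(counts + offset) / (lib + 2 * offset) * 1e6))
}

#' Estimate observation precision weights with sample quality weights
#'
#' Fits the mean-variance trend of count data: per-feature residual
#' SD^(1/2) is regressed on mean log2 CPM by lowess, per-observation SDs
#' are predicted at the per-feature fitted values, and the precision
#' weight is predicted SD^(-4). Per-sample quality weights (inverse mean
#' squared leverage-adjusted standardized residual) multiply the trend
#' weights, down-weighting globally noisy samples.
#'
#' @param y log2 CPM matrix (features x samples).
#' @param design Design matrix from [build_design()].
#' @param span Lowess span.
#' @param sd_floor Minimum predicted SD (guards all-equal input).
#' @return Strictly positive weight matrix, same shape as `y`; per-sample
#'   quality weights in attribute `sample_weights`.
#' @export
estimate_precision_weights <- function(y, design, span = 0.5,
                                       sd_floor = 1e-6) {
  y <- as.matrix(y)
  p <- ncol(design)
  if (nrow(y) < p + 1)
    stop("need more features than design columns to estimate the trend")
  fit <- stats::lm.fit(design, t(y))
  res <- t(fit$residuals)                     # features x samples
  df_res <- nrow(design) - p
  if (df_res <= 0) stop("no residual degrees of freedom")
  s <- sqrt(rowSums(res^2) / df_res)
  ybar <- rowMeans(y)
  lo <- stats::lowess(ybar, sqrt(pmax(s, sd_floor)), f = span)
  fitted <- t(design %*% fit$coefficients)    # features x samples
  pred <- if (length(unique(lo$x)) < 2) rep(mean(lo$y), length(fitted))
  else stats::approx(lo$x, lo$y, xout = as.vector(fitted),
                     rule = 2, ties = mean)$y
  pred <- pmax(pred, sqrt(sd_floor))
  w <- matrix(pred^-4, nrow(y), ncol(y), dimnames = dimnames(y))
  # sample quality weights: iteratively reweighted inverse relative
  # variance factors (leverage-adjusted); a plain one-pass estimate is
  # biased by cross-sample leverage when one sample is much noisier
  q <- rep(1, ncol(y))
  for (it in 1:3) {
    fw <- stats::lm.wfit(design, t(y), w = q)
    rw <- t(fw$residuals)
    hq <- stats::hat(design * sqrt(q), intercept = FALSE)
    s2w <- pmax(rowSums(sweep(rw^2, 2, q, "*")) / df_res, sd_floor^2)
    z2 <- sweep(sweep(rw^2, 2, q / (1 - hq), "*"), 1, s2w, "/")
    gam <- colMeans(z2)
    q <- q / gam
    q <- q / exp(mean(log(q)))                # geometric mean 1
  }
  w <- sweep(w, 2, q, "*")
  attr(w, "sample_weights") <- q
  w
}

# Newton inversion of the trigamma function (for the moments estimator
# of the prior degrees of freedom)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes squeeze of residual variances
#'
#' Closed-form method of moments on `log(s^2)`: with `e = log(s2) -
#' digamma(df/2) + log(df/2)`, the prior degrees of freedom solve
#' `trigamma(d0/2) = var(e) - trigamma(df/2)` and the prior variance is
#' `exp(mean(e) + digamma(d0/2) - log(d0/2))`. Posterior variances are
#' the df-weighted average of prior and observed.
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `df_prior`, `var_prior`, `var_post`.
#' @export
squeeze_var <- function(s2, df) {
  if (df <= 0) stop("residual degrees of freedom must be positive")
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- if (is.infinite(d0)) rep(s02, length(s2))
    else (d0 * s02 + df * s2) / (d0 + df)
  list(df_prior = d0, var_prior = s02, var_post = var_post)
}

#' Fit the moderated weighted linear model
#'
#' Per-feature weighted least squares on the design, followed by
#' empirical-Bayes moderation of the residual variances ([squeeze_var()]).
#' The moderated t for the contrast coefficient uses the posterior
#' variance and `df_residual + df_prior` degrees of freedom.
#'
#' @param y log2 CPM matrix (features x samples).
#' @param weights Positive observation-weight matrix (same shape), e.g.
#'   from [estimate_precision_weights()]; `NULL` for unweighted.
#' @param design Design matrix.
#' @param coef Column index of the contrast coefficient; defaults to the
#'   design's `group_col` attribute.
#' @param df_prior Override for the prior df: `0` switches moderation
#'   off (ordinary WLS t), `Inf` fully pools variances.
#' @return Data frame of class `"de_result"`: `feature`, `log2FC`,
#'   `ave_expr`, `t`, `p`, `df_total`; moderation parameters in
#'   attributes `df_prior` and `var_prior`.
#' @export
fit_moderated <- function(y, weights = NULL, design,
                          coef = attr(design, "group_col"),
                          df_prior = NULL) {
  y <- as.matrix(y)
  n <- ncol(y); p <- ncol(design)
  if (is.null(coef) || is.na(coef)) stop("contrast coefficient not found")
  if (is.null(weights)) weights <- matrix(1, nrow(y), n)
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("weights must be positive and finite")
  df_res <- n - p
  if (df_res <= 0) stop("no residual degrees of freedom")
  nf <- nrow(y)
  beta <- s2 <- vunsc <- numeric(nf)
  for (i in seq_len(nf)) {
    w <- weights[i, ]
    fit <- stats::lm.wfit(design, y[i, ], w)
    beta[i] <- fit$coefficients[coef]
    s2[i] <- sum(w * fit$residuals^2) / df_res
    R <- qr.R(fit$qr)
    XtXi <- chol2inv(R)
    # lm.wfit pivots; map coef through the pivot
    pos <- match(coef, fit$qr$pivot)
    vunsc[i] <- XtXi[pos, pos]
  }
  sq <- if (is.null(df_prior)) squeeze_var(s2, df_res)
  else if (df_prior == 0)
    list(df_prior = 0, var_prior = NA_real_, var_post = s2)
  else if (is.infinite(df_prior)) {
    full <- squeeze_var(s2, df_res)
    list(df_prior = Inf, var_prior = full$var_prior,
         var_post = rep(full$var_prior, nf))
  } else stop("df_prior override must be 0 or Inf")
  df_total <- df_res + sq$df_prior
  tstat <- beta / sqrt(sq$var_post * vunsc)
  pval <- 2 * stats::pt(-abs(tstat), df_total)
  out <- data.frame(feature = rownames(y) %||% as.character(seq_len(nf)),
                    log2FC = beta, ave_expr = rowMeans(y),
                    t = tstat, p = pval, df_total = df_total,
                    stringsAsFactors = FALSE)
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  class(out) <- c("de_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up procedure: `q_(k) = min_{j >= k} p_(j) * m / j`, capped at 1,
#' returned in input order.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Prefilter genes on raw counts
#'
#' Keeps a gene when it has at least `gene_min_count` counts in strictly
#' more than `gene_min_samples_strict` samples (default: >= 20 counts in
#' >= 4 samples).
#'
#' @param counts Gene count matrix (genes x samples).
#' @param settings A [de_settings()].
#' @return Character vector of kept gene ids.
#' @export
prefilter_genes <- function(counts, settings = de_settings()) {
  keep <- rowSums(counts >= settings$gene_min_count) >
    settings$gene_min_samples_strict
  rownames(counts)[keep]
}

#' Call differentially expressed features
#'
#' Strict thresholds on both criteria: adjusted p below `alpha` and
#' absolute log2 fold change above `lfc`. For genes, pass `lfc = 0` to
#' use the adjusted-p rule alone.
#'
#' @param results A `"de_result"` data frame carrying an `adj_p` column
#'   (see [de_analysis()]), or any frame with `log2FC` and `adj_p`.
#' @param lfc Fold-change threshold on the log2 scale (strict; default 1).
#' @param alpha Adjusted-p threshold (strict; default 0.05).
#' @return `results` with a logical `significant` column.
#' @export
call_decs <- function(results, lfc = 1, alpha = 0.05) {
  if (is.null(results$adj_p)) results$adj_p <- bh_adjust(results$p)
  results$significant <- results$adj_p < alpha & abs(results$log2FC) > lfc
  results
}

#' One-stop differential expression for a contrast
#'
#' Builds the design, log2-CPM-transforms the counts, estimates precision
#' and sample quality weights, fits the moderated model, and applies the
#' feature-type significance rule: adjusted p < 0.05 and |log2FC| > 1 for
#' circRNAs, adjusted p < 0.05 alone for genes (with the count prefilter
#' applied first).
#'
#' @param counts Raw count matrix (features x samples).
#' @param metadata Cohort data frame.
#' @param contrast A [contrast_spec()].
#' @param feature_type `"circ"` or `"gene"`.
#' @param settings A [de_settings()].
#' @return A `"de_result"` data frame with `adj_p` and `significant`.
#' @export
de_analysis <- function(counts, metadata, contrast,
                        feature_type = c("circ", "gene"),
                        settings = de_settings()) {
  feature_type <- match.arg(feature_type)
  design <- build_design(metadata, contrast)
  counts <- counts[, attr(design, "samples"), drop = FALSE]
  if (feature_type == "gene")
    counts <- counts[prefilter_genes(counts, settings), , drop = FALSE]
  if (settings$subject_covariate) {
    md <- metadata[match(rownames(design), metadata$sample_id), ]
    subj <- factor(md$subject_id)
    if (nlevels(subj) < length(subj)) {
      S <- stats::model.matrix(~subj)[, -1, drop = FALSE]
      Xnew <- suppressWarnings(add_full_rank(design, S))
      attr(Xnew, "group_col") <- match("group", colnames(Xnew))
      attr(Xnew, "samples") <- attr(design, "samples")
      design <- Xnew
    }
  }
  y <- log_cpm_transform(counts)
  w <- estimate_precision_weights(y, design, span = settings$lowess_span,
                                  sd_floor = settings$sd_floor)
  res <- fit_moderated(y, w, design)
  res$adj_p <- bh_adjust(res$p)
  res <- call_decs(res, lfc = if (feature_type == "circ") 1 else 0)
  attr(res, "contrast") <- contrast
  res
}
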