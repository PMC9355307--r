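#' Generate a synthetic gene/exon annotation
#'
#' Lays out non-overlapping multi-exon genes on five autosomes, non-PAR
#' chrX (split into XCI-escape and XCI-inactivated), non-PAR chrY, and the
#' two pseudoautosomal regions of chrX. PAR genes are packed so that every
#' gene lies wholly inside the printed PAR interval. Region-class counts
#' are the rounded configured fractions of `n_circ` (remainder autosomal),
#' one host-gene slot per circRNA.
#'
#' @param config A [sim_config()].
#' @return An object of class `"sca_annotation"`: a list with data frames
#'   `genes` (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `region_class`) and `exons` (`gene_id`, `exon`, `start`, `end`).
#'   Coordinates are 0-based half-open.
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "annotation"))
  n <- config$n_circ
  n_par1 <- round(config$frac_par1 * n)
  n_par2 <- round(config$frac_par2 * n)
  n_esc  <- round(config$frac_chrX_escape * n)
  n_ina  <- round(config$frac_chrX_inactive * n)
  n_y    <- round(config$frac_chrY * n)
  n_auto <- n - (n_par1 + n_par2 + n_esc + n_ina + n_y)
  if (n_auto < 0) stop("region-class fractions sum above 1")

  pr <- par_regions()
  blocks <- list()
  add <- function(nn, chrom, class, from, to = Inf, compact = FALSE) {
    if (nn == 0) return(invisible(NULL))
    blocks[[length(blocks) + 1L]] <<-
      place_genes(nn, chrom, class, from, to, compact)
  }
  # PAR intervals: printed 1-based inclusive -> internal 0-based half-open
  add(n_par1, "chrX", "PAR1", pr$PAR1[1] - 1L, pr$PAR1[2], compact = TRUE)
  add(n_par2, "chrX", "PAR2", pr$PAR2[1] - 1L, pr$PAR2[2], compact = TRUE)
  add(n_esc, "chrX", "chrX_escape", 3e6)
  add(n_ina, "chrX", "chrX_inactive", 3e6 + 5e7)
  add(n_y, "chrY", "chrY", 3e6)
  if (n_auto > 0) {
    autos <- paste0("chr", 1:5)
    per <- diff(round(seq(0, n_auto, length.out = length(autos) + 1)))
    for (i in seq_along(autos)) add(per[i], autos[i], "autosome", 1e4)
  }

  genes <- do.call(rbind, lapply(blocks, `[[`, "genes"))
  exons <- do.call(rbind, lapply(blocks, `[[`, "exons"))
  # stable ids in emission order
  ids <- sprintf("G%05d", seq_len(nrow(genes)))
  exons$gene_id <- ids[match(exons$gene_id, genes$gene_id)]
  genes$gene_id <- ids
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "sca_annotation")
}

# sequential non-overlapping gene placement within [from, to)
place_genes <- function(n, chrom, class, from, to = Inf, compact = FALSE) {
  if (compact) {
    exon_len <- 100:200; intron_len <- 100:300; gap <- 1500:3000
  } else {
    exon_len <- 150:300; intron_len <- 500:1500; gap <- 5000:10000
  }
  genes <- vector("list", n); exons <- vector("list", n)
  cursor <- from
  for (i in seq_len(n)) {
    cursor <- cursor + sample(gap, 1L)
    k <- sample(4:8, 1L)
    lens <- sample(exon_len, k, replace = TRUE)
    ints <- if (k > 1) sample(intron_len, k - 1L, replace = TRUE) else integer(0)
    starts <- cursor + cumsum(c(0L, lens[-k] + ints))
    ends <- starts + lens
    if (ends[k] > to)
      stop("region ", class, " on ", chrom,
           " cannot hold the requested number of genes")
    gid <- paste0(class, "_", chrom, "_", i)
    genes[[i]] <- data.frame(
      gene_id = gid, chrom = chrom,
      strand = sample(c("+", "-"), 1L),
      start = starts[1L], end = ends[k], region_class = class,
      stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, exon = seq_len(k),
                             start = starts, end = ends,
                             stringsAsFactors = FALSE)
    cursor <- ends[k]
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

#' Generate the study cohort
#'
#' One subject row per karyotype slot, sampled in every configured tissue;
#' subjects carry stable ids so paired designs across tissues are
#' possible. Batches are assigned round-robin over samples. Karyotype
#' fixes the sex-chromosome counts: 45,X = (1X, 0Y); 46,XX = (2, 0);
#' 46,XY = (1, 1); 47,XXY = (2, 1).
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `sample_id`, `subject_id`,
#'   `karyotype`, `tissue`, `batch`, `nX`, `nY`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "cohort"))
  subj <- expand.grid(rep = seq_len(config$n_per_group),
                      karyotype = config$karyotypes,
                      stringsAsFactors = FALSE)
  subj$subject_id <- sprintf("S%03d", seq_len(nrow(subj)))
  cohort <- merge(subj, data.frame(tissue = config$tissues),
                  by = NULL, sort = FALSE)
  cohort <- cohort[order(cohort$subject_id, cohort$tissue), ]
  cohort$sample_id <- paste(cohort$subject_id, cohort$tissue, sep = "_")
  cohort$batch <- rep_len(seq_len(config$n_batches), nrow(cohort))
  cp <- karyotype_copies(cohort$karyotype)
  cohort$nX <- cp$nX
  cohort$nY <- cp$nY
  rownames(cohort) <- NULL
  cohort[, c("sample_id", "subject_id", "karyotype", "tissue",
             "batch", "nX", "nY")]
}

# sex-chromosome copy count of a region class given (nX, nY);
# inactivated chrX genes have one active copy regardless of karyotype
region_copies <- function(region_class, nX, nY) {
  switch(region_class,
         PAR1 = , PAR2 = nX + nY,
         chrX_escape = nX,
         chrX_inactive = 2L,
         chrY = nY,
         autosome = 2L,
         stop("unknown region class: ", region_class))
}

#' Simulate ground-truth circRNA, linear-junction, and gene counts
#'
#' Counts follow a negative-binomial model on a log2-linear predictor:
#' per-feature baseline, tissue effect, batch effect, per-sample library
#' size, and a karyotype dosage multiplier `(copies/2)^alpha` for
#' circRNAs and `(copies/2)` for mRNAs (when `mrna_dosage_full`), with
#' copies = nX + nY for PAR features, nX for XCI-escape features, nY for
#' chrY, and copy-invariant otherwise. Library scaling targets the drawn
#' per-sample total using baseline (dosage-free) intensities, so group
#' mean ratios of dosed features converge to the copy ratio. Linear
#' junction counts are drawn so each feature's configured
#' circular-to-linear target holds in expectation
#' (`linear mean = 2 * circ mean * (1 - CTL) / CTL`; a target of 1 yields
#' zero linear counts everywhere).
#'
#' @param annotation From [generate_annotation()].
#' @param cohort From [generate_cohort()].
#' @param config The same [sim_config()] used for both.
#' @return An object of class `"sca_truth"`: config, annotation, cohort,
#'   `circ_features` (key, coordinates, host, origin, exon count, region
#'   class, CTL target, dosage exponent), count matrices
#'   `true_circ_counts`, `true_linear_counts`, `true_gene_counts`, and the
#'   known-circRNA `catalogue`.
#' @export
simulate_counts <- function(annotation, cohort, config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "counts"))
  genes <- annotation$genes
  exons <- annotation$exons
  n <- nrow(genes)
  ns <- nrow(cohort)

  # --- circRNA features: one per host-gene slot -------------------------
  origin <- rep("exonic", n)
  auto_idx <- which(genes$region_class == "autosome")
  n_intronic <- min(round(config$frac_intronic * n), length(auto_idx))
  n_intergenic <- min(round(config$frac_intergenic * n),
                      length(auto_idx) - n_intronic)
  origin[auto_idx[seq_len(n_intronic)]] <- "intronic"
  origin[auto_idx[n_intronic + seq_len(n_intergenic)]] <- "intergenic"

  feat <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, ]
    k <- nrow(ex)
    if (origin[i] == "exonic") {
      a <- sample(seq_len(k), 1L)
      b <- if (a < k) sample(a:k, 1L) else k
      st <- ex$start[a]; en <- ex$end[b]
      ec <- b - a + 1L
      sl <- sum(ex$end[a:b] - ex$start[a:b])
      host <- g$gene_id
    } else if (origin[i] == "intronic") {
      r <- sample(seq_len(k - 1L), 1L)
      st <- ex$end[r] + 20L; en <- ex$start[r + 1L] - 20L
      if (en - st < 50L) { st <- ex$end[r] + 5L; en <- ex$start[r + 1L] - 5L }
      ec <- 0L; sl <- en - st; host <- g$gene_id
    } else { # intergenic: in the guaranteed gap downstream of the gene
      st <- g$end + 500L; en <- st + sample(300:900, 1L)
      ec <- 0L; sl <- en - st; host <- NA_character_
    }
    feat[[i]] <- data.frame(
      chrom = g$chrom, start = st, end = en, strand = g$strand,
      gene_id = host, origin = origin[i], exon_count = ec,
      spliced_length = sl, region_class = g$region_class,
      stringsAsFactors = FALSE)
  }
  feat <- do.call(rbind, feat)
  feat$key <- bsj_key(feat$chrom, feat$start, feat$end, feat$strand)
  if (anyDuplicated(feat$key)) {
    dup <- duplicated(feat$key)
    feat$start[dup] <- feat$start[dup] + 1L   # extremely rare collision guard
    feat$key <- bsj_key(feat$chrom, feat$start, feat$end, feat$strand)
  }
  u <- runif(n)
  feat$ctl_target <- ifelse(u < config$frac_ctl_one, 1,
                            rbeta(n, config$ctl_beta[1], config$ctl_beta[2]))
  feat$base_log2 <- rnorm(n, config$mean_log_expression,
                          config$sd_log_expression)
  feat$dose_exponent <- ifelse(
    feat$region_class %in% c("PAR1", "PAR2", "chrX_escape", "chrY"),
    config$circ_attenuation, 0)

  # --- shared effect machinery -----------------------------------------
  tissues <- sort(unique(cohort$tissue))
  batches <- sort(unique(cohort$batch))
  draw_counts <- function(mu) {
    cnt <- if (config$dispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    else rpois(length(mu), mu)
    matrix(cnt, nrow = nrow(mu), ncol = ncol(mu),
           dimnames = dimnames(mu))
  }
  mu_matrix <- function(base_log2, region_class, exponent) {
    nf <- length(base_log2)
    te <- matrix(rnorm(nf * length(tissues), 0, config$tissue_sd),
                 nf, dimnames = list(NULL, tissues))
    be <- matrix(rnorm(nf * length(batches), 0, config$batch_sd),
                 nf, dimnames = list(NULL, as.character(batches)))
    w <- 2^(base_log2 +
              te[, cohort$tissue, drop = FALSE] +
              be[, as.character(cohort$batch), drop = FALSE])
    copies <- vapply(seq_len(nf), function(i)
      vapply(seq_len(ns), function(j)
        region_copies(region_class[i], cohort$nX[j], cohort$nY[j]),
        numeric(1)), numeric(ns))
    copies <- t(copies)
    dose <- (copies / 2)^rep(exponent, ns)
    dose[copies == 0] <- 0   # no template chromosome, no expression
    dim(dose) <- dim(w)
    lib <- runif(ns, config$lib_size_range[1], config$lib_size_range[2])
    scal <- lib / colSums(w)      # dosage-free scaling: karyotype-neutral
    mu <- w * dose * rep(scal, each = nf)
    colnames(mu) <- cohort$sample_id
    mu
  }

  mu_circ <- mu_matrix(feat$base_log2, feat$region_class, feat$dose_exponent)
  rownames(mu_circ) <- feat$key
  circ_counts <- draw_counts(mu_circ)

  mu_lin <- mu_circ * 2 * (1 - feat$ctl_target) /
    ifelse(feat$ctl_target > 0, feat$ctl_target, 1)
  mu_lin[feat$ctl_target == 0, ] <- 0
  lin_counts <- draw_counts(mu_lin)
  lin_counts[feat$ctl_target == 1, ] <- 0L

  gene_exponent <- ifelse(
    genes$region_class %in% c("PAR1", "PAR2", "chrX_escape", "chrY"),
    if (config$mrna_dosage_full) 1 else config$circ_attenuation, 0)
  gene_base <- rnorm(n, config$gene_mean_log_expression,
                     config$sd_log_expression)
  mu_gene <- mu_matrix(gene_base, genes$region_class, gene_exponent)
  rownames(mu_gene) <- genes$gene_id
  gene_counts <- draw_counts(mu_gene)

  # --- known-circRNA catalogue -----------------------------------------
  n_known <- round(config$frac_known * n)
  known_idx <- sort(sample(n, n_known))
  cat_true <- feat[known_idx, c("chrom", "start", "end", "strand", "key")]
  n_decoy <- min(20L, n)
  decoy <- feat[sample(n, n_decoy), c("chrom", "start", "end", "strand")]
  decoy$start <- decoy$start + 10L
  decoy$end <- decoy$end + 10L
  decoy$key <- bsj_key(decoy$chrom, decoy$start, decoy$end, decoy$strand)
  decoy <- decoy[!decoy$key %in% feat$key, ]
  catalogue <- rbind(cat_true, decoy)
  catalogue$known_id <- sprintf("hsa_circ_%07d", seq_len(nrow(catalogue)))
  rownames(catalogue) <- NULL

  structure(list(
    config = config, annotation = annotation, cohort = cohort,
    circ_features = feat,
    true_circ_counts = circ_matrix(circ_counts, "raw"),
    true_linear_counts = lin_counts,
    true_gene_counts = gene_counts,
    catalogue = catalogue[, c("known_id", "chrom", "start", "end",
                              "strand", "key")]
  ), class = "sca_truth")
}

#' Write per-sample caller output files
#'
#' Emits, per sample, one count-bearing primary-caller table (TSV, printed
#' 1-based inclusive coordinates, columns `key`, `chrom`, `start`, `end`,
#' `strand`, `bsj_reads`, `linear_reads`) and one detection-only BED6
#' file per secondary caller (0-based half-open). Every true key appears
#' in the primary table; each secondary caller drops true keys with
#' probability `fn_rate_per_caller` and injects disjoint false keys with
#' per-true-key probability `fp_rate_per_caller`. Injected keys are
#' recorded in the returned truth object.
#'
#' @param truth An `"sca_truth"` from [simulate_counts()].
#' @param dir Output directory (created if missing).
#' @param config Simulation config; defaults to the one inside `truth`.
#' @param callers Names of the secondary callers.
#' @return `truth`, augmented with `caller_files` (one row per emitted
#'   file) and `injected_fp` (sample, caller, injected key).
#' @export
emit_caller_outputs <- function(truth, dir, config = truth$config,
                                callers = c("circexplorer2",
                                            "circrna_finder")) {
  set.seed(sim_seed(config, "callers"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- truth$circ_features
  samples <- colnames(truth$true_circ_counts)
  files <- list(); injected <- list(); fp_counter <- 0L
  for (s in samples) {
    prim <- data.frame(
      key = feat$key, chrom = feat$chrom,
      start = feat$start + 1L, end = feat$end, strand = feat$strand,
      bsj_reads = truth$true_circ_counts[, s],
      linear_reads = truth$true_linear_counts[, s])
    ppath <- file.path(dir, paste0(s, ".primary.tsv"))
    utils::write.table(prim, ppath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[length(files) + 1L]] <-
      data.frame(sample_id = s, caller = "primary", role = "primary",
                 path = ppath)
    for (cl in callers) {
      keep <- runif(nrow(feat)) >= config$fn_rate_per_caller
      inject <- runif(nrow(feat)) < config$fp_rate_per_caller
      n_inj <- sum(inject)
      bed <- feat[keep, c("chrom", "start", "end", "strand")]
      if (n_inj > 0) {
        st <- 5e7 + (fp_counter + seq_len(n_inj)) * 1000L
        fp_counter <- fp_counter + n_inj
        fp <- data.frame(chrom = "chr1", start = st,
                         end = st + sample(200:800, n_inj, replace = TRUE),
                         strand = sample(c("+", "-"), n_inj, replace = TRUE))
        injected[[length(injected) + 1L]] <- data.frame(
          sample_id = s, caller = cl,
          key = bsj_key(fp$chrom, fp$start, fp$end, fp$strand))
        bed <- rbind(bed, fp)
      }
      bed6 <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                         name = paste0(cl, "_", seq_len(nrow(bed)),
                                       recycle0 = TRUE),
                         score = rep(0L, nrow(bed)), strand = bed$strand)
      bpath <- file.path(dir, paste0(s, ".", cl, ".bed"))
      utils::write.table(bed6, bpath, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      files[[length(files) + 1L]] <-
        data.frame(sample_id = s, caller = cl, role = "secondary",
                   path = bpath)
    }
  }
  truth$caller_files <- do.call(rbind, files)
  truth$injected_fp <- if (length(injected)) do.call(rbind, injected)
    else data.frame(sample_id = character(), caller = character(),
                    key = character())
  truth
}

#' Simulate circRNA-miRNA and miRNA-mRNA interaction tables
#'
#' Plants `n_triplets` sign-consistent sponge triplets (circRNA and mRNA
#' share a regulation direction; the intervening miRNA is unobserved),
#' `n_decoy_triplets` sign-inconsistent decoys that still pass the CLIP
#' evidence filter, and `n_noise_edges` random circRNA-miRNA edges whose
#' miRNA targets fall outside any differential/PAR gene set. CLIP
#' experiment counts are >= 2 for planted/decoy edges and 1-4 for noise,
#' so the evidence filter at threshold 2 has both passing and failing
#' edges.
#'
#' @param truth An `"sca_truth"` (catalogue and annotation are used).
#' @param config Simulation config; defaults to the one inside `truth`.
#' @return `truth` augmented with `circ_mirna` (circ_id, mirna,
#'   n_experiments), `mirna_targets` (mirna, gene_id), and
#'   `planted_triplets` (known_id, circ_key, mirna, gene_id, direction,
#'   sign_consistent).
#' @export
simulate_interaction_tables <- function(truth, config = truth$config) {
  set.seed(sim_seed(config, "interactions"))
  n_planted <- config$n_triplets
  n_decoy <- config$n_decoy_triplets
  known <- truth$catalogue[truth$catalogue$key %in% truth$circ_features$key, ]
  need <- n_planted + n_decoy
  if (nrow(known) < need)
    stop("catalogue holds ", nrow(known),
         " known true circRNAs; need ", need, " for planted triplets")
  genes <- truth$annotation$genes$gene_id
  pick_circ <- if (need > 0) sample(nrow(known), need) else integer(0)
  mirnas <- sprintf("hsa-miR-%d-5p", 100 + seq_len(need))
  tgt <- sample(genes, need)

  cm <- list(); mt <- list(); planted <- list()
  for (i in seq_len(need)) {
    consistent <- i <= n_planted
    dir_circ <- sample(c("up", "down"), 1L)
    dir_gene <- if (consistent) dir_circ
      else setdiff(c("up", "down"), dir_circ)
    cm[[i]] <- data.frame(circ_id = known$known_id[pick_circ[i]],
                          mirna = mirnas[i],
                          n_experiments = sample(2:5, 1L))
    mt[[i]] <- data.frame(mirna = mirnas[i], gene_id = tgt[i])
    planted[[i]] <- data.frame(
      known_id = known$known_id[pick_circ[i]],
      circ_key = known$key[pick_circ[i]],
      mirna = mirnas[i], gene_id = tgt[i],
      circ_direction = dir_circ, gene_direction = dir_gene,
      sign_consistent = consistent)
  }
  n_noise <- config$n_noise_edges
  if (n_noise > 0) {
    pool <- setdiff(seq_len(nrow(known)), pick_circ)
    if (!length(pool)) pool <- seq_len(nrow(known))
    noise_mir <- sprintf("hsa-miR-%d-3p", 900 + seq_len(n_noise))
    cm[[length(cm) + 1L]] <- data.frame(
      circ_id = known$known_id[sample(pool, n_noise, replace = TRUE)],
      mirna = noise_mir,
      n_experiments = sample(1:4, n_noise, replace = TRUE))
    mt[[length(mt) + 1L]] <- data.frame(
      mirna = noise_mir,
      gene_id = sample(genes, n_noise, replace = TRUE))
  }
  truth$circ_mirna <- do.call(rbind, cm)
  truth$mirna_targets <- do.call(rbind, mt)
  truth$planted_triplets <- if (length(planted)) do.call(rbind, planted)
    else data.frame()
  rownames(truth$circ_mirna) <- rownames(truth$mirna_targets) <- NULL
  truth
}

#' Theoretical log2 fold change planted for a truth feature
#'
#' Convenience accessor used in parameter-recovery tests: the generator's
#' own expected log2 fold change for a feature class under a contrast,
#' i.e. `exponent * log2(copies_case / copies_control)`.
#'
#' @param truth An `"sca_truth"`.
#' @param case,control Karyotype labels.
#' @param region_class Feature region class.
#' @param type `"circ"` or `"gene"`.
#' @return The planted log2 fold change.
#' @export
true_dosage_log2fc <- function(truth, case, control, region_class,
                               type = c("circ", "gene")) {
  type <- match.arg(type)
  cfg <- truth$config
  expo <- if (region_class %in% c("PAR1", "PAR2", "chrX_escape", "chrY")) {
    if (type == "circ") cfg$circ_attenuation
    else if (cfg$mrna_dosage_full) 1 else cfg$circ_attenuation
  } else 0
  a <- karyotype_copies(case); b <- karyotype_copies(control)
  ca <- region_copies(region_class, a$nX, a$nY)
  cb <- region_copies(region_class, b$nX, b$nY)
  if (cb == 0) stop("control karyotype has zero copies for ", region_class)
  expo * log2(ca / cb)
}
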