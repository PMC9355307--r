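#' Read a pipeline run configuration
#'
#' A YAML file with top-level keys `seed`, `outdir`, and optional blocks
#' `simulate` (fields of [sim_config()]), `thresholds` (fields of
#' [filter_thresholds()]), `de` (fields of [de_settings()]), `network`
#' (`min_experiments`), and `contrasts` (list of `case`/`control`
#' pairs). Missing blocks fall back to package defaults.
#'
#' @param path Path to the YAML config.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "circsca_out"
  if (is.null(cfg$contrasts))
    cfg$contrasts <- list(list(case = "45X", control = "46XX"),
                          list(case = "47XXY", control = "46XY"))
  class(cfg) <- "run_config"
  cfg
}

run_thresholds <- function(config) {
  do.call(filter_thresholds, config$thresholds %||% list())
}

run_de_settings <- function(config) {
  do.call(de_settings, config$de %||% list())
}

log_stage <- function(...) message("[circsca] ", ...)

#' Run the analysis pipeline
#'
#' Orchestrates all stages over a run configuration: `simulate` (synthetic
#' study + caller files), `consensus` (read callers, consensus rule,
#' circCPM, expression filter, CTL table), `annotate`, `de`
#' (circRNA and gene differential expression per contrast and tissue),
#' `dosage` (collective PAR shifts, stoichiometry, attenuation),
#' `network` (ceRNA construction and export), and `report`. Every stage
#' persists its outputs as TSV under `outdir/<stage>/` and logs the
#' thresholds applied with before/after feature counts; re-running a
#' stage from persisted intermediates reproduces identical outputs.
#'
#' @param config A `"run_config"` (or path to one).
#' @param stage One of `"simulate"`, `"consensus"`, `"annotate"`, `"de"`,
#'   `"dosage"`, `"network"`, `"report"`, `"all"`.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, stage = "all") {
  if (is.character(config)) config <- read_run_config(config)
  stage <- match.arg(stage, c("simulate", "consensus", "annotate", "de",
                              "dosage", "network", "report", "all"))
  stages <- if (stage == "all")
    c("simulate", "consensus", "annotate", "de", "dosage", "network",
      "report") else stage
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out, "run_config.yaml"))
  for (st in stages) {
    log_stage("stage: ", st)
    switch(st,
           simulate = stage_simulate(config),
           consensus = stage_consensus(config),
           annotate = stage_annotate(config),
           de = stage_de(config),
           dosage = stage_dosage(config),
           network = stage_network(config),
           report = summary_report(out))
  }
  invisible(out)
}

stage_simulate <- function(config) {
  out <- config$outdir
  sdir <- file.path(out, "simulate")
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config,
                  c(config$simulate %||% list(), list(seed = config$seed)))
  ann <- generate_annotation(scfg)
  cohort <- generate_cohort(scfg)
  truth <- simulate_counts(ann, cohort, scfg)
  truth <- emit_caller_outputs(truth, file.path(out, "callers"))
  truth <- simulate_interaction_tables(truth)
  log_stage("simulated ", nrow(truth$circ_features), " circRNAs over ",
            nrow(cohort), " samples; caller files in ",
            file.path(out, "callers"))
  write_annotation_tsv(ann, file.path(sdir, "annotation.tsv"))
  utils::write.table(cohort, file.path(sdir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_catalogue_tsv(truth$catalogue, file.path(sdir, "catalogue.tsv"))
  write_matrix_tsv(truth$true_gene_counts,
                   file.path(sdir, "gene_counts.tsv"), "gene_id")
  utils::write.table(truth$circ_features,
                     file.path(sdir, "circ_features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$circ_mirna, file.path(sdir, "circ_mirna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$mirna_targets,
                     file.path(sdir, "mirna_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$planted_triplets,
                     file.path(sdir, "planted_triplets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}

stage_consensus <- function(config) {
  out <- config$outdir
  cdir <- file.path(out, "consensus")
  dir.create(cdir, showWarnings = FALSE, recursive = TRUE)
  thr <- run_thresholds(config)
  caller_dir <- file.path(out, "callers")
  prim_files <- list.files(caller_dir, "\\.primary\\.tsv$",
                           full.names = TRUE)
  if (!length(prim_files))
    stop("no primary caller files under ", caller_dir)
  samples <- sub("\\.primary\\.tsv$", "", basename(prim_files))
  records <- lapply(prim_files, read_primary_caller)
  names(records) <- samples
  raw <- circ_count_matrix(records)
  linear <- circ_count_matrix(records, keys = rownames(raw),
                              value = "linear_reads")
  bed_files <- list.files(caller_dir, "\\.bed$", full.names = TRUE)
  caller_of <- sub("^[^.]+\\.", "", sub("\\.bed$", "", basename(bed_files)))
  secondary <- lapply(split(bed_files, caller_of), function(fs)
    unique(unlist(lapply(fs, read_secondary_caller))))
  kept <- consensus_filter(rownames(raw), secondary, thr)
  log_stage("consensus (>= ", thr$consensus_min_secondary,
            " secondary caller): ", nrow(raw), " -> ", length(kept),
            " junctions")
  raw <- raw[kept, , drop = FALSE]
  linear <- linear[kept, , drop = FALSE]
  cpm <- circ_cpm(circ_matrix(raw, "raw"))
  expressed <- expression_filter(cpm, thr)
  log_stage("expression filter (>= ", thr$min_circCPM, " circCPM in >= ",
            thr$min_samples, " samples): ", length(kept), " -> ",
            length(expressed), " junctions")
  write_matrix_tsv(raw[expressed, , drop = FALSE],
                   file.path(cdir, "filtered_raw.tsv"))
  write_matrix_tsv(cpm[expressed, , drop = FALSE],
                   file.path(cdir, "circ_cpm.tsv"))
  utils::write.table(ctl_table(raw[expressed, , drop = FALSE],
                               linear[expressed, , drop = FALSE]),
                     file.path(cdir, "ctl.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(expressed, file.path(cdir, "kept_keys.txt"))
  invisible(expressed)
}

stage_annotate <- function(config) {
  out <- config$outdir
  adir <- file.path(out, "annotate")
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  keys <- readLines(file.path(out, "consensus", "kept_keys.txt"))
  ann <- read_annotation_tsv(file.path(out, "simulate", "annotation.tsv"))
  ct <- read_catalogue_tsv(file.path(out, "simulate", "catalogue.tsv"))
  ca <- annotate_circ(keys, ann, ct)
  utils::write.table(ca, file.path(adir, "circ_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cpm <- read_matrix_tsv(file.path(out, "consensus", "circ_cpm.tsv"),
                         scale = "circCPM")
  iso <- isoforms_per_host(ca, cpm)
  utils::write.table(iso, file.path(adir, "isoforms_per_host.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ca)
}

run_contrasts <- function(config) {
  lapply(config$contrasts, function(x)
    list(case = x$case, control = x$control))
}

stage_de <- function(config) {
  out <- config$outdir
  ddir <- file.path(out, "de")
  dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
  sets <- run_de_settings(config)
  cohort <- utils::read.delim(file.path(out, "simulate", "cohort.tsv"),
                              stringsAsFactors = FALSE)
  raw <- read_matrix_tsv(file.path(out, "consensus", "filtered_raw.tsv"))
  genes <- read_matrix_tsv(file.path(out, "simulate", "gene_counts.tsv"))
  for (cs in run_contrasts(config)) {
    for (tis in unique(cohort$tissue)) {
      ctr <- contrast_spec(cs$case, cs$control, tis)
      tag <- paste0(cs$case, "_vs_", cs$control, "_", tis)
      for (ft in c("circ", "gene")) {
        counts <- if (ft == "circ") raw else genes
        res <- tryCatch(
          de_analysis(counts, cohort, ctr, feature_type = ft,
                      settings = sets),
          error = function(e) {
            log_stage("skipping ", ft, " DE for ", tag, ": ",
                      conditionMessage(e))
            NULL
          })
        if (is.null(res)) next
        log_stage(ft, " DE ", tag, ": ", sum(res$significant), " of ",
                  nrow(res), " significant")
        utils::write.table(res, file.path(ddir, paste0(ft, "_", tag,
                                                       ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
}

read_de_table <- function(config, type, case, control, tissue) {
  p <- file.path(config$outdir, "de",
                 paste0(type, "_", case, "_vs_", control, "_", tissue,
                        ".tsv"))
  if (!file.exists(p)) return(NULL)
  utils::read.delim(p, stringsAsFactors = FALSE)
}

stage_dosage <- function(config) {
  out <- config$outdir
  gdir <- file.path(out, "dosage")
  dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
  ca <- utils::read.delim(file.path(out, "annotate", "circ_annotation.tsv"),
                          stringsAsFactors = FALSE)
  cohort <- utils::read.delim(file.path(out, "simulate", "cohort.tsv"),
                              stringsAsFactors = FALSE)
  shifts <- list(); atten <- list()
  for (cs in run_contrasts(config)) {
    tag <- paste0(cs$case, "_vs_", cs$control)
    for (tis in unique(cohort$tissue)) {
      cd <- read_de_table(config, "circ", cs$case, cs$control, tis)
      if (is.null(cd)) next
      sh <- tryCatch(collective_par_shift(cd, ca, tis, tag),
                     error = function(e) NULL)
      if (!is.null(sh)) {
        sh$expected_log2fc <- expected_dosage_log2fc(cs$case, cs$control,
                                                     "PAR1")
        shifts[[length(shifts) + 1L]] <- sh
      }
      gd <- read_de_table(config, "gene", cs$case, cs$control, tis)
      if (!is.null(gd)) {
        at <- tryCatch(circ_mrna_attenuation(cd, gd, ca),
                       error = function(e) NULL)
        if (!is.null(at))
          atten[[length(atten) + 1L]] <- data.frame(
            tissue = tis, contrast = tag, n_pairs = at$n,
            correlation = at$correlation, slope = at$slope)
      }
    }
  }
  if (length(shifts))
    utils::write.table(do.call(rbind, shifts),
                       file.path(gdir, "collective_shifts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(atten))
    utils::write.table(do.call(rbind, atten),
                       file.path(gdir, "attenuation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  # stoichiometry of the most expressed PAR1 circRNA, if any
  cpm <- read_matrix_tsv(file.path(out, "consensus", "circ_cpm.tsv"),
                         scale = "circCPM")
  par_keys <- intersect(ca$key[ca$par == "PAR1"], rownames(cpm))
  if (length(par_keys)) {
    top <- par_keys[which.max(rowMeans(cpm[par_keys, , drop = FALSE]))]
    sp <- stoichiometry_profile(cpm, cohort, top)
    utils::write.table(
      data.frame(key = top, karyotype = names(sp$profile),
                 mean_circCPM = sp$means, profile = sp$profile,
                 expected = sp$expected, rmsd = sp$rmsd),
      file.path(gdir, "stoichiometry.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
}

stage_network <- function(config) {
  out <- config$outdir
  ndir <- file.path(out, "network")
  dir.create(ndir, showWarnings = FALSE, recursive = TRUE)
  min_exp <- (config$network %||% list())$min_experiments %||% 2
  ca <- utils::read.delim(file.path(out, "annotate", "circ_annotation.tsv"),
                          stringsAsFactors = FALSE)
  cm <- utils::read.delim(file.path(out, "simulate", "circ_mirna.tsv"),
                          stringsAsFactors = FALSE)
  mt <- utils::read.delim(file.path(out, "simulate", "mirna_targets.tsv"),
                          stringsAsFactors = FALSE)
  genes <- read_matrix_tsv(file.path(out, "simulate", "gene_counts.tsv"))
  ann <- read_annotation_tsv(file.path(out, "simulate", "annotation.tsv"))
  expressed <- prefilter_genes(genes, run_de_settings(config))
  par_genes <- intersect(
    ann$genes$gene_id[ann$genes$region_class %in% c("PAR1", "PAR2")],
    expressed)
  cohort <- utils::read.delim(file.path(out, "simulate", "cohort.tsv"),
                              stringsAsFactors = FALSE)
  for (cs in run_contrasts(config)) {
    tag <- paste0(cs$case, "_vs_", cs$control)
    decs <- list(); degs <- list()
    for (tis in unique(cohort$tissue)) {
      cd <- read_de_table(config, "circ", cs$case, cs$control, tis)
      if (!is.null(cd)) {
        sig <- cd[cd$significant, ]
        sig$circ_id <- ca$known_id[match(sig$feature, ca$key)]
        sig <- sig[!is.na(sig$circ_id), ]
        if (nrow(sig))
          decs[[length(decs) + 1L]] <- data.frame(
            circ_id = sig$circ_id,
            direction = ifelse(sig$log2FC > 0, "up", "down"),
            log2FC = sig$log2FC)
      }
      gd <- read_de_table(config, "gene", cs$case, cs$control, tis)
      if (!is.null(gd)) {
        gs <- gd[gd$significant, ]
        if (nrow(gs))
          degs[[length(degs) + 1L]] <- data.frame(
            gene_id = gs$feature,
            direction = ifelse(gs$log2FC > 0, "up", "down"),
            log2FC = gs$log2FC)
      }
    }
    decs <- if (length(decs)) unique(do.call(rbind, decs))
      else data.frame(circ_id = character(), direction = character(),
                      log2FC = numeric())
    degs <- if (length(degs)) unique(do.call(rbind, degs))
      else data.frame(gene_id = character(), direction = character(),
                      log2FC = numeric())
    kept <- filter_circ_mirna(cm, min_exp, known_ids = ca$known_id)
    log_stage("evidence filter (>= ", min_exp, " CLIP experiments): ",
              nrow(cm), " -> ", nrow(kept), " circRNA-miRNA edges")
    net <- build_network(decs, kept, mt, degs, par_genes)
    net <- sign_consistency_filter(net)
    log_stage("network ", tag, ": ", nrow(net$nodes), " nodes, ",
              nrow(net$edges), " edges after sign filter")
    export_network(net, ndir, prefix = tag)
  }
}

#' Command-line entry point
#'
#' `circsca <stage> --config <yaml> [--seed N] [--outdir DIR]`, with
#' stage one of `simulate`, `consensus`, `annotate`, `de`, `dosage`,
#' `network`, `report`, `all`.
#'
#' @param args Character vector of arguments (defaults to the process
#'   command line).
#' @return Exit status, invisibly (0 on success).
#' @export
circsca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: circsca <simulate|consensus|annotate|de|dosage|network|",
    "report|all> --config <yaml> [--seed N] [--outdir DIR]")
  if (!length(args)) stop(usage, call. = FALSE)
  stage <- args[1]
  stages <- c("simulate", "consensus", "annotate", "de", "dosage",
              "network", "report", "all")
  if (!stage %in% stages)
    stop("unknown subcommand '", stage, "'\n", usage, call. = FALSE)
  args <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!a %in% c("--config", "--seed", "--outdir"))
      stop("unknown flag '", a, "'\n", usage, call. = FALSE)
    if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
    opts[[sub("^--", "", a)]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opts$config)) stop("--config is required\n", usage,
                                 call. = FALSE)
  config <- read_run_config(opts$config)
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$outdir)) config$outdir <- opts$outdir
  run_pipeline(config, stage)
  invisible(0L)
}
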