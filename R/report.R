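#' Summary report over pipeline outputs
#'
#' Recomputes the dataset-description metrics from the persisted stage
#' tables: junctions surviving the filters, fraction matching the known
#' catalogue, fraction of exonic origin, mean exon count of exonic
#' circRNAs, per-tissue detection counts, differentially expressed
#' circRNA counts per contrast, and the collective PAR shift table.
#' Every number is recomputable from the TSVs alone.
#'
#' @param outdir Pipeline output directory.
#' @return Invisibly, a list with `metrics` (named numbers),
#'   `dec_counts`, and `par_shifts`; also written to
#'   `outdir/report/summary.tsv`.
#' @export
summary_report <- function(outdir) {
  rdir <- file.path(outdir, "report")
  dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
  ca <- utils::read.delim(file.path(outdir, "annotate",
                                    "circ_annotation.tsv"),
                          stringsAsFactors = FALSE)
  cpm <- read_matrix_tsv(file.path(outdir, "consensus", "circ_cpm.tsv"),
                         scale = "circCPM")
  cohort <- utils::read.delim(file.path(outdir, "simulate", "cohort.tsv"),
                              stringsAsFactors = FALSE)
  n_kept <- nrow(ca)
  exonic <- ca$origin == "exonic"
  metrics <- c(
    n_circ_post_filter = n_kept,
    fraction_known = if (n_kept) mean(!is.na(ca$known_id)) else 0,
    fraction_exonic = if (n_kept) mean(exonic) else 0,
    mean_exon_count = if (any(exonic)) mean(ca$exon_count[exonic]) else 0,
    n_par1 = sum(ca$par == "PAR1"),
    n_par2 = sum(ca$par == "PAR2"))
  md <- cohort[match(colnames(cpm), cohort$sample_id), ]
  det <- vapply(unique(md$tissue), function(tis) {
    sub <- cpm[, md$tissue == tis, drop = FALSE]
    sum(rowSums(sub > 0) > 0)
  }, numeric(1))
  names(det) <- paste0("detected_", names(det))
  metrics <- c(metrics, det)

  de_files <- list.files(file.path(outdir, "de"), "^circ_.*\\.tsv$",
                         full.names = TRUE)
  dec_counts <- do.call(rbind, lapply(de_files, function(f) {
    d <- utils::read.delim(f, stringsAsFactors = FALSE)
    data.frame(contrast = sub("^circ_", "", sub("\\.tsv$", "",
                                                basename(f))),
               n_tested = nrow(d), n_significant = sum(d$significant))
  }))
  if (is.null(dec_counts))
    dec_counts <- data.frame(contrast = character(), n_tested = integer(),
                             n_significant = integer())

  shifts_path <- file.path(outdir, "dosage", "collective_shifts.tsv")
  par_shifts <- if (file.exists(shifts_path))
    utils::read.delim(shifts_path, stringsAsFactors = FALSE)
  else data.frame()

  kv <- data.frame(metric = names(metrics), value = unname(metrics))
  utils::write.table(kv, file.path(rdir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dec_counts, file.path(rdir, "dec_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(par_shifts))
    utils::write.table(par_shifts, file.path(rdir, "par_shifts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(metrics = metrics, dec_counts = dec_counts,
                 par_shifts = par_shifts))
}
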