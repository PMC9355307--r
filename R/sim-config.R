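#' Simulation configuration for a synthetic sex-chromosome-aneuploidy cohort
#'
#' Bundles every tunable of the synthetic study generator: cohort layout,
#' genomic region composition, negative-binomial expression model,
#' karyotype dosage model, and caller noise model. Defaults describe a
#' small but structurally complete study; see the methods vignette for the
#' rationale behind each value.
#'
#' @param n_per_group Subjects per karyotype (each subject is sampled in
#'   every tissue).
#' @param karyotypes Karyotypes in the cohort, a subset of
#'   `c("45X", "46XX", "46XY", "47XXY")`.
#' @param tissues Tissues sampled per subject, a subset of
#'   `c("blood", "muscle", "fat")`.
#' @param n_batches Number of processing batches, assigned round-robin.
#' @param n_circ Number of true circRNAs (one host-gene slot each).
#' @param frac_par1,frac_par2 Fractions of features placed in the
#'   pseudoautosomal regions PAR1/PAR2 of chrX.
#' @param frac_chrX_escape,frac_chrX_inactive Fractions of features on
#'   non-PAR chrX that escape / undergo X inactivation.
#' @param frac_chrY Fraction of features on non-PAR chrY.
#' @param frac_intronic,frac_intergenic Fractions of circRNAs of intronic /
#'   intergenic origin (carved out of the autosomal slots; the remainder,
#'   and all sex-chromosome slots, are exonic).
#' @param mean_log_expression,sd_log_expression Mean and SD of per-feature
#'   baseline log2 relative abundance.
#' @param gene_mean_log_expression Baseline mean for host-gene (mRNA)
#'   abundance, log2 scale.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param mrna_dosage_full If `TRUE`, PAR/escape mRNA expression scales
#'   with the full copy ratio `(copies/2)`.
#' @param circ_attenuation Attenuation exponent `alpha` in `[0, 1]`: the
#'   fraction of the mRNA log2 dosage effect retained at the circRNA
#'   level (`1` = full dosage, `0` = none).
#' @param fp_rate_per_caller,fn_rate_per_caller Per-secondary-caller
#'   false-positive injection and false-negative dropout probabilities,
#'   applied per true key per sample.
#' @param batch_sd,tissue_sd SDs of per-feature log2 batch and tissue
#'   effects.
#' @param lib_size_range Length-2 range of per-sample total counts.
#' @param frac_ctl_one Fraction of circRNAs with a circular-to-linear
#'   target of exactly 1 (no linear expression over the junction).
#' @param ctl_beta Length-2 Beta shape parameters for the remaining
#'   circular-to-linear targets.
#' @param frac_known Fraction of true circRNAs present in the known
#'   circRNA catalogue.
#' @param n_triplets Number of planted sign-consistent
#'   circRNA-miRNA-mRNA sponge triplets.
#' @param n_decoy_triplets Number of planted sign-inconsistent decoy
#'   triplets (pass the evidence filter, fail the sign rule).
#' @param n_noise_edges Number of random circRNA-miRNA noise edges.
#' @param seed Integer seed; all generator stages draw from substreams
#'   derived from it, so identical config + seed reproduces identical
#'   output.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = 5,
                       karyotypes = c("45X", "46XX", "46XY", "47XXY"),
                       tissues = c("blood", "muscle", "fat"),
                       n_batches = 2,
                       n_circ = 300,
                       frac_par1 = 0.10,
                       frac_par2 = 0.04,
                       frac_chrX_escape = 0.06,
                       frac_chrX_inactive = 0.06,
                       frac_chrY = 0.02,
                       frac_intronic = 0.03,
                       frac_intergenic = 0.03,
                       mean_log_expression = 4,
                       sd_log_expression = 1.5,
                       gene_mean_log_expression = 6,
                       dispersion = 0.1,
                       mrna_dosage_full = TRUE,
                       circ_attenuation = 0.5,
                       fp_rate_per_caller = 0.05,
                       fn_rate_per_caller = 0.05,
                       batch_sd = 0.1,
                       tissue_sd = 0.5,
                       lib_size_range = c(5e5, 1e6),
                       frac_ctl_one = 0.05,
                       ctl_beta = c(1.5, 5),
                       frac_known = 0.36,
                       n_triplets = 5,
                       n_decoy_triplets = 2,
                       n_noise_edges = 20,
                       seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), karyotypes = karyotypes,
    tissues = tissues, n_batches = as.integer(n_batches),
    n_circ = as.integer(n_circ),
    frac_par1 = frac_par1, frac_par2 = frac_par2,
    frac_chrX_escape = frac_chrX_escape,
    frac_chrX_inactive = frac_chrX_inactive, frac_chrY = frac_chrY,
    frac_intronic = frac_intronic, frac_intergenic = frac_intergenic,
    mean_log_expression = mean_log_expression,
    sd_log_expression = sd_log_expression,
    gene_mean_log_expression = gene_mean_log_expression,
    dispersion = dispersion, mrna_dosage_full = isTRUE(mrna_dosage_full),
    circ_attenuation = circ_attenuation,
    fp_rate_per_caller = fp_rate_per_caller,
    fn_rate_per_caller = fn_rate_per_caller,
    batch_sd = batch_sd, tissue_sd = tissue_sd,
    lib_size_range = lib_size_range,
    frac_ctl_one = frac_ctl_one, ctl_beta = ctl_beta,
    frac_known = frac_known,
    n_triplets = as.integer(n_triplets),
    n_decoy_triplets = as.integer(n_decoy_triplets),
    n_noise_edges = as.integer(n_noise_edges),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_par1, cfg$frac_par2, cfg$frac_chrX_escape,
          cfg$frac_chrX_inactive, cfg$frac_chrY)
  props <- c(fr, cfg$frac_intronic, cfg$frac_intergenic, cfg$frac_ctl_one,
             cfg$frac_known, cfg$fp_rate_per_caller, cfg$fn_rate_per_caller)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (sum(fr) > 1)
    stop("region-class fractions sum above 1")
  if (cfg$circ_attenuation < 0 || cfg$circ_attenuation > 1)
    stop("circ_attenuation must lie in [0, 1]")
  if (cfg$n_per_group < 1) stop("n_per_group must be >= 1")
  if (length(cfg$karyotypes) == 0 || length(cfg$tissues) == 0)
    stop("karyotype and tissue sets must be non-empty")
  bad_k <- setdiff(cfg$karyotypes, c("45X", "46XX", "46XY", "47XXY"))
  if (length(bad_k)) stop("unknown karyotype: ", paste(bad_k, collapse = ", "))
  bad_t <- setdiff(cfg$tissues, c("blood", "muscle", "fat"))
  if (length(bad_t)) stop("unknown tissue: ", paste(bad_t, collapse = ", "))
  if (cfg$n_batches < 1) stop("n_batches must be >= 1")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0)
    stop("lib_size_range must be an increasing positive pair")
  invisible(cfg)
}

# derived per-stage RNG substreams (stage offsets fixed; keeps stages
# independently reproducible from one config seed)
sim_seed <- function(cfg, stage) {
  off <- c(annotation = 101L, cohort = 211L, counts = 307L,
           callers = 401L, interactions = 503L)
  cfg$seed + off[[stage]]
}
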