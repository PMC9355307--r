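# shared fixture builders; everything is generated in code at test time

# compact cohort config used by most generator tests
tiny_config <- function(...) {
  sim_config(n_per_group = 3, n_circ = 100, seed = 7, ...)
}

# a deterministic toy annotation: one gene, six exons of 100 bp spaced
# 200 bp apart on chr1, plus a second adjacent gene
toy_annotation <- function() {
  starts_a <- 1000 + (0:5) * 300
  starts_b <- 5000 + (0:3) * 300
  structure(list(
    genes = data.frame(
      gene_id = c("GA", "GB"), chrom = "chr1", strand = "+",
      start = c(starts_a[1], starts_b[1]),
      end = c(starts_a[6] + 100, starts_b[4] + 100),
      region_class = "autosome", stringsAsFactors = FALSE),
    exons = rbind(
      data.frame(gene_id = "GA", exon = 1:6, start = starts_a,
                 end = starts_a + 100),
      data.frame(gene_id = "GB", exon = 1:4, start = starts_b,
                 end = starts_b + 100))),
    class = "sca_annotation")
}

# metadata for a two-group, two-batch direct DE fixture
flat_metadata <- function(n_per_group, case = "45X", control = "46XX",
                          n_batches = 2) {
  n <- 2 * n_per_group
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             subject_id = sprintf("s%02d", seq_len(n)),
             karyotype = rep(c(case, control), each = n_per_group),
             tissue = "blood",
             batch = rep_len(seq_len(n_batches), n),
             stringsAsFactors = FALSE)
}

# NB count matrix with optional planted log2 effects in the first group
nb_counts <- function(n_feat, metadata, mu = 100, size = 10,
                      lfc = 0, n_planted = 0, case = "45X") {
  n <- nrow(metadata)
  mu_mat <- matrix(mu, n_feat, n)
  if (n_planted > 0) {
    idx <- metadata$karyotype == case
    mu_mat[seq_len(n_planted), idx] <- mu * 2^lfc
  }
  matrix(rnbinom(n_feat * n, mu = mu_mat, size = size), n_feat, n,
         dimnames = list(paste0("f", seq_len(n_feat)),
                         metadata$sample_id))
}
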