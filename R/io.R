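# Plain-text readers/writers for the pipeline's intermediates. All genomic
# coordinates are printed 1-based inclusive on disk and 0-based half-open
# in memory; conversion happens only here.

#' Write/read a feature-by-sample matrix as TSV
#'
#' @param mat Numeric matrix with rownames.
#' @param path File path.
#' @param id_col Name of the identifier column (default `"key"`).
#' @return `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "key") {
  df <- data.frame(id = rownames(mat), as.data.frame(mat, optional = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param scale Optional scale tag (`"raw"`/`"circCPM"`) applied on read.
#' @export
read_matrix_tsv <- function(path, scale = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (!is.null(scale)) mat <- circ_matrix(mat, scale)
  mat
}

#' Write/read the gene/exon annotation as a GTF-like TSV
#'
#' One row per gene and per exon, printed 1-based inclusive.
#'
#' @param annotation An `"sca_annotation"`.
#' @param path File path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  rows <- rbind(
    data.frame(chrom = g$chrom, feature = "gene", start = g$start + 1L,
               end = g$end, strand = g$strand, gene_id = g$gene_id,
               exon = NA_integer_, region_class = g$region_class),
    data.frame(chrom = g$chrom[match(e$gene_id, g$gene_id)],
               feature = "exon", start = e$start + 1L, end = e$end,
               strand = g$strand[match(e$gene_id, g$gene_id)],
               gene_id = e$gene_id, exon = e$exon,
               region_class = g$region_class[match(e$gene_id, g$gene_id)]))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  rows <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- rows[rows$feature == "gene", ]
  e <- rows[rows$feature == "exon", ]
  structure(list(
    genes = data.frame(gene_id = g$gene_id, chrom = g$chrom,
                       strand = g$strand, start = g$start - 1L,
                       end = g$end, region_class = g$region_class,
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = e$gene_id, exon = e$exon,
                       start = e$start - 1L, end = e$end,
                       stringsAsFactors = FALSE)),
    class = "sca_annotation")
}

#' Write/read the known-circRNA catalogue
#'
#' @param catalogue Data frame with `known_id`, `chrom`, `start`, `end`,
#'   `strand` (internal coordinates).
#' @param path File path.
#' @export
write_catalogue_tsv <- function(catalogue, path) {
  out <- data.frame(known_id = catalogue$known_id, chrom = catalogue$chrom,
                    start = catalogue$start + 1L, end = catalogue$end,
                    strand = catalogue$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue_tsv
#' @export
read_catalogue_tsv <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  ct$start <- ct$start - 1L
  ct$key <- bsj_key(ct$chrom, ct$start, ct$end, ct$strand)
  ct
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: set name, description, then member genes,
#'   tab-separated.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE),
                 function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}
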