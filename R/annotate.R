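#' Pseudoautosomal region boundaries
#'
#' The fixed hg38 PAR intervals shared by chrX and chrY, in the printed
#' 1-based inclusive convention: PAR1 spans 10,001-2,781,479 and PAR2
#' spans 155,701,383-156,030,895.
#'
#' @return A list with integer vectors `PAR1` and `PAR2` of
#'   `c(start, end)`.
#' @export
par_regions <- function() {
  list(PAR1 = c(10001L, 2781479L),
       PAR2 = c(155701383L, 156030895L))
}

#' Assign PAR membership to backsplice junctions
#'
#' A junction is PAR1 or PAR2 only when it lies on chrX or chrY and
#' *both* endpoints fall inside the same interval; containment is
#' evaluated in the printed 1-based inclusive frame (internal start + 1,
#' internal end). Strand is ignored.
#'
#' @param keys Character vector of canonical junction keys.
#' @param regions PAR intervals, by default [par_regions()].
#' @return Character vector over `{"PAR1", "PAR2", "none"}`.
#' @export
assign_par <- function(keys, regions = par_regions()) {
  b <- parse_bsj_key(keys)
  s1 <- b$start + 1L   # printed 1-based start
  e1 <- b$end          # printed 1-based inclusive end
  on_sex <- b$chrom %in% c("chrX", "chrY")
  out <- rep("none", length(keys))
  in1 <- on_sex & s1 >= regions$PAR1[1] & e1 <= regions$PAR1[2]
  in2 <- on_sex & s1 >= regions$PAR2[1] & e1 <= regions$PAR2[2]
  out[in1] <- "PAR1"
  out[in2] <- "PAR2"
  out
}

#' Classify the genomic origin of backsplice junctions
#'
#' A junction is `exonic` for a host gene when its start coincides with
#' an exon start and its end with an exon end of that gene (within
#' `boundary_tol` bp); `intronic` when it lies inside a gene without
#' meeting the exon rule; `intergenic` otherwise. A junction spanning
#' two adjacent genes reports both hosts. For exonic junctions the exon
#' count is the number of annotated host exons fully inside
#' `[start, end)` and the spliced length is their total length (union
#' over hosts for multi-gene spans).
#'
#' @param keys Character vector of canonical junction keys.
#' @param annotation An `"sca_annotation"`.
#' @param boundary_tol Tolerance in bp for endpoint/exon-boundary
#'   coincidence (default 0).
#' @return Data frame with `key`, `origin`, `host_gene_ids`
#'   (comma-separated, `""` for intergenic), `exon_count`,
#'   `spliced_length`.
#' @export
classify_origin <- function(keys, annotation, boundary_tol = 0) {
  b <- parse_bsj_key(keys)
  genes <- annotation$genes
  exons <- annotation$exons
  out <- data.frame(key = keys, origin = "intergenic",
                    host_gene_ids = "", exon_count = 0L,
                    spliced_length = 0L, stringsAsFactors = FALSE)
  known_chrom <- unique(genes$chrom)
  for (i in seq_along(keys)) {
    if (!b$chrom[i] %in% known_chrom) {
      warning("chromosome ", b$chrom[i], " absent from annotation; ",
              "classified intergenic", call. = FALSE)
      next
    }
    g <- genes[genes$chrom == b$chrom[i] &
                 genes$start < b$end[i] & genes$end > b$start[i], ]
    if (nrow(g) == 0) next
    ex <- exons[exons$gene_id %in% g$gene_id, ]
    inner <- ex[ex$start >= b$start[i] & ex$end <= b$end[i], ]
    start_hit <- any(abs(ex$start - b$start[i]) <= boundary_tol)
    end_hit <- any(abs(ex$end - b$end[i]) <= boundary_tol)
    if (start_hit && end_hit && nrow(inner) > 0) {
      out$origin[i] <- "exonic"
      out$exon_count[i] <- nrow(inner)
      out$spliced_length[i] <- sum(inner$end - inner$start)
    } else {
      out$origin[i] <- "intronic"
    }
    out$host_gene_ids[i] <- paste(sort(unique(g$gene_id)), collapse = ",")
  }
  out
}

#' Match junctions against a known-circRNA catalogue
#'
#' Exact match on harmonized coordinates (both catalogue and query in the
#' internal convention); an optional slack relaxes both endpoints.
#'
#' @param keys Character vector of canonical junction keys.
#' @param catalogue Data frame with at least `known_id` and `key` columns.
#' @param slack_bp Endpoint slack in bp (default 0 = exact key equality).
#' @return Character vector of catalogue ids, `NA` where unmatched.
#' @export
match_known <- function(keys, catalogue, slack_bp = 0) {
  if (slack_bp == 0)
    return(catalogue$known_id[match(keys, catalogue$key)])
  q <- parse_bsj_key(keys)
  ct <- parse_bsj_key(catalogue$key)
  vapply(seq_along(keys), function(i) {
    hit <- which(ct$chrom == q$chrom[i] & ct$strand == q$strand[i] &
                   abs(ct$start - q$start[i]) <= slack_bp &
                   abs(ct$end - q$end[i]) <= slack_bp)
    if (length(hit)) catalogue$known_id[hit[1]] else NA_character_
  }, character(1))
}

#' Full per-circRNA annotation table
#'
#' Combines genomic origin, PAR membership, region/escape class of the
#' host gene, and known-catalogue matching for a set of kept junctions.
#'
#' @param keys Character vector of canonical junction keys.
#' @param annotation An `"sca_annotation"`.
#' @param catalogue Known-circRNA catalogue data frame (or `NULL`).
#' @param boundary_tol Passed to [classify_origin()].
#' @return Data frame with `key`, `origin`, `host_gene_ids`,
#'   `exon_count`, `spliced_length`, `par`, `region_class`, `known_id`.
#' @export
annotate_circ <- function(keys, annotation, catalogue = NULL,
                          boundary_tol = 0) {
  out <- classify_origin(keys, annotation, boundary_tol)
  out$par <- assign_par(keys)
  first_host <- sub(",.*$", "", out$host_gene_ids)
  out$region_class <- annotation$genes$region_class[
    match(first_host, annotation$genes$gene_id)]
  # intergenic junctions inside a PAR still class as PAR by position
  out$region_class[is.na(out$region_class)] <-
    ifelse(out$par[is.na(out$region_class)] == "none", "autosome",
           out$par[is.na(out$region_class)])
  out$known_id <- if (is.null(catalogue)) NA_character_
    else match_known(keys, catalogue)
  out
}

#' Circular isoforms per host transcript
#'
#' Counts the distinct kept junctions attributed to each host gene and
#' their mean circCPM over keys and samples. Multi-host junctions count
#' once per host.
#'
#' @param circ_annotations Output of [annotate_circ()] (or any frame with
#'   `key` and `host_gene_ids`).
#' @param mat circCPM matrix over (a superset of) the annotated keys.
#' @return Data frame (`host_gene_id`, `isoform_count`,
#'   `mean_expression`), hosts with no kept keys absent.
#' @export
isoforms_per_host <- function(circ_annotations, mat) {
  ca <- circ_annotations[nzchar(circ_annotations$host_gene_ids), ]
  if (nrow(ca) == 0)
    return(data.frame(host_gene_id = character(),
                      isoform_count = integer(),
                      mean_expression = numeric()))
  hosts <- strsplit(ca$host_gene_ids, ",", fixed = TRUE)
  long <- data.frame(host_gene_id = unlist(hosts),
                     key = rep(ca$key, lengths(hosts)),
                     stringsAsFactors = FALSE)
  long <- long[long$key %in% rownames(mat), ]
  if (nrow(long) == 0)
    return(data.frame(host_gene_id = character(),
                      isoform_count = integer(),
                      mean_expression = numeric()))
  sp <- split(long$key, long$host_gene_id)
  data.frame(
    host_gene_id = names(sp),
    isoform_count = lengths(lapply(sp, unique)),
    mean_expression = vapply(sp, function(k)
      mean(mat[unique(k), , drop = FALSE]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
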