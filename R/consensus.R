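#' Filtering thresholds for consensus quantification
#'
#' @param min_circCPM Minimum circCPM for the expression filter
#'   (inclusive; default 25).
#' @param min_samples Minimum number of samples at or above `min_circCPM`
#'   (inclusive; default 7).
#' @param consensus_min_secondary Minimum number of secondary callers that
#'   must also detect a primary-caller key (default 1).
#' @param coord_slack_bp Coordinate slack, in bp, allowed when matching
#'   keys across callers (default 0 = exact).
#' @return A list of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_circCPM = 25, min_samples = 7,
                              consensus_min_secondary = 1,
                              coord_slack_bp = 0) {
  stopifnot(min_circCPM >= 0, min_samples >= 0,
            consensus_min_secondary >= 0, coord_slack_bp >= 0)
  structure(list(min_circCPM = min_circCPM, min_samples = min_samples,
                 consensus_min_secondary = consensus_min_secondary,
                 coord_slack_bp = coord_slack_bp),
            class = "filter_thresholds")
}

#' Read a primary-caller quantification table
#'
#' The primary dialect is a headered TSV with columns `chrom`, `start`,
#' `end`, `strand`, `bsj_reads`, `linear_reads` (extra columns such as a
#' `key` are ignored), with 1-based inclusive coordinates; these are
#' shifted to the internal 0-based half-open convention on read. Rows
#' with `start >= end` (after conversion) are rejected and counted in the
#' `n_rejected` attribute.
#'
#' @param path Path to the TSV file.
#' @return A data frame of records (`chrom`, `start`, `end`, `strand`,
#'   `key`, `bsj_reads`, `linear_reads`) with attribute `n_rejected`.
#' @export
read_primary_caller <- function(path) {
  if (!file.exists(path)) stop("primary caller file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "bsj_reads", "linear_reads")
  if (!all(need %in% names(tab)))
    stop("primary caller header must contain: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      key = character(), bsj_reads = integer(),
                      linear_reads = integer())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  for (col in c("start", "end", "bsj_reads", "linear_reads")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) | is.na(tab[[col]]))
    if (length(bad))
      stop("malformed row ", bad[1] + 1L, " in ", path,
           ": non-integer ", col)
    tab[[col]] <- v
  }
  if (any(tab$bsj_reads < 0) || any(tab$linear_reads < 0))
    stop("negative read counts in ", path)
  ok <- tab$start < tab$end          # degenerate printed intervals rejected
  start0 <- tab$start - 1L           # 1-based inclusive -> 0-based half-open
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message(n_rej, " record(s) with start >= end rejected in ", path)
  out <- data.frame(chrom = tab$chrom[ok], start = start0[ok],
                    end = tab$end[ok], strand = tab$strand[ok],
                    stringsAsFactors = FALSE)
  out$key <- bsj_key(out$chrom, out$start, out$end, out$strand)
  out$bsj_reads <- tab$bsj_reads[ok]
  out$linear_reads <- tab$linear_reads[ok]
  attr(out, "n_rejected") <- n_rej
  out
}

#' Read a detection-only secondary-caller file
#'
#' BED6 input is natively 0-based half-open and taken as-is; the `tsv`
#' dialect mirrors the primary caller's headered 1-based inclusive layout
#' without count columns. Duplicate junctions collapse to one key (set
#' semantics). Records on chromosomes absent from any annotation are kept:
#' detection is annotation-independent.
#'
#' @param path Path to the file.
#' @param dialect `"bed6"` or `"tsv"`.
#' @return A character vector of unique canonical keys.
#' @export
read_secondary_caller <- function(path, dialect = c("bed6", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("secondary caller file not found: ", path)
  if (dialect == "bed6") {
    tab <- tryCatch(
      utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE),
      error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0) return(character(0))
    if (ncol(tab) < 6) stop("BED6 requires 6 columns: ", path)
    names(tab)[c(1:3, 6)] <- c("chrom", "start", "end", "strand")
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "start", "end", "strand") %in% names(tab)))
      stop("secondary TSV header must contain chrom/start/end/strand")
    if (nrow(tab) == 0) return(character(0))
    tab$start <- tab$start - 1L
  }
  ok <- tab$start < tab$end
  if (any(!ok))
    message(sum(!ok), " record(s) with start >= end rejected in ", path)
  tab <- tab[ok, ]
  unique(bsj_key(tab$chrom, tab$start, tab$end, tab$strand))
}

#' Multi-caller consensus filter
#'
#' Keeps a primary-caller junction only if it is also detected by at least
#' `consensus_min_secondary` secondary callers. With
#' `coord_slack_bp = 0` matching is exact key equality; otherwise two
#' junctions match when chromosome and strand agree and both endpoints
#' differ by at most the slack.
#'
#' @param primary_keys Character vector of primary-caller keys.
#' @param secondary_key_sets List of character vectors, one per secondary
#'   caller.
#' @param thresholds A [filter_thresholds()].
#' @return The kept subset of `primary_keys` (order preserved).
#' @export
consensus_filter <- function(primary_keys, secondary_key_sets,
                             thresholds = filter_thresholds()) {
  if (!length(secondary_key_sets))
    stop("at least one secondary caller key set is required")
  primary_keys <- unique(primary_keys)
  if (!length(primary_keys)) return(character(0))
  slack <- thresholds$coord_slack_bp
  if (slack == 0) {
    hits <- vapply(secondary_key_sets,
                   function(s) primary_keys %in% s, logical(length(primary_keys)))
  } else {
    p <- parse_bsj_key(primary_keys)
    hits <- vapply(secondary_key_sets, function(s) {
      if (!length(s)) return(rep(FALSE, nrow(p)))
      q <- parse_bsj_key(s)
      vapply(seq_len(nrow(p)), function(i) {
        any(q$chrom == p$chrom[i] & q$strand == p$strand[i] &
              abs(q$start - p$start[i]) <= slack &
              abs(q$end - p$end[i]) <= slack)
      }, logical(1))
    }, logical(nrow(p)))
  }
  hits <- matrix(hits, nrow = length(primary_keys))
  primary_keys[rowSums(hits) >= thresholds$consensus_min_secondary]
}

#' Normalize backsplice counts to circCPM
#'
#' Per-sample counts per million of circular reads: each column is divided
#' by its own total backsplice read count and multiplied by 1e6. An
#' all-zero column stays all zero.
#'
#' @param mat Raw backsplice count matrix (keys x samples), as returned by
#'   [circ_count_matrix()] or tagged by the pipeline.
#' @return The circCPM matrix, tagged with scale `"circCPM"`.
#' @export
circ_cpm <- function(mat) {
  if (circ_scale(mat) != "raw") stop("circ_cpm expects a raw count matrix")
  if (any(mat < 0)) stop("negative counts")
  tot <- colSums(mat)
  denom <- ifelse(tot > 0, tot, 1)
  out <- sweep(mat, 2, denom, "/") * 1e6
  circ_matrix(out, "circCPM")
}

#' Expression filter on a circCPM matrix
#'
#' Keeps a junction when it reaches at least `min_circCPM` in at least
#' `min_samples` samples (both comparisons inclusive).
#'
#' @param mat circCPM matrix.
#' @param thresholds A [filter_thresholds()].
#' @return Character vector of kept keys.
#' @export
expression_filter <- function(mat, thresholds = filter_thresholds()) {
  if (circ_scale(mat) != "circCPM")
    stop("expression_filter expects a circCPM matrix")
  if (thresholds$min_samples > ncol(mat)) {
    warning("min_samples (", thresholds$min_samples,
            ") exceeds the number of samples (", ncol(mat),
            "); no junction can pass")
    return(character(0))
  }
  keep <- rowSums(mat >= thresholds$min_circCPM) >= thresholds$min_samples
  rownames(mat)[keep]
}

#' Circular-to-linear ratio
#'
#' `CTL = 2c / (2c + l)`, with the convention that zero backsplice reads
#' give 0 (so `c > 0, l = 0` gives 1: purely circular expression over the
#' junction).
#'
#' @param circ_reads,linear_reads Non-negative integer vectors (recycled).
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
ctl_ratio <- function(circ_reads, linear_reads) {
  if (any(circ_reads < 0) || any(linear_reads < 0))
    stop("read counts must be non-negative")
  n <- max(length(circ_reads), length(linear_reads))
  c2 <- rep_len(2 * circ_reads, n)
  l <- rep_len(linear_reads, n)
  ifelse(c2 == 0, 0, c2 / (c2 + l))
}

#' Assemble a raw backsplice count matrix from primary-caller records
#'
#' @param records Named list of per-sample data frames from
#'   [read_primary_caller()].
#' @param keys Optional key universe (rows); defaults to the union of all
#'   observed keys in first-seen order.
#' @param value `"bsj_reads"` or `"linear_reads"`.
#' @return Keys x samples matrix tagged with scale `"raw"`.
#' @export
circ_count_matrix <- function(records, keys = NULL, value = "bsj_reads") {
  if (is.null(keys))
    keys <- unique(unlist(lapply(records, `[[`, "key"), use.names = FALSE))
  mat <- matrix(0L, length(keys), length(records),
                dimnames = list(keys, names(records)))
  for (s in names(records)) {
    r <- records[[s]]
    idx <- match(r$key, keys)
    hit <- !is.na(idx)
    mat[idx[hit], s] <- r[[value]][hit]
  }
  circ_matrix(mat, "raw")
}

#' Circular-to-linear table for a set of samples
#'
#' @param circ Raw backsplice count matrix (keys x samples).
#' @param linear Matching linear junction count matrix.
#' @return Long-format data frame (`key`, `sample_id`, `circ_reads`,
#'   `linear_reads`, `ctl`).
#' @export
ctl_table <- function(circ, linear) {
  stopifnot(identical(dim(circ), dim(linear)))
  data.frame(
    key = rep(rownames(circ), ncol(circ)),
    sample_id = rep(colnames(circ), each = nrow(circ)),
    circ_reads = as.vector(circ),
    linear_reads = as.vector(linear),
    ctl = ctl_ratio(as.vector(circ), as.vector(linear)),
    stringsAsFactors = FALSE)
}
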