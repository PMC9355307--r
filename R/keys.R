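#' Backsplice junction keys
#'
#' A circRNA is identified by the genomic endpoints of its backsplice
#' junction (BSJ). Internally all coordinates are 0-based half-open;
#' conversions to 1-based inclusive happen only at I/O boundaries. The
#' canonical string key is `"chrom:start-end:strand"`.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return `bsj_key()` returns a character vector of keys;
#'   `parse_bsj_key()` returns a data frame with columns `chrom`, `start`,
#'   `end`, `strand`, `key`.
#' @examples
#' k <- bsj_key("chrX", 100, 500, "-")
#' parse_bsj_key(k)
#' @export
bsj_key <- function(chrom, start, end, strand = ".") {
  if (any(start >= end))
    stop("backsplice junction requires start < end")
  # force fixed notation: coordinates must never print as 7e+05
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end),
          rep_len(strand, length(chrom)))
}

#' @rdname bsj_key
#' @param key Character vector of canonical keys.
#' @export
parse_bsj_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):([0-9]+)-([0-9]+):([+.-])$", key))
  bad <- vapply(m, length, 0L) != 5L
  if (any(bad))
    stop("malformed backsplice key: ", key[bad][1L])
  out <- data.frame(
    chrom  = vapply(m, `[`, "", 2L),
    start  = as.integer(vapply(m, `[`, "", 3L)),
    end    = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    key    = as.character(key),
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end))
    stop("malformed backsplice key: start >= end")
  out
}

#' Strip strand from keys for unstranded matching
#'
#' Callers disagree on strand more often than on coordinates; collapsing
#' `+`/`-`/`.` to `.` gives an unstranded key space.
#'
#' @param key Character vector of canonical keys.
#' @return Keys with the strand field replaced by `"."`.
#' @export
unstranded_key <- function(key) {
  sub(":[+.-]$", ":.", key)
}

# tag a counts matrix with its scale ("raw" or "circCPM")
circ_matrix <- function(values, scale = c("raw", "circCPM")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicate backsplice keys in count matrix")
  if (any(values < 0)) stop("counts must be non-negative")
  attr(values, "scale") <- scale
  values
}

circ_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "raw" else s
}
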