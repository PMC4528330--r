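#' Genomic interval constructor
#'
#' Intervals are zero-based, half-open `[start, end)` on an explicit strand.
#' GFF3 input/output converts to and from 1-based inclusive coordinates at the
#' file boundary; everything inside the package uses this convention so that
#' interval lengths and adjacency need no off-by-one corrections.
#'
#' @param seqid sequence (contig) identifier.
#' @param start,end zero-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `genomic_interval`.
#' @export
g_interval <- function(seqid, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval [", start, ", ", end, ") on ", seqid)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got: ", strand)
  structure(list(seqid = as.character(seqid), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

interval_len <- function(iv) iv$end - iv$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:[%d,%d)%s>\n", x$seqid, x$start, x$end, x$strand))
  invisible(x)
}

## TRUE when two intervals share >= 1 base on the same seqid (strand ignored)
intervals_intersect <- function(a, b) {
  a$seqid == b$seqid && a$start < b$end && b$start < a$end
}

## genomic base positions (0-based) covered by an interval
interval_positions <- function(iv) seq.int(iv$start, iv$end - 1L)

## maximal runs of consecutive integers -> list of c(start, end) half-open
runs_of <- function(pos) {
  if (length(pos) == 0L) return(list())
  pos <- sort(unique(as.integer(pos)))
  brk <- which(diff(pos) != 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))] + 1L
  Map(function(s, e) c(start = s, end = e), starts, ends)
}
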