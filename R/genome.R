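#' In-memory genome sequence set
#'
#' @param records named character vector of uppercase nucleotide sequences
#'   (alphabet `A`, `C`, `G`, `T`, `N`).
#' @param circular character vector of identifiers to treat as circular
#'   (typically the mitochondrial contig).
#' @return an object of class `genome_seq`.
#' @export
genome_seq <- function(records, circular = character()) {
  if (is.null(names(records)) || any(names(records) == ""))
    stop("every genome record needs an identifier")
  if (anyDuplicated(names(records)))
    stop("duplicate sequence identifier: ",
         names(records)[duplicated(names(records))][1])
  records <- vapply(records, toupper, character(1))
  for (id in names(records)) {
    if (nchar(records[[id]]) == 0L) stop("empty sequence for record ", id)
    bad <- regexpr("[^ACGTN]", records[[id]])
    if (bad > 0L)
      stop("non-IUPAC character '", substr(records[[id]], bad, bad),
           "' in record ", id, " at position ", bad)
  }
  missing_circ <- setdiff(circular, names(records))
  if (length(missing_circ))
    stop("circular id not present in records: ", missing_circ[1])
  structure(list(records = records, circular = circular),
            class = "genome_seq")
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased on input; lowercase (soft-masked) FASTA is
#' accepted. Only `A`, `C`, `G`, `T`, `N` are allowed after normalization.
#'
#' @param path FASTA file.
#' @param circular identifiers to mark as circular contigs.
#' @return a [genome_seq] object.
#' @export
read_genome <- function(path, circular = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  genome_seq(stats::setNames(as.character(ss),
                             sub("\\s.*$", "", names(ss))),
             circular = circular)
}

#' Write a genome to FASTA
#'
#' @param g a [genome_seq].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_genome <- function(g, path, width = 70L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (id in names(g$records)) {
    writeLines(c(paste0(">", id), wrap_seq(g$records[[id]], width)), con,
               sep = "\n")
  }
  invisible(path)
}

wrap_seq <- function(s, width = 70L) {
  n <- nchar(s)
  substring(s, seq.int(1L, n, width), pmin(seq.int(1L, n, width) + width - 1L, n))
}

contig_length <- function(g, seqid) {
  if (!seqid %in% names(g$records)) stop("unknown contig: ", seqid)
  nchar(g$records[[seqid]])
}

## reverse complement (N-preserving)
rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Extract the sequence of one interval, strand-aware
#'
#' Minus-strand intervals are reverse-complemented. Intervals running past the
#' end of a circular contig wrap around the origin; on a linear contig this is
#' an error.
#'
#' @param g a [genome_seq].
#' @param iv a [g_interval].
#' @return nucleotide string, read 5' to 3' on `iv$strand`.
#' @export
interval_seq <- function(g, iv) {
  len <- contig_length(g, iv$seqid)
  rec <- g$records[[iv$seqid]]
  if (iv$end <= len) {
    s <- substr(rec, iv$start + 1L, iv$end)
  } else if (iv$seqid %in% g$circular && iv$start < len && iv$end - iv$start <= len) {
    s <- paste0(substr(rec, iv$start + 1L, len), substr(rec, 1L, iv$end - len))
  } else {
    stop("interval [", iv$start, ",", iv$end, ") beyond end of contig ",
         iv$seqid, " (length ", len, ")")
  }
  if (iv$strand == "-") rc(s) else s
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq:", length(x$records), "contig(s)\n")
  for (id in names(x$records))
    cat(sprintf("  %s  %d nt%s\n", id, nchar(x$records[[id]]),
                if (id %in% x$circular) "  (circular)" else ""))
  invisible(x)
}
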