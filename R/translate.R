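#' Genetic code tables
#'
#' The standard nuclear code and the invertebrate mitochondrial code (NCBI
#' translation table 5, in which AGA/AGG encode serine, AUA methionine and
#' UGA tryptophan). Tables come from Biostrings' genetic-code registry.
#'
#' @param code_id `"standard"` or `"invertebrate_mitochondrial"`.
#' @return list with `code_id`, `table` (named character vector, DNA codon ->
#'   one-letter amino acid, stops as `"*"`) and `stops` (stop codon set).
#' @export
genetic_code <- function(code_id = "standard") {
  tab <- switch(code_id,
    standard = Biostrings::getGeneticCode("1"),
    invertebrate_mitochondrial = Biostrings::getGeneticCode("5"),
    stop("unknown genetic code id: ", code_id))
  ## Biostrings keys codons in DNA alphabet already
  structure(list(code_id = code_id, table = tab,
                 stops = names(tab)[tab == "*"]),
            class = "genetic_code")
}

translate_codon <- function(codon, code) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  aa <- unname(code$table[codon])
  if (is.na(aa)) stop("untranslatable codon: ", codon)
  aa
}

#' Apply a programmed +1 ribosomal frameshift to a coding sequence
#'
#' Returns the effective coding sequence the ribosome actually reads: the
#' first `codon_index` codons, then one skipped nucleotide, then the
#' remainder in the new frame.
#'
#' @param cds_nt coding nucleotide string (pre-shift annotation coordinates).
#' @param event `list(codon_index =, shift = 1L)`; only `+1` is supported,
#'   matching the single known programmed translational frameshift. `NULL`
#'   returns the input unchanged.
#' @return effective coding sequence.
#' @export
apply_frameshift <- function(cds_nt, event = NULL) {
  if (is.null(event)) return(cds_nt)
  if (!identical(as.integer(event$shift), 1L))
    stop("only a +1 translational frameshift is supported")
  ci <- as.integer(event$codon_index)
  n <- nchar(cds_nt)
  if (ci < 1L || 3L * ci + 1L > n)
    stop("frameshift after codon ", ci, " leaves no sequence to resume in")
  paste0(substr(cds_nt, 1L, 3L * ci), substr(cds_nt, 3L * ci + 2L, n))
}

#' Complete an incomplete (polyadenylation-finished) stop codon
#'
#' Some mitochondrial CDSs end in `T` or `TA`; the UAA stop codon only exists
#' on the polyadenylated mRNA. Appends the missing `A`s.
#'
#' @param cds_nt coding sequence whose length is not a multiple of 3.
#' @param code a [genetic_code] (the completed codon must be a stop in it).
#' @return list with `cds` (completed sequence) and `completed_stop = TRUE`.
#' @export
complete_incomplete_stop <- function(cds_nt, code = genetic_code()) {
  rem <- nchar(cds_nt) %% 3L
  if (rem == 0L)
    stop("CDS length is already a multiple of 3; nothing to complete")
  tail <- substr(cds_nt, nchar(cds_nt) - rem + 1L, nchar(cds_nt))
  completed <- paste0(tail, strrep("A", 3L - rem))
  if (completed != "TAA" || !"TAA" %in% code$stops)
    stop("trailing '", tail, "' cannot be completed to a TAA stop codon ",
         "by polyadenylation")
  list(cds = paste0(cds_nt, strrep("A", 3L - rem)), completed_stop = TRUE)
}

#' Translate an ORF under its declared exceptions
#'
#' Applies, in order: incomplete-stop completion, the +1 frameshift, then
#' codon-by-codon translation in the ORF's genetic code with
#' * a declared non-AUG start translated as methionine,
#' * declared selenocysteine stops as `"U"`,
#' * declared readthrough stops as `"X"` (translation continues),
#' * codons containing `N` as `"X"`,
#' * an `"undetermined"` start translated from the annotated first codon with
#'   a `start_codon_not_determined` event recorded.
#' The final codon must be a stop; any *undeclared* internal stop is an
#' annotation inconsistency and raises an error naming the codon index.
#'
#' @param o an [orf_annotation].
#' @param t the [transcript_model] carrying it.
#' @param g a [genome_seq].
#' @return list of class `translation_result`: `peptide`, `events`
#'   (data.frame of applied exceptions), `completed_stop`.
#' @export
translate_orf <- function(o, t, g) {
  code <- genetic_code(o$genetic_code)
  cds <- cds_sequence(o, g)
  completed <- FALSE
  if (o$incomplete_stop) {
    cc <- complete_incomplete_stop(cds, code)
    cds <- cc$cds
    completed <- TRUE
  }
  cds <- apply_frameshift(cds, o$frameshift)
  if (nchar(cds) %% 3L != 0L)
    stop("effective CDS length for ", o$gene_id, " is not a multiple of 3")
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))

  bad <- setdiff(c(o$readthrough_positions, o$selenocysteine_positions),
                 which(codons %in% code$stops))
  if (length(bad))
    stop("declared translation exception at codon ", bad[1], " of ",
         o$gene_id, ", which is not a stop codon")

  events <- list()
  note <- function(type, idx) events[[length(events) + 1L]] <<-
    data.frame(type = type, codon_index = idx, stringsAsFactors = FALSE)
  aa <- character(0)
  for (i in seq_len(n_codon)) {
    codon <- codons[i]
    if (i == 1L) {
      kind <- o$start_codon_kind
      if (identical(kind, "undetermined")) {
        note("start_codon_not_determined", 1L)
        aa <- c(aa, translate_codon(codon, code))
      } else if (identical(kind, "AUG")) {
        aa <- c(aa, translate_codon(codon, code))
      } else {
        if (codon != kind)
          stop("declared ", kind, " start of ", o$gene_id,
               " does not match genomic codon ", codon)
        note("non_AUG_start", 1L)
        aa <- c(aa, "M")
      }
      next
    }
    if (codon %in% code$stops) {
      if (i %in% o$selenocysteine_positions) {
        note("selenocysteine", i); aa <- c(aa, "U")
      } else if (i %in% o$readthrough_positions) {
        note("stop_codon_read_through", i); aa <- c(aa, "X")
      } else if (i == n_codon) {
        break  # terminal stop, not part of the peptide
      } else {
        stop("undeclared internal stop codon at codon ", i, " of ",
             o$gene_id)
      }
    } else {
      if (i == n_codon)
        stop("ORF of ", o$gene_id, " does not end in a stop codon")
      aa <- c(aa, translate_codon(codon, code))
    }
  }
  structure(list(peptide = paste(aa, collapse = ""),
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(type = character(),
                                          codon_index = integer(),
                                          stringsAsFactors = FALSE),
                 completed_stop = completed),
            class = "translation_result")
}

#' @export
print.translation_result <- function(x, ...) {
  cat("peptide (", nchar(x$peptide), " aa): ",
      if (nchar(x$peptide) > 60)
        paste0(substr(x$peptide, 1, 57), "...") else x$peptide, "\n", sep = "")
  if (nrow(x$events))
    cat("events:", paste(sprintf("%s@%d", x$events$type, x$events$codon_index),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Candidate C-terminal extensions for readthrough annotation
#'
#' Utility for building readthrough annotations: for an ORF whose final codon
#' is a stop, reports where the *next* in-frame stop lies in the genome if
#' translation were to read through the annotated one.
#'
#' @param o an [orf_annotation].
#' @param t its [transcript_model].
#' @param g a [genome_seq].
#' @param max_codons search horizon.
#' @return number of codons between the annotated stop and the next in-frame
#'   stop (NA when none found within the horizon).
#' @export
readthrough_extension_candidate <- function(o, t, g, max_codons = 1000L) {
  code <- genetic_code(o$genetic_code)
  last <- o$cds_segments[[length(o$cds_segments)]]
  contig_len <- contig_length(g, last$seqid)
  for (k in seq_len(max_codons)) {
    iv <- if (last$strand == "+") {
      if (last$end + 3L * k > contig_len) return(NA_integer_)
      g_interval(last$seqid, last$end + 3L * (k - 1L), last$end + 3L * k, "+")
    } else {
      if (last$start - 3L * k < 0L) return(NA_integer_)
      g_interval(last$seqid, last$start - 3L * k, last$start - 3L * (k - 1L),
                 "-")
    }
    if (interval_seq(g, iv) %in% code$stops) return(k - 1L)
  }
  NA_integer_
}
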