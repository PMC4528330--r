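#' ORF annotation with declared translation exceptions
#'
#' One coding region belonging to one gene on one transcript. All exceptions
#' that bend the standard rules of translation are *declared* here: they come
#' from curation, never from re-prediction.
#'
#' @param gene_id owning gene.
#' @param cds_segments list of [g_interval], ordered 5' to 3' along the
#'   transcript. The stop codon is included in the CDS (unless incomplete).
#' @param start_codon_kind `"AUG"` for a standard start, a 3-letter DNA codon
#'   (e.g. `"CTG"`) for a declared non-AUG start, or `"undetermined"`.
#' @param readthrough_positions codon indices (1-based within the ORF) of
#'   in-frame stop codons read through (translated as `"X"`).
#' @param selenocysteine_positions codon indices recoded as selenocysteine
#'   (`"U"`).
#' @param frameshift `NULL` or `list(codon_index =, shift = 1L)`: after
#'   translating `codon_index` codons, the ribosome skips one nucleotide
#'   (programmed +1 frameshift).
#' @param incomplete_stop `TRUE` when the stop codon is completed by
#'   post-transcriptional polyadenylation (mitochondrial transcripts).
#' @param genetic_code `"standard"` or `"invertebrate_mitochondrial"`.
#' @return object of class `orf_annotation`.
#' @export
orf_annotation <- function(gene_id, cds_segments,
                           start_codon_kind = "AUG",
                           readthrough_positions = integer(),
                           selenocysteine_positions = integer(),
                           frameshift = NULL,
                           incomplete_stop = FALSE,
                           genetic_code = "standard") {
  stopifnot(length(cds_segments) >= 1L)
  if (!(identical(start_codon_kind, "AUG") ||
        identical(start_codon_kind, "undetermined") ||
        grepl("^[ACGT]{3}$", start_codon_kind)))
    stop("start_codon_kind must be 'AUG', 'undetermined' or a 3-nt DNA codon")
  if (!genetic_code %in% c("standard", "invertebrate_mitochondrial"))
    stop("unknown genetic code: ", genetic_code)
  rt <- sort(unique(as.integer(readthrough_positions)))
  if (length(rt) && any(rt < 1L)) stop("readthrough positions must be >= 1")
  sec <- sort(unique(as.integer(selenocysteine_positions)))
  if (length(intersect(rt, sec)))
    stop("a codon cannot be both readthrough and selenocysteine")
  if (!is.null(frameshift)) {
    if (!identical(as.integer(frameshift$shift), 1L))
      stop("only a +1 translational frameshift is supported")
    frameshift <- list(codon_index = as.integer(frameshift$codon_index),
                       shift = 1L)
  }
  o <- structure(list(gene_id = as.character(gene_id),
                      cds_segments = cds_segments,
                      start_codon_kind = start_codon_kind,
                      readthrough_positions = rt,
                      selenocysteine_positions = sec,
                      frameshift = frameshift,
                      incomplete_stop = isTRUE(incomplete_stop),
                      genetic_code = genetic_code),
                 class = "orf_annotation")
  len <- sum(vapply(cds_segments, interval_len, integer(1)))
  eff <- len - if (is.null(frameshift)) 0L else 1L
  if (o$incomplete_stop) {
    if (eff %% 3L == 0L)
      stop("ORF for ", gene_id, " flagged incomplete_stop but CDS length ",
           "is a multiple of 3")
  } else if (eff %% 3L != 0L) {
    stop("CDS length for ", gene_id, " not a multiple of 3 (", len, " nt)")
  }
  o
}

#' Transcript model
#'
#' @param transcript_id identifier.
#' @param gene_ids ordered character vector of owning genes; more than one
#'   gene encodes a shared (dicistronic/polycistronic) transcript.
#' @param exons list of [g_interval] sorted 5' to 3' in transcript order.
#'   All exons must lie on one seqid and strand unless the transcript carries
#'   the declared `trans_spliced_transcript` flag.
#' @param orfs list of [orf_annotation], 5' to 3'; empty for a noncoding
#'   transcript.
#' @param declared_flags character vector of passthrough flag tokens (see
#'   [transcript_flag_vocabulary]).
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_ids, exons, orfs = list(),
                             declared_flags = character()) {
  stopifnot(length(exons) >= 1L, length(gene_ids) >= 1L)
  bad <- setdiff(declared_flags, names(transcript_flag_vocabulary()))
  if (length(bad)) stop("unknown exception token on ", transcript_id, ": ",
                        bad[1])
  t <- structure(list(transcript_id = as.character(transcript_id),
                      gene_ids = as.character(gene_ids),
                      exons = exons, orfs = orfs,
                      declared_flags = as.character(declared_flags)),
                 class = "transcript_model")
  validate_transcript(t)
  t
}

is_trans_spliced <- function(t) "trans_spliced_transcript" %in% t$declared_flags

validate_transcript <- function(t) {
  ex <- t$exons
  keys <- vapply(ex, function(e) paste0(e$seqid, e$strand), character(1))
  if (length(unique(keys)) > 1L && !is_trans_spliced(t))
    stop("transcript ", t$transcript_id, " mixes seqid/strand without a ",
         "declared trans_spliced_transcript flag")
  ## exons must not overlap one another (per seqid)
  for (i in seq_along(ex)) for (j in seq_len(i - 1L)) {
    if (intervals_intersect(ex[[i]], ex[[j]]))
      stop("overlapping exons on transcript ", t$transcript_id)
  }
  ## 5'->3' order within each same-strand block
  if (!is_trans_spliced(t) && length(ex) > 1L) {
    starts <- vapply(ex, `[[`, integer(1), "start")
    ordered <- if (ex[[1]]$strand == "+") all(diff(starts) > 0)
               else all(diff(starts) < 0)
    if (!ordered)
      stop("exons of ", t$transcript_id, " are not in 5'->3' order")
  }
  ## every CDS base must fall inside the exon union
  tkeys <- transcript_pos_keys(t)
  for (o in t$orfs) {
    if (!o$gene_id %in% t$gene_ids)
      stop("ORF gene ", o$gene_id, " is not an owner of transcript ",
           t$transcript_id)
    ckeys <- orf_pos_keys(o)
    if (!all(ckeys %in% tkeys))
      stop("CDS of gene ", o$gene_id, " extends outside the exon union of ",
           "transcript ", t$transcript_id)
    if (is.unsorted(match(ckeys, tkeys)))
      stop("CDS segments of gene ", o$gene_id, " are not in transcript ",
           "5'->3' order on ", t$transcript_id)
  }
  invisible(t)
}

## position keys in transcript (5'->3') order; key encodes seqid, strand and
## genomic base so that trans-spliced transcripts cannot collide
interval_pos_keys <- function(iv) {
  pos <- interval_positions(iv)
  if (iv$strand == "-") pos <- rev(pos)
  paste0(iv$seqid, iv$strand, pos)
}

transcript_pos_keys <- function(t) {
  unlist(lapply(t$exons, interval_pos_keys), use.names = FALSE)
}

orf_pos_keys <- function(o) {
  unlist(lapply(o$cds_segments, interval_pos_keys), use.names = FALSE)
}

orf_cds_length <- function(o) {
  sum(vapply(o$cds_segments, interval_len, integer(1)))
}

## transcript coordinates (1-based, 5'->3') of the first and last CDS base
orf_transcript_span <- function(o, t) {
  tk <- transcript_pos_keys(t)
  ck <- orf_pos_keys(o)
  idx <- match(ck, tk)
  if (anyNA(idx)) stop("ORF of ", o$gene_id, " not on transcript ",
                       t$transcript_id)
  c(first = idx[1], last = idx[length(idx)])
}

#' Annotation set
#'
#' Container tying genes to transcripts with referential integrity. Genes and
#' transcripts are stored sorted by identifier; gene spans (bounding intervals
#' per seqid/strand) are derived from the exons of their transcripts.
#'
#' @param transcripts list of [transcript_model].
#' @param gene_flags optional named list: gene_id -> character vector of
#'   gene-level declared flags.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts = list(), gene_flags = list()) {
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")
  if (anyDuplicated(names(transcripts)))
    stop("duplicate transcript id: ",
         names(transcripts)[duplicated(names(transcripts))][1])
  transcripts <- transcripts[order(names(transcripts))]
  gids <- sort(unique(unlist(lapply(transcripts, `[[`, "gene_ids"))))
  extra <- setdiff(names(gene_flags), gids)
  if (length(extra) && length(transcripts))
    stop("gene_flags given for unknown gene: ", extra[1])
  genes <- lapply(gids, function(g) {
    tids <- names(transcripts)[vapply(transcripts,
                                      function(t) g %in% t$gene_ids,
                                      logical(1))]
    list(gene_id = g, transcript_ids = tids,
         spans = gene_spans(transcripts[tids], g),
         flags = as.character(gene_flags[[g]] %||% character()))
  })
  names(genes) <- gids
  structure(list(genes = genes, transcripts = transcripts),
            class = "annotation_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gene_spans <- function(transcripts, gene_id) {
  ivs <- list()
  for (t in transcripts) for (e in t$exons) ivs <- c(ivs, list(e))
  keys <- vapply(ivs, function(e) paste0(e$seqid, "\r", e$strand), character(1))
  out <- list()
  for (k in unique(keys)) {
    sub <- ivs[keys == k]
    out[[length(out) + 1L]] <-
      g_interval(sub[[1]]$seqid,
                 min(vapply(sub, `[[`, integer(1), "start")),
                 max(vapply(sub, `[[`, integer(1), "end")),
                 sub[[1]]$strand)
  }
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  n_poly <- sum(vapply(x$transcripts,
                       function(t) length(t$orfs) > 1L, logical(1)))
  cat("annotation_set:", length(x$genes), "gene(s),",
      length(x$transcripts), "transcript(s)",
      if (n_poly) paste0("(", n_poly, " polycistronic)") else "", "\n")
  invisible(x)
}

## ---- spliced sequence and introns ----------------------------------------

#' Mature (spliced) transcript sequence
#'
#' Exon sequences are extracted strand-aware and concatenated in annotated
#' exon order; for trans-spliced transcripts this joins sequence from both
#' strands exactly as annotated.
#'
#' @param t a [transcript_model].
#' @param g a [genome_seq].
#' @return nucleotide string, 5' to 3' on the mature transcript.
#' @export
spliced_sequence <- function(t, g) {
  paste(vapply(t$exons, function(e) interval_seq(g, e), character(1)),
        collapse = "")
}

## spliced sequence of one ORF's CDS
cds_sequence <- function(o, g) {
  paste(vapply(o$cds_segments, function(e) interval_seq(g, e), character(1)),
        collapse = "")
}

intron_record <- function(interval, donor, acceptor, transcript_ids,
                          classification = character()) {
  structure(list(interval = interval, donor = donor, acceptor = acceptor,
                 transcript_ids = transcript_ids,
                 classification = classification),
            class = "intron_record")
}

#' @export
print.intron_record <- function(x, ...) {
  cat(sprintf("intron %s:[%d,%d)%s  %s-%s  %s\n", x$interval$seqid,
              x$interval$start, x$interval$end, x$interval$strand,
              x$donor, x$acceptor,
              paste(x$classification, collapse = ",")))
  invisible(x)
}

#' Introns of a transcript
#'
#' One record per adjacent exon pair, with the boundary dinucleotides (donor =
#' first two intron bases, acceptor = last two) read on the transcript strand.
#' For trans-spliced transcripts only same-seqid, same-strand adjacent pairs
#' yield introns; cross-strand gaps are skipped and counted in the
#' `skipped_gaps` attribute.
#'
#' @param t a [transcript_model] with at least 2 exons.
#' @param g a [genome_seq].
#' @return list of `intron_record`, with attribute `skipped_gaps`.
#' @export
introns_of <- function(t, g) {
  if (length(t$exons) < 2L)
    return(structure(list(), skipped_gaps = 0L))
  out <- list()
  skipped <- 0L
  for (i in seq_len(length(t$exons) - 1L)) {
    a <- t$exons[[i]]; b <- t$exons[[i + 1L]]
    if (a$seqid != b$seqid || a$strand != b$strand) {
      if (!is_trans_spliced(t))
        stop("cannot take intron across seqid/strand on ", t$transcript_id)
      skipped <- skipped + 1L
      next
    }
    iv <- if (a$strand == "+") g_interval(a$seqid, a$end, b$start, "+")
          else g_interval(a$seqid, b$end, a$start, "-")
    if (interval_len(iv) < 4L)
      stop("intron of ", t$transcript_id, " shorter than 4 nt")
    s <- interval_seq(g, iv)
    out[[length(out) + 1L]] <-
      intron_record(iv, donor = substr(s, 1L, 2L),
                    acceptor = substr(s, nchar(s) - 1L, nchar(s)),
                    transcript_ids = t$transcript_id)
  }
  structure(out, skipped_gaps = skipped)
}

## unique introns across a whole annotation set, merging supporting
## transcripts; keyed by seqid/start/end/strand
collect_introns <- function(set, g) {
  pool <- list()
  for (t in set$transcripts) {
    for (ir in introns_of(t, g)) {
      k <- intron_key(ir$interval)
      if (is.null(pool[[k]])) pool[[k]] <- ir
      else pool[[k]]$transcript_ids <-
          sort(unique(c(pool[[k]]$transcript_ids, ir$transcript_ids)))
    }
  }
  if (!length(pool)) return(list())
  pool[order(names(pool))]
}

intron_key <- function(iv) {
  sprintf("%s:%09d-%09d(%s)", iv$seqid, iv$start, iv$end, iv$strand)
}
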