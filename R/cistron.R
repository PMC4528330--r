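#' Cistronic arity of a transcript
#'
#' Number of ORFs (separately annotated coding genes) on the mature
#' transcript: 1 = monocistronic, 2 = dicistronic, 3 = tricistronic,
#' 4 = tetracistronic.
#'
#' @param t a [transcript_model].
#' @return integer arity.
#' @export
cistronic_arity <- function(t) length(t$orfs)

#' Cistronic profile of a gene
#'
#' Collects the arities of every transcript carrying the gene. A gene is
#' exclusively polycistronic when it has no monocistronic isoform.
#'
#' @param gene_id gene of interest.
#' @param set an [annotation_set].
#' @return list with `gene_id`, `arity_set` (sorted unique arities) and
#'   `exclusively_polycistronic`.
#' @export
gene_cistronic_profile <- function(gene_id, set) {
  g <- set$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene: ", gene_id)
  arities <- sort(unique(vapply(set$transcripts[g$transcript_ids],
                                cistronic_arity, integer(1))))
  arities <- arities[arities >= 1L]  # noncoding isoforms carry no cistron
  structure(list(gene_id = gene_id, arity_set = arities,
                 exclusively_polycistronic =
                   length(arities) > 0L && !(1L %in% arities)),
            class = "cistronic_profile")
}

#' Intercistronic distance on the mature transcript
#'
#' Signed distance in nucleotides between the last base of the upstream ORF's
#' stop codon and the first base of the downstream ORF's start codon, both in
#' transcript coordinates: 0 when the start immediately follows the stop,
#' negative when the two coding regions overlap in different reading frames.
#'
#' @param upstream,downstream [orf_annotation]s on `t`, with `upstream`
#'   preceding `downstream` in transcript coordinates.
#' @param t the shared [transcript_model].
#' @return integer distance (nt).
#' @export
intercistronic_distance <- function(upstream, downstream, t) {
  owners <- vapply(t$orfs, `[[`, character(1), "gene_id")
  if (!upstream$gene_id %in% owners || !downstream$gene_id %in% owners)
    stop("both ORFs must be annotated on transcript ", t$transcript_id)
  up <- orf_transcript_span(upstream, t)
  dn <- orf_transcript_span(downstream, t)
  if (up[["first"]] > dn[["first"]])
    stop("upstream ORF does not precede downstream ORF on ", t$transcript_id)
  as.integer(dn[["first"]] - up[["last"]] - 1L)
}

#' Size class of a small polypeptide
#'
#' Bins the predicted polypeptide length (stop codon excluded) into the size
#' classes used when screening for small-ORF cistrons.
#'
#' @param o an [orf_annotation].
#' @return `"<25 aa"`, `"25-45 aa"` or `">45 aa"`.
#' @export
small_polypeptide_class <- function(o) {
  len <- orf_cds_length(o)
  if (!is.null(o$frameshift)) len <- len - 1L
  if (o$incomplete_stop) len <- len + (3L - len %% 3L)
  aa <- len %/% 3L - 1L
  if (aa < 25L) "<25 aa" else if (aa <= 45L) "25-45 aa" else ">45 aa"
}

#' Gene pairs co-occurring on a transcript
#'
#' @param set an [annotation_set].
#' @return data.frame with columns `gene_a`, `gene_b` (lexicographic,
#'   `gene_a < gene_b`) and `n_shared_transcripts`.
#' @export
shared_transcript_pairs <- function(set) {
  rows <- list()
  for (t in set$transcripts) {
    gids <- sort(unique(t$gene_ids))
    if (length(gids) < 2L) next
    cmb <- utils::combn(gids, 2L)
    for (k in seq_len(ncol(cmb)))
      rows[[length(rows) + 1L]] <- c(cmb[1L, k], cmb[2L, k])
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      n_shared_transcripts = integer(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, rows)
  key <- paste(m[, 1], m[, 2], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[[`, character(1), 1L),
                    gene_b = vapply(parts, `[[`, character(1), 2L),
                    n_shared_transcripts = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
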