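#' Candidate noncanonical splice donor-acceptor pairs
#'
#' The one-base-off neighborhood of the primary canonical pair GT-AG with the
#' donor G held invariant, excluding the two canonical pairs (GT-AG, GC-AG).
#' Exactly eight pairs satisfy these criteria.
#'
#' @return character vector of `"DD-AA"` pair labels, sorted.
#' @export
enumerate_candidate_noncanonical_pairs <- function() {
  ref <- c("G", "T", "A", "G")
  bases <- c("A", "C", "G", "T")
  out <- character()
  for (pos in 2:4) {             # donor position 1 (G) is invariant
    for (b in setdiff(bases, ref[pos])) {
      v <- ref; v[pos] <- b
      out <- c(out, paste0(v[1], v[2], "-", v[3], v[4]))
    }
  }
  sort(setdiff(out, c("GT-AG", "GC-AG")))
}

splice_pair <- function(i) paste0(i$donor, "-", i$acceptor)

#' Classify an intron by its boundary dinucleotides
#'
#' @param i an `intron_record` with donor/acceptor populated.
#' @param declared_flags declared flags of the supporting transcript(s);
#'   `endonuclease_spliced_intron` gates the HAC1-type class and the
#'   sequence-alteration flags gate the `convenience` class (gene models
#'   drawn across assembly gaps, strain variation or transposon insertions).
#' @return one of `canonical_GT_AG`, `canonical_GC_AG`,
#'   `noncanonical:<pair>`, `noncanonical_AT_AC`, `endonuclease_spliced`,
#'   `convenience`, `other_nonconforming`.
#' @export
classify_intron <- function(i, declared_flags = character()) {
  pair <- splice_pair(i)
  if (pair == "GT-AG") return("canonical_GT_AG")
  if (pair == "GC-AG") return("canonical_GC_AG")
  if (pair == "CA-TG" && "endonuclease_spliced_intron" %in% declared_flags)
    return("endonuclease_spliced")
  if (pair %in% enumerate_candidate_noncanonical_pairs())
    return(paste0("noncanonical:", pair))
  if (pair == "AT-AC") return("noncanonical_AT_AC")
  if (any(c("genomic sequence error or gap", "mutation in strain") %in%
            declared_flags))
    return("convenience")
  "other_nonconforming"
}

#' Tag an intron as U12 (minor spliceosome) type
#'
#' Matches the configured 5' consensus at the intron start (default
#' `[GA]TATCC`, i.e. the donor dinucleotide followed by ATCC); branch-point
#' matching is not attempted. U12-type introns occur with both GT-AG and
#' AT-AC termini.
#'
#' @param i an `intron_record`.
#' @param g a [genome_seq].
#' @param config an [audit_config] (`u12_pattern`).
#' @return logical.
#' @export
tag_u12 <- function(i, g, config = audit_config()) {
  if (interval_len(i$interval) < 10L) return(FALSE)
  grepl(config$u12_pattern, interval_seq(g, i$interval))
}

## intron boundary positions on the transcript strand:
## donor = 5' end of the intron, acceptor = 3' end
intron_donor_pos <- function(iv) if (iv$strand == "+") iv$start else iv$end
intron_acceptor_pos <- function(iv) if (iv$strand == "+") iv$end else iv$start

#' Similar alternative canonical splice for a noncanonical intron
#'
#' Looks for an annotated canonical (GT-AG / GC-AG) intron of the same gene
#' sharing exactly one boundary with the query (same donor position,
#' different acceptor, or vice versa). The nearest alternative boundary wins;
#' ties break toward the smaller coordinate shift, then toward the upstream
#' (5'-ward) alternative.
#'
#' @param i a noncanonical `intron_record`.
#' @param set the [annotation_set].
#' @param g a [genome_seq].
#' @return the matching canonical `intron_record`, or `NULL`.
#' @export
similar_alternative_splice <- function(i, set, g) {
  genes <- unique(unlist(lapply(i$transcript_ids, function(tid)
    set$transcripts[[tid]]$gene_ids)))
  tids <- unique(unlist(lapply(genes, function(gid)
    set$genes[[gid]]$transcript_ids)))
  cand <- list()
  seen <- character()
  for (tid in tids) {
    for (j in introns_of(set$transcripts[[tid]], g)) {
      k <- intron_key(j$interval)
      if (k %in% seen || k == intron_key(i$interval)) next
      seen <- c(seen, k)
      if (!classify_intron(j) %in% c("canonical_GT_AG", "canonical_GC_AG"))
        next
      if (j$interval$seqid != i$interval$seqid ||
          j$interval$strand != i$interval$strand) next
      same_donor <- intron_donor_pos(j$interval) == intron_donor_pos(i$interval)
      same_acceptor <-
        intron_acceptor_pos(j$interval) == intron_acceptor_pos(i$interval)
      if (xor(same_donor, same_acceptor)) {
        moved_q <- if (same_donor) intron_acceptor_pos(i$interval)
                   else intron_donor_pos(i$interval)
        moved_c <- if (same_donor) intron_acceptor_pos(j$interval)
                   else intron_donor_pos(j$interval)
        shift <- abs(moved_c - moved_q)
        ## upstream = 5'-ward on the transcript strand
        upstream_rank <- if (i$interval$strand == "+") moved_c else -moved_c
        cand[[length(cand) + 1L]] <-
          list(intron = j, shift = shift, rank = upstream_rank)
      }
    }
  }
  if (!length(cand)) return(NULL)
  shifts <- vapply(cand, `[[`, numeric(1), "shift")
  ranks <- vapply(cand, `[[`, numeric(1), "rank")
  cand[[order(shifts, ranks)[1]]]$intron
}

#' Junction call constructor
#'
#' @param seqid,start,end zero-based half-open junction interval (the intron
#'   the aligner inferred).
#' @param strand `"+"`, `"-"`, or `NA` for an unstranded call.
#' @param read_count supporting reads.
#' @param score aligner confidence score.
#' @param name optional identifier.
#' @return object of class `junction_call`.
#' @export
junction_call <- function(seqid, start, end, strand = NA_character_,
                          read_count = 0L, score = 1, name = NA_character_) {
  structure(list(interval = g_interval(seqid, start, end,
                                       if (is.na(strand)) "+" else strand),
                 stranded = !is.na(strand),
                 read_count = as.integer(read_count),
                 score = as.numeric(score), name = name),
            class = "junction_call")
}

#' Read junction calls from BED
#'
#' Six-column BED, zero-based half-open. Dialect: the BED score column
#' carries the supporting read count; an optional seventh numeric column
#' carries an aligner confidence score (default 1); strand `"."` marks an
#' unstranded call.
#'
#' @param path BED file.
#' @return list of [junction_call].
#' @export
read_junctions <- function(path) {
  first <- readLines(path, n = 1L)
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  gr <- if (ncol >= 7L)
    rtracklayer::import(path, format = "BED",
                        extraCols = c(conf = "numeric"))
  else rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  if (is.null(df$name)) df$name <- NA_character_
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$conf)) df$conf <- 1
  lapply(seq_len(nrow(df)), function(k) {
    st <- as.character(df$strand[k])
    junction_call(as.character(df$seqnames[k]), df$start[k] - 1L, df$end[k],
                  strand = if (st %in% c("+", "-")) st else NA_character_,
                  read_count = df$score[k], score = df$conf[k],
                  name = df$name[k])
  })
}

#' Audit one junction call against the annotated introns
#'
#' Verdicts, in precedence order: `matches_annotated` (coordinates equal an
#' annotated intron, compatible strand); `strand_flip_gt_at` (an unstranded
#' or opposite-strand AT-AC call that coincides with an annotated GT-AT
#' intron read on the other strand); `off_by_one_artifact` (the whole
#' junction displaced by one nucleotide from a canonical annotated intron);
#' `low_frequency` (culled by the read-count/score thresholds);
#' `misaligned_near_annotated` (both boundaries within `junction_window` nt
#' of an annotated intron); otherwise `unsupported_noncanonical`.
#'
#' @param j a [junction_call].
#' @param set the [annotation_set].
#' @param g a [genome_seq].
#' @param config an [audit_config].
#' @param introns optionally, precomputed `collect_introns(set, g)`.
#' @return list of class `junction_diagnosis`: `verdict`, `nearest`
#'   (intron key or `NA`), `offset` (0 iff `matches_annotated`, the
#'   displacement for off-by-one/misaligned calls, otherwise `NA`).
#' @export
audit_junction <- function(j, set, g, config = audit_config(),
                           introns = collect_introns(set, g)) {
  diag <- function(verdict, nearest = NA_character_, offset = NA_integer_)
    structure(list(verdict = verdict, nearest = nearest,
                   offset = offset), class = "junction_diagnosis")
  iv <- j$interval
  same_coord <- Filter(function(ir)
    ir$interval$seqid == iv$seqid && ir$interval$start == iv$start &&
      ir$interval$end == iv$end, introns)
  for (ir in same_coord) {
    if (j$stranded && ir$interval$strand == iv$strand)
      return(diag("matches_annotated", intron_key(ir$interval), 0L))
  }
  for (ir in same_coord) {
    if ((!j$stranded || ir$interval$strand != iv$strand) &&
        splice_pair(ir) == "GT-AT") {
      ## read on the caller's (opposite) strand the boundaries are AT..AC
      return(diag("strand_flip_gt_at", intron_key(ir$interval)))
    }
  }
  if (length(same_coord) && !j$stranded)
    return(diag("matches_annotated", intron_key(same_coord[[1]]$interval), 0L))
  for (shift in c(-1L, 1L)) {
    hit <- Filter(function(ir)
      ir$interval$seqid == iv$seqid &&
        ir$interval$start == iv$start + shift &&
        ir$interval$end == iv$end + shift &&
        classify_intron(ir) %in% c("canonical_GT_AG", "canonical_GC_AG"),
      introns)
    if (length(hit))
      return(diag("off_by_one_artifact", intron_key(hit[[1]]$interval),
                  -shift))
  }
  if (j$read_count < config$junction_min_count ||
      j$score < config$junction_min_score)
    return(diag("low_frequency"))
  best <- NULL; best_d <- Inf
  for (ir in introns) {
    if (ir$interval$seqid != iv$seqid) next
    d <- max(abs(ir$interval$start - iv$start), abs(ir$interval$end - iv$end))
    if (d < best_d) { best <- ir; best_d <- d }
  }
  if (!is.null(best) && best_d <= config$junction_window)
    return(diag("misaligned_near_annotated", intron_key(best$interval),
                as.integer(best_d)))
  diag("unsupported_noncanonical")
}

## ---- census ---------------------------------------------------------------

census_row_order <- function() {
  c("AT-AC (U12)", "AT-AC (U2)", "GT-TG", "GT-GG", "GT-CG", "GT-AT", "GT-AA",
    "GA-AG", "GG-AG", "GT-AC")
}

## context of an intron: "coding", "utr5" or "lncrna" (introns at or past the
## CDS start, including 3' UTR introns, count as coding)
intron_context <- function(ir, set) {
  ctxs <- vapply(ir$transcript_ids, function(tid) {
    t <- set$transcripts[[tid]]
    if (!length(t$orfs)) return("lncrna")
    cum <- 0L
    jpoint <- NA_integer_
    for (k in seq_len(length(t$exons) - 1L)) {
      cum <- cum + interval_len(t$exons[[k]])
      a <- t$exons[[k]]; b <- t$exons[[k + 1L]]
      if (a$seqid != b$seqid || a$strand != b$strand) next
      iv <- if (a$strand == "+") c(a$end, b$start) else c(b$end, a$start)
      if (identical(iv[1], ir$interval$start) &&
          identical(iv[2], ir$interval$end)) { jpoint <- cum; break }
    }
    if (is.na(jpoint)) return(NA_character_)
    cds_first <- min(vapply(t$orfs, function(o)
      orf_transcript_span(o, t)[["first"]], numeric(1)))
    if (jpoint < cds_first) "utr5" else "coding"
  }, character(1))
  ctxs <- ctxs[!is.na(ctxs)]
  if (!length(ctxs)) return("coding")
  if (all(ctxs == "lncrna")) "lncrna"
  else if (any(ctxs == "coding")) "coding"
  else "utr5"
}

#' Noncanonical splice census
#'
#' Per donor-acceptor pair: the number of annotated introns, the number with
#' an exactly matching junction call, the number with a similar alternative
#' canonical splice, and counts by context (within coding sequence, within a
#' 5' UTR, within a lncRNA). AT-AC introns are split into U12- and U2-type
#' rows by the 5' consensus; canonical-boundary U12 introns are appended as
#' footer rows and excluded from the Total.
#'
#' @param set an [annotation_set].
#' @param g a [genome_seq].
#' @param junctions list of [junction_call] (optional).
#' @param config an [audit_config].
#' @return data.frame of class `splice_census` with a `Total` row.
#' @export
splice_summary <- function(set, g, junctions = NULL,
                           config = audit_config()) {
  introns <- collect_introns(set, g)
  rows <- c(census_row_order(), "GT-AG (U12)", "GC-AG (U12)")
  tab <- data.frame(pair = rows, n_introns = 0L, n_junction_support = 0L,
                    n_similar_alternative = 0L, n_coding = 0L, n_utr5 = 0L,
                    n_lncrna = 0L, stringsAsFactors = FALSE)
  jn_keys <- unique(vapply(junctions %||% list(), function(j)
    intron_key_unstranded(j$interval), character(1)))
  for (ir in introns) {
    flags <- unique(unlist(lapply(ir$transcript_ids, function(tid)
      set$transcripts[[tid]]$declared_flags)))
    cls <- classify_intron(ir, flags)
    u12 <- tag_u12(ir, g, config)
    pair <- splice_pair(ir)
    row <- if (cls == "canonical_GT_AG") { if (u12) "GT-AG (U12)" else NA }
      else if (cls == "canonical_GC_AG") { if (u12) "GC-AG (U12)" else NA }
      else if (cls == "noncanonical_AT_AC")
        paste0("AT-AC (", if (u12) "U12" else "U2", ")")
      else if (startsWith(cls, "noncanonical:")) sub("noncanonical:", "", cls)
      else NA  # endonuclease-spliced and convenience splices are not census'd
    if (is.na(row)) next
    k <- which(tab$pair == row)
    tab$n_introns[k] <- tab$n_introns[k] + 1L
    if (intron_key_unstranded(ir$interval) %in% jn_keys)
      tab$n_junction_support[k] <- tab$n_junction_support[k] + 1L
    if (!startsWith(row, "GT-AG") && !startsWith(row, "GC-AG") &&
        !is.null(similar_alternative_splice(ir, set, g)))
      tab$n_similar_alternative[k] <- tab$n_similar_alternative[k] + 1L
    ctx <- intron_context(ir, set)
    col <- c(coding = "n_coding", utr5 = "n_utr5", lncrna = "n_lncrna")[ctx]
    tab[[col]][k] <- tab[[col]][k] + 1L
  }
  census_with_total(tab)
}

intron_key_unstranded <- function(iv)
  sprintf("%s:%09d-%09d", iv$seqid, iv$start, iv$end)

## insert the Total row (sum over the main pair rows; footer rows excluded)
census_with_total <- function(tab) {
  main <- tab$pair %in% census_row_order()
  total <- data.frame(pair = "Total", t(colSums(tab[main, -1, drop = FALSE],
                                                na.rm = TRUE)),
                      stringsAsFactors = FALSE)
  names(total) <- names(tab)
  out <- rbind(tab[main, , drop = FALSE], total,
               tab[!main, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("splice_census", "data.frame")
  out
}

#' Read a splice census table from TSV
#'
#' Expects the per-pair rows (no Total row); [census_with_totals] recomputes
#' the Total. `NA` marks columns not applicable to unobserved pairs.
#'
#' @param path TSV with columns `pair`, `n_introns`, `n_junction_support`,
#'   `n_similar_alternative`, `n_coding`, `n_utr5`, `n_lncrna`.
#' @return data.frame.
#' @export
read_splice_census <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Recompute the Total row of a census table
#'
#' @param tab per-pair census rows (as from [read_splice_census]).
#' @return `splice_census` data.frame with the Total row inserted.
#' @export
census_with_totals <- function(tab) census_with_total(tab)

#' Observed one-base-off pairs in a census
#'
#' @param tab a census data.frame.
#' @return number of candidate (one-base-off, invariant donor G) pairs with
#'   at least one annotated intron.
#' @export
observed_candidate_pairs <- function(tab) {
  cand <- enumerate_candidate_noncanonical_pairs()
  sum(tab$pair %in% cand & !is.na(tab$n_introns) & tab$n_introns > 0L)
}
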