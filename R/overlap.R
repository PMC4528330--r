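#' Codon offset (phase) map of an ORF
#'
#' For every genomic base of the spliced CDS, the offset of that base within
#' its codon (0, 1, 2), counted 5' to 3' along the transcript. This is the
#' substrate for frame comparisons between overlapping coding regions.
#'
#' @param o an [orf_annotation].
#' @param t its [transcript_model] (used for validation only).
#' @return list with `seqid`, `strand`, `pos` (0-based genomic positions in
#'   translation order) and `offset` (integer 0/1/2 per position).
#' @export
codon_offset_map <- function(o, t = NULL) {
  seqids <- unique(vapply(o$cds_segments, `[[`, character(1), "seqid"))
  strands <- unique(vapply(o$cds_segments, `[[`, character(1), "strand"))
  if (length(seqids) > 1L || length(strands) > 1L)
    stop("codon offsets are defined per seqid/strand; ORF of ", o$gene_id,
         " mixes them")
  pos <- unlist(lapply(o$cds_segments, function(s) {
    p <- interval_positions(s)
    if (s$strand == "-") rev(p) else p
  }), use.names = FALSE)
  list(gene_id = o$gene_id, seqid = seqids, strand = strands,
       pos = pos, offset = (seq_along(pos) - 1L) %% 3L)
}

## genomic positions of an ORF's stop codon (last 3 CDS bases)
orf_stop_positions <- function(map) {
  n <- length(map$pos)
  if (n < 3L) integer() else map$pos[(n - 2L):n]
}

#' Multiphasic regions between two coding regions
#'
#' Maximal runs of genomic bases that are coding in both ORFs but translated
#' in different reading frames. Symmetric in its first two arguments.
#'
#' @param a,b [orf_annotation]s on the same seqid and strand (overlapping
#'   opposite-strand CDSs are a different phenomenon; see
#'   [detect_bidirectional]).
#' @param members optional character(2) labels for reporting (defaults to the
#'   gene ids).
#' @return list of `multiphasic_region` objects with fields `interval`,
#'   `length_nt`, `members`, `involves_first_coding_exon`, `cross_gene`,
#'   `includes_stop`.
#' @export
multiphasic_regions <- function(a, b, members = NULL) {
  ma <- codon_offset_map(a)
  mb <- codon_offset_map(b)
  if (ma$seqid != mb$seqid) return(list())
  if (ma$strand != mb$strand)
    stop("ORFs on opposite strands: use detect_bidirectional()")
  if (is.null(members)) members <- c(a$gene_id, b$gene_id)
  shared <- intersect(ma$pos, mb$pos)
  if (!length(shared)) return(list())
  off_a <- ma$offset[match(shared, ma$pos)]
  off_b <- mb$offset[match(shared, mb$pos)]
  conflict <- shared[off_a != off_b]
  runs <- runs_of(conflict)
  lapply(runs, function(r) {
    iv <- g_interval(ma$seqid, r[["start"]], r[["end"]], ma$strand)
    run_pos <- seq.int(r[["start"]], r[["end"]] - 1L)
    stops <- c(orf_stop_positions(ma), orf_stop_positions(mb))
    first_exon_hit <- any(vapply(list(a$cds_segments[[1]], b$cds_segments[[1]]),
                                 function(s) intervals_intersect(s, iv),
                                 logical(1)))
    structure(list(interval = iv, length_nt = interval_len(iv),
                   members = members,
                   involves_first_coding_exon = first_exon_hit,
                   cross_gene = a$gene_id != b$gene_id,
                   includes_stop = any(stops %in% run_pos)),
              class = "multiphasic_region")
  })
}

#' Audit configuration
#'
#' All tunable thresholds in one record. Defaults follow the curation rules
#' the classifications are modeled on: multiphasic extents shorter than 40 nt
#' (stop codon included, i.e. fewer than 13 aa) are reported as alternative
#' translation stops; extents above 63 nt (>20 aa) are additionally marked as
#' long overlaps.
#'
#' @param multiphasic_short_nt within-gene extents strictly below this are
#'   "alternative translation stop" cases (nt).
#' @param long_overlap_nt extents strictly above this are marked
#'   `long_overlap` (nt).
#' @param u12_pattern regular expression the 5' end of an intron must match
#'   to be tagged U12-type.
#' @param junction_min_count,junction_min_score culling thresholds for
#'   low-frequency / low-confidence junction calls.
#' @param junction_window maximum boundary offset (nt) for a junction to be
#'   "misaligned near" an annotated intron.
#' @return list of class `audit_config`.
#' @export
audit_config <- function(multiphasic_short_nt = 40L,
                         long_overlap_nt = 63L,
                         u12_pattern = "^[GA]TATCC",
                         junction_min_count = 2L,
                         junction_min_score = 0,
                         junction_window = 6L) {
  structure(list(multiphasic_short_nt = as.integer(multiphasic_short_nt),
                 long_overlap_nt = as.integer(long_overlap_nt),
                 u12_pattern = u12_pattern,
                 junction_min_count = as.integer(junction_min_count),
                 junction_min_score = as.numeric(junction_min_score),
                 junction_window = as.integer(junction_window)),
            class = "audit_config")
}

#' Read an audit configuration from YAML
#'
#' @param path YAML file whose keys are [audit_config] arguments.
#' @return an `audit_config`.
#' @export
read_audit_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(audit_config)))
  if (length(bad)) stop("unknown configuration key: ", bad[1])
  do.call(audit_config, vals)
}

#' Classify a multiphasic region with the standardized comment vocabulary
#'
#' Cross-gene regions get the shared-coding-region comment; within-gene
#' regions involving the first coding exon take precedence over the
#' short-extent rule; short extents (< `multiphasic_short_nt`) that include a
#' stop codon are "alternative translation stop" cases; everything else is a
#' postulated multiphase exon. Regions longer than `long_overlap_nt` are
#' additionally marked `long_overlap`.
#'
#' @param r a `multiphasic_region`.
#' @param config an [audit_config].
#' @return list with `comment` (verbatim vocabulary string) and
#'   `long_overlap` (logical).
#' @export
classify_multiphasic <- function(r, config = audit_config()) {
  comment <-
    if (r$cross_gene) mp_comment("cross_gene")
    else if (r$involves_first_coding_exon) mp_comment("first_coding_exon")
    else if (r$length_nt < config$multiphasic_short_nt && r$includes_stop)
      mp_comment("alt_stop")
    else mp_comment("multiphase_exon")
  list(comment = comment, long_overlap = r$length_nt > config$long_overlap_nt)
}

#' Amino-acid bound implied by a multiphasic nucleotide threshold
#'
#' A multiphasic extent measured *including* the stop codon and strictly
#' below `nt_threshold` nucleotides can change at most
#' `multiphasic_aa_bound(nt_threshold) - 1` amino acids; the returned value
#' is the strict upper bound (13 for the default 40-nt rule).
#'
#' @param nt_threshold nucleotide threshold (extent strictly below it).
#' @return strict amino-acid upper bound.
#' @export
multiphasic_aa_bound <- function(nt_threshold = 40L) {
  ((nt_threshold - 1L) - 3L) %/% 3L + 1L
}

#' Bidirectional coding overlap between opposite-strand ORFs
#'
#' @param a,b [orf_annotation]s on opposite strands of one seqid.
#' @return `NULL` when the CDSs share no genomic base; otherwise a list with
#'   `regions` (maximal shared runs as intervals), `length_nt` (total) and
#'   the verbatim `comment`.
#' @export
detect_bidirectional <- function(a, b) {
  ma <- codon_offset_map(a)
  mb <- codon_offset_map(b)
  if (ma$seqid != mb$seqid) return(NULL)
  if (ma$strand == mb$strand)
    stop("ORFs on the same strand: use multiphasic/same-frame classifiers")
  shared <- intersect(ma$pos, mb$pos)
  if (!length(shared)) return(NULL)
  runs <- runs_of(shared)
  regions <- lapply(runs, function(r)
    g_interval(ma$seqid, r[["start"]], r[["end"]], "+"))
  list(members = c(a$gene_id, b$gene_id), regions = regions,
       length_nt = sum(vapply(regions, interval_len, integer(1))),
       comment = mp_comment("bidirectional"))
}

#' Same-frame CDS overlap between two genes
#'
#' Reports maximal runs of genomic bases coding in both genes with *equal*
#' codon offsets (e.g. gene pairs sharing a promoter, translation start and
#' an N-terminal stretch of coding sequence). Bases coding in both but in
#' different frames belong to [multiphasic_regions] instead: every shared
#' coding base is classified by exactly one of the two.
#'
#' @param gA,gB gene identifiers.
#' @param set an [annotation_set].
#' @return `NULL` when no same-frame shared coding base exists, else a list
#'   with `gene_a`, `gene_b`, `regions`, `length_nt`, `comment`.
#' @export
detect_cds_overlap_same_frame <- function(gA, gB, set) {
  shared_pos <- c()
  seqid <- NULL
  for (oa in gene_orfs(set, gA)) for (ob in gene_orfs(set, gB)) {
    ma <- codon_offset_map(oa); mb <- codon_offset_map(ob)
    if (ma$seqid != mb$seqid || ma$strand != mb$strand) next
    sh <- intersect(ma$pos, mb$pos)
    if (!length(sh)) next
    same <- sh[ma$offset[match(sh, ma$pos)] == mb$offset[match(sh, mb$pos)]]
    if (length(same)) { shared_pos <- c(shared_pos, same); seqid <- ma$seqid
                        strand <- ma$strand }
  }
  if (!length(shared_pos)) return(NULL)
  runs <- runs_of(shared_pos)
  regions <- lapply(runs, function(r)
    g_interval(seqid, r[["start"]], r[["end"]], strand))
  list(gene_a = gA, gene_b = gB, regions = regions,
       length_nt = sum(vapply(regions, interval_len, integer(1))),
       comment = overlap_comment("cds_overlap_same_frame"))
}

## all distinct ORFs of a gene across its transcripts (deduplicated on CDS
## coordinates and declared exceptions)
gene_orfs <- function(set, gene_id) {
  g <- set$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene: ", gene_id)
  out <- list(); seen <- character()
  for (tid in g$transcript_ids) {
    for (o in set$transcripts[[tid]]$orfs) {
      if (o$gene_id != gene_id) next
      k <- paste(vapply(o$cds_segments, intron_key, character(1)),
                 collapse = ";")
      if (k %in% seen) next
      seen <- c(seen, k)
      attr(o, "transcript_id") <- tid
      out[[length(out) + 1L]] <- o
    }
  }
  out
}

#' Classify a same-strand noncoding overlap between two genes
#'
#' For gene pairs that overlap on the same strand without sharing any coding
#' base (and without sharing a transcript, which is the polycistronic case):
#' identical 5'-terminal exons or a shared 5' exon start (shared promoter)
#' give `shared_5_exons`; a shared 3'-terminal exon gives `shared_3_utr`;
#' both at once is `complex_atypical`. Two configurations are recognized but
#' deliberately not flagged with a comment: a gene nested inside another
#' gene's intron (`nested_unflagged`) and a 3' UTR running over the
#' downstream gene's 5' UTR (`utr_chain_unflagged`).
#'
#' @param gA,gB gene identifiers.
#' @param set an [annotation_set].
#' @return list of class `overlap_call`: `gene_a`, `gene_b`, `category`,
#'   `comment` (`NA` for the unflagged categories).
#' @export
classify_noncoding_overlap <- function(gA, gB, set) {
  ga <- set$genes[[gA]]; gb <- set$genes[[gB]]
  if (is.null(ga) || is.null(gb)) stop("unknown gene pair ", gA, "/", gB)
  ta <- own_transcripts(set, gA, exclude_shared_with = gB)
  tb <- own_transcripts(set, gB, exclude_shared_with = gA)
  shared5 <- FALSE; shared3 <- FALSE
  for (a in ta) for (b in tb) {
    ea <- a$exons[[1]]; eb <- b$exons[[1]]
    if (ea$seqid == eb$seqid && ea$strand == eb$strand &&
        five_prime(ea) == five_prime(eb)) shared5 <- TRUE
    la <- a$exons[[length(a$exons)]]; lb <- b$exons[[length(b$exons)]]
    if (la$seqid == lb$seqid && la$strand == lb$strand &&
        three_prime(la) == three_prime(lb)) shared3 <- TRUE
  }
  category <-
    if (shared5 && shared3) "complex_atypical"
    else if (shared5) "shared_5_exons"
    else if (shared3) "shared_3_utr"
    else if (gene_nested_in_intron(set, gA, gB) ||
             gene_nested_in_intron(set, gB, gA)) "nested_unflagged"
    else if (utr_chain(set, gA, gB)) "utr_chain_unflagged"
    else "none"
  structure(list(gene_a = gA, gene_b = gB, category = category,
                 comment = overlap_comment(category)),
            class = "overlap_call")
}

## 5' / 3' boundary coordinate of an interval on its own strand
five_prime <- function(iv) if (iv$strand == "+") iv$start else iv$end
three_prime <- function(iv) if (iv$strand == "+") iv$end else iv$start

own_transcripts <- function(set, gid, exclude_shared_with = NULL) {
  tids <- set$genes[[gid]]$transcript_ids
  out <- set$transcripts[tids]
  if (!is.null(exclude_shared_with))
    out <- Filter(function(t) !exclude_shared_with %in% t$gene_ids, out)
  out
}

## is every exon of `inner` inside one intron of some transcript of `outer`?
gene_nested_in_intron <- function(set, inner, outer) {
  spans <- set$genes[[inner]]$spans
  if (length(spans) != 1L) return(FALSE)
  sp <- spans[[1]]
  for (t in own_transcripts(set, outer)) {
    if (length(t$exons) < 2L) next
    ex <- t$exons
    for (i in seq_len(length(ex) - 1L)) {
      a <- ex[[i]]; b <- ex[[i + 1L]]
      if (a$seqid != sp$seqid || a$strand != sp$strand) next
      lo <- min(a$end, b$end); hi <- max(a$start, b$start)
      if (lo <= sp$start && sp$end <= hi) return(TRUE)
    }
  }
  FALSE
}

## 3'-terminal exon of the upstream gene overlapping the 5'-terminal exon of
## the downstream gene (UTR over UTR, not flagged)
utr_chain <- function(set, gA, gB) {
  for (a in own_transcripts(set, gA)) for (b in own_transcripts(set, gB)) {
    for (pair in list(c(1, 2), c(2, 1))) {
      up <- list(a, b)[[pair[1]]]; dn <- list(a, b)[[pair[2]]]
      last_up <- up$exons[[length(up$exons)]]
      first_dn <- dn$exons[[1]]
      if (last_up$strand == first_dn$strand &&
          intervals_intersect(last_up, first_dn)) return(TRUE)
    }
  }
  FALSE
}
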