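## Deterministic synthetic fixtures: a toy genome plus gene models with
## planted exceptional features and a ground-truth manifest, so every
## classifier can be exercised end-to-end without external data.
##
## Planted ORFs are built codon-wise from non-stop codons (so their expected
## peptides are known at planting time); loci whose construction couples two
## reading frames (multiphasic, bidirectional, overlapping cistrons) fix the
## required motifs and resample the free positions until both frames are
## stop-free.

#' Fixture specification
#'
#' Counts per planted exception category. The defaults plant one locus of
#' every category (mirroring that several of these phenomena have exactly one
#' or two known representatives) plus two plain monocistronic control genes.
#'
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param mono plain single-ORF control genes.
#' @param dicistronic,tricistronic,tetracistronic shared transcripts with
#'   2/3/4 cistrons.
#' @param shared_5,shared_3 gene pairs sharing 5'-terminal / 3'-terminal
#'   noncoding exons.
#' @param multiphasic_short,multiphasic_long within-gene multiphasic regions
#'   (about 30 nt including the alternative stop, and about 81 nt).
#' @param multiphasic_cross overlapping cistrons of one dicistronic
#'   transcript translated in different frames (70 nt overlap).
#' @param bidirectional opposite-strand CDS overlaps (50 nt).
#' @param noncanonical named integer vector over the eight candidate
#'   one-base-off pairs.
#' @param at_ac_u12,at_ac_u2,gt_ag_u12 AT-AC introns with/without the U12 5'
#'   consensus, and a U12-consensus GT-AG intron.
#' @param hac1 endonuclease-spliced 23-nt CA-TG introns (declared).
#' @param trans_splice trans-spliced transcripts joining exons from opposite
#'   strands (declared).
#' @param cug_start,undetermined_start declared non-AUG / undetermined
#'   translation starts.
#' @param sec,readthrough,double_readthrough,frameshift translation
#'   exceptions (selenocysteine, single and double stop-codon readthrough,
#'   +1 ribosomal frameshift).
#' @param mito_incomplete_stop mitochondrial genes (invertebrate
#'   mitochondrial code) with a polyadenylation-completed stop.
#' @param edited genes with an A-to-I editing site.
#' @param contig_length optional fixed main-contig length; error when too
#'   small for the requested features (default: sized automatically).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, mono = 2L, dicistronic = 1L,
                         tricistronic = 1L, tetracistronic = 1L,
                         shared_5 = 1L, shared_3 = 1L,
                         multiphasic_short = 1L, multiphasic_long = 1L,
                         multiphasic_cross = 1L, bidirectional = 1L,
                         noncanonical = c("GA-AG" = 1L, "GG-AG" = 1L,
                                          "GT-TG" = 1L, "GT-GG" = 1L,
                                          "GT-CG" = 1L, "GT-AA" = 1L,
                                          "GT-AT" = 1L, "GT-AC" = 1L),
                         at_ac_u12 = 1L, at_ac_u2 = 1L, gt_ag_u12 = 1L,
                         hac1 = 1L, trans_splice = 1L, cug_start = 1L,
                         undetermined_start = 1L, sec = 1L, readthrough = 1L,
                         double_readthrough = 1L, frameshift = 1L,
                         mito_incomplete_stop = 1L, edited = 1L,
                         contig_length = NULL) {
  spec <- list(seed = as.integer(seed), mono = mono,
               dicistronic = dicistronic, tricistronic = tricistronic,
               tetracistronic = tetracistronic, shared_5 = shared_5,
               shared_3 = shared_3, multiphasic_short = multiphasic_short,
               multiphasic_long = multiphasic_long,
               multiphasic_cross = multiphasic_cross,
               bidirectional = bidirectional, noncanonical = noncanonical,
               at_ac_u12 = at_ac_u12, at_ac_u2 = at_ac_u2,
               gt_ag_u12 = gt_ag_u12, hac1 = hac1,
               trans_splice = trans_splice, cug_start = cug_start,
               undetermined_start = undetermined_start, sec = sec,
               readthrough = readthrough,
               double_readthrough = double_readthrough,
               frameshift = frameshift,
               mito_incomplete_stop = mito_incomplete_stop, edited = edited,
               contig_length = contig_length)
  counts <- unlist(spec[setdiff(names(spec), c("seed", "contig_length"))])
  if (any(counts < 0)) stop("fixture counts must be non-negative")
  bad <- setdiff(names(spec$noncanonical),
                 enumerate_candidate_noncanonical_pairs())
  if (length(bad)) stop("not a candidate noncanonical pair: ", bad[1])
  structure(spec, class = "fixture_spec")
}

## ---- low-level planting helpers ------------------------------------------

.BASES <- c("A", "C", "G", "T")

rnt <- function(n) sample(.BASES, n, replace = TRUE)

sense_codons <- function(tab) names(tab)[tab != "*"]

rcod <- function(n, tab) {
  if (n == 0L) return(character())
  sample(sense_codons(tab), n, replace = TRUE)
}

## expected peptide for a planted CDS (stop codon included at the end)
plant_peptide <- function(cds, tab, start_kind = "AUG",
                          rt = integer(), sec = integer()) {
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- character()
  for (i in seq_len(n - 1L)) {
    aa[i] <- if (i == 1L && !start_kind %in% c("AUG", "undetermined")) "M"
      else if (i %in% sec) "U"
      else if (i %in% rt) "X"
      else unname(tab[codons[i]])
  }
  paste(aa, collapse = "")
}

## resample `idx` positions of base vector s until `ok(s)` holds
resample_until <- function(s, idx, ok, max_iter = 20000L) {
  for (k in seq_len(max_iter)) {
    if (ok(s)) return(s)
    s[idx] <- rnt(length(idx))
  }
  stop("fixture constraint solving failed after ", max_iter, " iterations")
}

put <- function(s, at, what) {  # write string `what` at 0-based offset `at`
  s[(at + 1L):(at + nchar(what))] <- strsplit(what, "")[[1]]
  s
}

seg <- function(s, from, to) paste(s[(from + 1L):to], collapse = "")  # 0-based half-open

frame_clean <- function(s, from, to, tab) {  # codons in [from,to): none but the last may be a stop
  cds <- seg(s, from, to)
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  all(tab[codons[-n]] != "*") && tab[codons[n]] == "*"
}

frame_clean_rc <- function(s, from, to, tab) {
  cds <- rc(seg(s, from, to))
  n <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  all(tab[codons[-n]] != "*") && tab[codons[n]] == "*"
}

## id allocator
new_ids <- function() {
  env <- new.env()
  env$g <- 0L; env$t <- 0L
  env
}
next_gene <- function(ids) { ids$g <- ids$g + 1L; sprintf("g%03d", ids$g) }
next_tr <- function(ids) { ids$t <- ids$t + 1L; sprintf("t%03d", ids$t) }

manifest_entry <- function(category, genes = character(),
                           transcripts = character(), gene_so = list(),
                           transcript_flags = list(), intron_classes = list(),
                           u12 = list(), gene_comments = list(),
                           overlaps = list(), peptides = list(),
                           junction_verdicts = list(),
                           intercistronic = list(), arity = list()) {
  list(category = category, genes = genes, transcripts = transcripts,
       gene_so = gene_so, transcript_flags = transcript_flags,
       intron_classes = intron_classes, u12 = u12,
       gene_comments = gene_comments, overlaps = overlaps,
       peptides = peptides, junction_verdicts = junction_verdicts,
       intercistronic = intercistronic, arity = arity)
}

so <- function(...) unname(gene_so_vocabulary()[c(...)])

## intron interior must not accidentally match the U12 5' consensus (or must,
## for planted U12 introns): positions 2-5 of the intron hold the consensus
## tail ATCC when forced
fix_u12 <- function(s, intron_start, intron_end, want_u12, pattern) {
  if (want_u12) return(put(s, intron_start + 2L, "ATCC"))
  idx <- (intron_start + 3L):(intron_start + 6L)  # 1-based indices into s
  resample_until(s, idx, function(v)
    !grepl(pattern, seg(v, intron_start, intron_end)))
}

## ---- locus builders -------------------------------------------------------
## Each returns list(len, transcripts, gene_flags, junctions, editing,
## manifest); all coordinates absolute on `seqid` starting at `off`.

build_simple <- function(seqid, off, ids, tab, kind = "mono") {
  u <- 6L
  gid <- next_gene(ids); tid <- next_tr(ids)
  start_kind <- "AUG"; rt <- integer(); sec <- integer(); fs <- NULL
  n_sense <- 18L
  codons <- c("ATG", rcod(n_sense, tab), "TAA")
  flags <- character(); gso <- character()
  if (kind == "cug") {
    codons[1] <- "CTG"; start_kind <- "CTG"
    flags <- "non-canonical_start_codon"
    gso <- so("gene_with_unconventional_translation_start_codon",
              "gene_with_translation_start_codon_CUG")
  } else if (kind == "undetermined") {
    codons[1] <- "GTT"; start_kind <- "undetermined"
    flags <- "start_codon_not_determined"
  } else if (kind == "sec") {
    codons[6] <- "TGA"; sec <- 6L
    flags <- "stop_codon_redefined_as_selenocysteine"
    gso <- so("gene_with_stop_codon_redefined_as_selenocysteine")
  } else if (kind == "readthrough") {
    codons[8] <- "TGA"; rt <- 8L
    flags <- "stop_codon_read_through"
    gso <- so("gene_with_stop_codon_read_through")
  } else if (kind == "double_readthrough") {
    codons[5] <- "TGA"; codons[12] <- "TAG"; rt <- c(5L, 12L)
    flags <- "stop_codon_read_through"
    gso <- so("gene_with_stop_codon_read_through")
  }
  cds <- paste(codons, collapse = "")
  len <- u + nchar(cds) + 12L
  s <- rnt(len)
  s <- put(s, u, cds)
  exon <- g_interval(seqid, off, off + len, "+")
  orf <- orf_annotation(gid,
                        list(g_interval(seqid, off + u, off + u + nchar(cds),
                                        "+")),
                        start_codon_kind = start_kind,
                        readthrough_positions = rt,
                        selenocysteine_positions = sec)
  tr <- transcript_model(tid, gid, list(exon), list(orf))
  pep <- plant_peptide(cds, tab, start_kind, rt, sec)
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry(kind, genes = gid, transcripts = tid,
         gene_so = stats::setNames(list(gso), gid),
         transcript_flags = stats::setNames(list(flags), tid),
         peptides = stats::setNames(list(pep), paste0(tid, ":", gid)),
         arity = stats::setNames(list(1L), tid)))
}

build_frameshift <- function(seqid, off, ids, tab) {
  u <- 6L
  gid <- next_gene(ids); tid <- next_tr(ids)
  part1 <- c("ATG", rcod(3L, tab))
  part2 <- c(rcod(5L, tab), "TAA")
  cds <- paste0(paste(part1, collapse = ""), sample(.BASES, 1L),
                paste(part2, collapse = ""))
  len <- u + nchar(cds) + 12L
  s <- put(rnt(len), u, cds)
  exon <- g_interval(seqid, off, off + len, "+")
  orf <- orf_annotation(gid,
                        list(g_interval(seqid, off + u, off + u + nchar(cds),
                                        "+")),
                        frameshift = list(codon_index = 4L, shift = 1L))
  tr <- transcript_model(tid, gid, list(exon), list(orf))
  pep <- plant_peptide(paste0(paste(part1, collapse = ""),
                              paste(part2, collapse = "")), tab)
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("frameshift", genes = gid,
         transcripts = tid,
         gene_so = stats::setNames(
           list(so("gene_with_transcript_with_translational_frameshift")),
           gid),
         transcript_flags = stats::setNames(
           list("transcript_with_translational_frameshift"), tid),
         peptides = stats::setNames(list(pep), paste0(tid, ":", gid)),
         arity = stats::setNames(list(1L), tid)))
}

build_polycistronic <- function(seqid, off, ids, tab, arity) {
  u <- 6L; gap <- 10L
  gids <- vapply(seq_len(arity), function(i) next_gene(ids), character(1))
  tid <- next_tr(ids)
  aas <- c(19L, 14L, 11L, 10L)[seq_len(arity)]
  cdss <- lapply(aas, function(a) paste(c("ATG", rcod(a - 1L, tab), "TAA"),
                                        collapse = ""))
  pos <- u
  orfs <- list(); peps <- list()
  starts <- integer(arity)
  for (i in seq_len(arity)) {
    starts[i] <- pos
    pos <- pos + nchar(cdss[[i]]) + if (i < arity) gap else 0L
  }
  len <- pos + 12L
  s <- rnt(len)
  for (i in seq_len(arity)) s <- put(s, starts[i], cdss[[i]])
  exon <- g_interval(seqid, off, off + len, "+")
  for (i in seq_len(arity)) {
    orfs[[i]] <- orf_annotation(gids[i],
      list(g_interval(seqid, off + starts[i],
                      off + starts[i] + nchar(cdss[[i]]), "+")))
    peps[[paste0(tid, ":", gids[i])]] <- plant_peptide(cdss[[i]], tab)
  }
  tr <- transcript_model(tid, gids, list(exon), orfs)
  gso <- if (arity == 2L) so("gene_with_dicistronic_mRNA")
         else so("gene_with_polycistronic_transcript")
  tflag <- if (arity == 2L) "dicistronic_mRNA" else "polycistronic_transcript"
  inter <- stats::setNames(
    as.list(rep(gap, arity - 1L)),
    vapply(seq_len(arity - 1L), function(i)
      paste(tid, gids[i], gids[i + 1L], sep = ":"), character(1)))
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry(paste0("cistronic_", arity), genes = gids,
         transcripts = tid,
         gene_so = stats::setNames(rep(list(gso), arity), gids),
         transcript_flags = stats::setNames(list(tflag), tid),
         peptides = peps, intercistronic = inter,
         arity = stats::setNames(list(as.integer(arity)), tid)))
}

build_shared5 <- function(seqid, off, ids, tab, pattern) {
  gA <- next_gene(ids); gB <- next_gene(ids)
  tA <- next_tr(ids); tB <- next_tr(ids)
  len <- 330L
  s <- rnt(len)
  s <- put(s, 40L, "GT"); s <- put(s, 98L, "AG"); s <- put(s, 238L, "AG")
  s <- fix_u12(s, 40L, 100L, FALSE, pattern)
  cdsA <- paste(c("ATG", rcod(22L, tab), "TAA"), collapse = "")  # 72 nt
  cdsB <- paste(c("ATG", rcod(22L, tab), "TAA"), collapse = "")
  s <- put(s, 103L, cdsA)
  s <- put(s, 243L, cdsB)
  e1 <- g_interval(seqid, off, off + 40L, "+")
  eA <- g_interval(seqid, off + 100L, off + 190L, "+")
  eB <- g_interval(seqid, off + 240L, off + 330L, "+")
  trA <- transcript_model(tA, gA, list(e1, eA),
    list(orf_annotation(gA, list(g_interval(seqid, off + 103L, off + 175L,
                                            "+")))))
  trB <- transcript_model(tB, gB, list(e1, eB),
    list(orf_annotation(gB, list(g_interval(seqid, off + 243L, off + 315L,
                                            "+")))))
  cm <- overlap_comment("shared_5_exons")
  list(len = len, seq = s, transcripts = list(trA, trB), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("shared_5", genes = c(gA, gB),
         transcripts = c(tA, tB),
         gene_so = stats::setNames(list(character(), character()), c(gA, gB)),
         transcript_flags = stats::setNames(list(character(), character()),
                                            c(tA, tB)),
         gene_comments = stats::setNames(list(cm, cm), c(gA, gB)),
         overlaps = list(list(gene_a = gA, gene_b = gB,
                              category = "shared_5_exons")),
         peptides = stats::setNames(
           list(plant_peptide(cdsA, tab), plant_peptide(cdsB, tab)),
           c(paste0(tA, ":", gA), paste0(tB, ":", gB))),
         arity = stats::setNames(list(1L, 1L), c(tA, tB))))
}

build_shared3 <- function(seqid, off, ids, tab, pattern) {
  gA <- next_gene(ids); gB <- next_gene(ids)
  tA <- next_tr(ids); tB <- next_tr(ids)
  len <- 200L
  s <- rnt(len)
  cdsA <- paste(c("ATG", rcod(22L, tab), "TAA"), collapse = "")  # 72 nt
  cdsB <- paste(c("ATG", rcod(10L, tab), "TAA"), collapse = "")  # 36 nt
  s <- put(s, 6L, cdsA)
  s <- put(s, 90L, "GT"); s <- put(s, 137L, "GT"); s <- put(s, 148L, "AG")
  s <- put(s, 98L, cdsB)
  s <- fix_u12(s, 90L, 150L, FALSE, pattern)
  s <- fix_u12(s, 137L, 150L, FALSE, pattern)
  eA1 <- g_interval(seqid, off, off + 90L, "+")
  eB1 <- g_interval(seqid, off + 95L, off + 137L, "+")
  sh <- g_interval(seqid, off + 150L, off + 200L, "+")
  trA <- transcript_model(tA, gA, list(eA1, sh),
    list(orf_annotation(gA, list(g_interval(seqid, off + 6L, off + 78L,
                                            "+")))))
  trB <- transcript_model(tB, gB, list(eB1, sh),
    list(orf_annotation(gB, list(g_interval(seqid, off + 98L, off + 134L,
                                            "+")))))
  cm <- overlap_comment("shared_3_utr")
  list(len = len, seq = s, transcripts = list(trA, trB), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("shared_3", genes = c(gA, gB),
         transcripts = c(tA, tB),
         gene_so = stats::setNames(list(character(), character()), c(gA, gB)),
         transcript_flags = stats::setNames(list(character(), character()),
                                            c(tA, tB)),
         gene_comments = stats::setNames(list(cm, cm), c(gA, gB)),
         overlaps = list(list(gene_a = gA, gene_b = gB,
                              category = "shared_3_utr")),
         peptides = stats::setNames(
           list(plant_peptide(cdsA, tab), plant_peptide(cdsB, tab)),
           c(paste0(tA, ":", gA), paste0(tB, ":", gB))),
         arity = stats::setNames(list(1L, 1L), c(tA, tB))))
}

build_multiphasic_within <- function(seqid, off, ids, tab, pattern, long) {
  gid <- next_gene(ids)
  tA <- next_tr(ids); tB <- next_tr(ids)
  R <- if (long) 81L else 30L         # B's exon-2 CDS extent incl. its stop
  LA <- if (long) 96L else 45L        # A's exon-2 CDS extent
  u <- 6L
  exon2_end <- 86L + LA + 8L
  len <- exon2_end
  s <- rnt(len)
  cds1 <- paste(c("ATG", rcod(9L, tab)), collapse = "")      # 30 nt, no stop
  s <- put(s, u, cds1)
  s <- put(s, 36L, "GT"); s <- put(s, 84L, "AG"); s <- put(s, 86L, "AG")
  s <- fix_u12(s, 36L, 86L, FALSE, pattern)
  s <- put(s, 88L + R - 3L, "TAA")                           # B's stop
  s <- put(s, 86L + LA - 3L, "TAA")                          # A's stop
  free <- setdiff((86L + 3L):(86L + LA),
                  c((88L + R - 2L):(88L + R), (86L + LA - 2L):(86L + LA)))
  both_clean <- function(v) {
    cdsA <- paste0(cds1, seg(v, 86L, 86L + LA))
    cdsB <- paste0(cds1, seg(v, 88L, 88L + R))
    frame_clean(strsplit(cdsA, "")[[1]], 0L, nchar(cdsA), tab) &&
      frame_clean(strsplit(cdsB, "")[[1]], 0L, nchar(cdsB), tab)
  }
  s <- resample_until(s, free, both_clean)
  e1 <- g_interval(seqid, off, off + 36L, "+")
  eA2 <- g_interval(seqid, off + 86L, off + exon2_end, "+")
  eB2 <- g_interval(seqid, off + 88L, off + exon2_end, "+")
  orfA <- orf_annotation(gid, list(g_interval(seqid, off + u, off + 36L, "+"),
                                   g_interval(seqid, off + 86L,
                                              off + 86L + LA, "+")))
  orfB <- orf_annotation(gid, list(g_interval(seqid, off + u, off + 36L, "+"),
                                   g_interval(seqid, off + 88L,
                                              off + 88L + R, "+")))
  trA <- transcript_model(tA, gid, list(e1, eA2), list(orfA))
  trB <- transcript_model(tB, gid, list(e1, eB2), list(orfB))
  cm <- if (long) mp_comment("multiphase_exon") else mp_comment("alt_stop")
  pepA <- plant_peptide(paste0(cds1, seg(s, 86L, 86L + LA)), tab)
  pepB <- plant_peptide(paste0(cds1, seg(s, 88L, 88L + R)), tab)
  list(len = len, seq = s, transcripts = list(trA, trB), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry(
         if (long) "multiphasic_long" else "multiphasic_short",
         genes = gid, transcripts = c(tA, tB),
         gene_so = stats::setNames(list(character()), gid),
         transcript_flags = stats::setNames(list(character(), character()),
                                            c(tA, tB)),
         gene_comments = stats::setNames(list(cm), gid),
         overlaps = list(list(gene_a = gid, gene_b = gid,
                              category = "multiphasic_within_gene")),
         peptides = stats::setNames(list(pepA, pepB),
                                    c(paste0(tA, ":", gid),
                                      paste0(tB, ":", gid))),
         arity = stats::setNames(list(1L, 1L), c(tA, tB))))
}

build_multiphasic_cross <- function(seqid, off, ids, tab) {
  gA <- next_gene(ids); gB <- next_gene(ids)
  tid <- next_tr(ids)
  len <- 160L
  s <- rnt(len)
  s <- put(s, 6L, "ATG"); s <- put(s, 93L, "TAA")    # ORF A: [6,96)
  s <- put(s, 26L, "ATG"); s <- put(s, 143L, "TAA")  # ORF B: [26,146)
  fixed <- c(7:9, 94:96, 27:29, 144:146)             # 1-based indices
  free <- setdiff(7:146, fixed)
  s <- resample_until(s, free, function(v)
    frame_clean(v, 6L, 96L, tab) && frame_clean(v, 26L, 146L, tab))
  exon <- g_interval(seqid, off, off + len, "+")
  orfA <- orf_annotation(gA, list(g_interval(seqid, off + 6L, off + 96L,
                                             "+")))
  orfB <- orf_annotation(gB, list(g_interval(seqid, off + 26L, off + 146L,
                                             "+")))
  tr <- transcript_model(tid, c(gA, gB), list(exon), list(orfA, orfB))
  cm <- mp_comment("cross_gene")
  gso <- so("gene_with_dicistronic_mRNA")
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("multiphasic_cross", genes = c(gA, gB),
         transcripts = tid,
         gene_so = stats::setNames(list(gso, gso), c(gA, gB)),
         transcript_flags = stats::setNames(list("dicistronic_mRNA"), tid),
         gene_comments = stats::setNames(list(cm, cm), c(gA, gB)),
         overlaps = list(list(gene_a = gA, gene_b = gB,
                              category = "multiphasic_cross_gene")),
         peptides = stats::setNames(
           list(plant_peptide(seg(s, 6L, 96L), tab),
                plant_peptide(seg(s, 26L, 146L), tab)),
           c(paste0(tid, ":", gA), paste0(tid, ":", gB))),
         intercistronic = stats::setNames(list(-70L),
                                          paste(tid, gA, gB, sep = ":")),
         arity = stats::setNames(list(2L), tid)))
}

build_bidirectional <- function(seqid, off, ids, tab) {
  gP <- next_gene(ids); gM <- next_gene(ids)
  tP <- next_tr(ids); tM <- next_tr(ids)
  len <- 150L
  s <- rnt(len)
  s <- put(s, 6L, "ATG"); s <- put(s, 93L, "TAA")     # plus CDS [6,96)
  s <- put(s, 133L, "CAT"); s <- put(s, 46L, "TTA")   # minus CDS [46,136)
  fixed <- c(7:9, 94:96, 134:136, 47:49)
  free <- setdiff(7:136, fixed)
  s <- resample_until(s, free, function(v)
    frame_clean(v, 6L, 96L, tab) && frame_clean_rc(v, 46L, 136L, tab))
  eP <- g_interval(seqid, off, off + 100L, "+")
  eM <- g_interval(seqid, off + 40L, off + 142L, "-")
  trP <- transcript_model(tP, gP, list(eP),
    list(orf_annotation(gP, list(g_interval(seqid, off + 6L, off + 96L,
                                            "+")))))
  trM <- transcript_model(tM, gM, list(eM),
    list(orf_annotation(gM, list(g_interval(seqid, off + 46L, off + 136L,
                                            "-")))))
  cm <- mp_comment("bidirectional")
  list(len = len, seq = s, transcripts = list(trP, trM), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("bidirectional", genes = c(gP, gM),
         transcripts = c(tP, tM),
         gene_so = stats::setNames(list(character(), character()), c(gP, gM)),
         transcript_flags = stats::setNames(list(character(), character()),
                                            c(tP, tM)),
         gene_comments = stats::setNames(list(cm, cm), c(gP, gM)),
         overlaps = list(list(gene_a = gP, gene_b = gM,
                              category = "bidirectional")),
         peptides = stats::setNames(
           list(plant_peptide(seg(s, 6L, 96L), tab),
                plant_peptide(rc(seg(s, 46L, 136L)), tab)),
           c(paste0(tP, ":", gP), paste0(tM, ":", gM))),
         arity = stats::setNames(list(1L, 1L), c(tP, tM))))
}

build_splice <- function(seqid, off, ids, tab, pattern, pair,
                         u12 = FALSE, extras = FALSE) {
  gid <- next_gene(ids)
  donor <- substr(pair, 1L, 2L); acceptor <- substr(pair, 4L, 5L)
  ## a similar alternative canonical splice (shared donor position, AG
  ## acceptor 4 nt downstream) is only planted when the donor reads GT --
  ## donor-variant and AT-AC introns have no canonical alternative, and a
  ## U12-type intron keeps its single minor-spliceosome junction
  with_alt <- donor == "GT" && !u12
  t1 <- next_tr(ids)
  t2 <- if (with_alt) next_tr(ids) else NULL
  len <- 160L
  s <- rnt(len)
  codons <- c("ATG", rcod(22L, tab), "TAA")
  cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
  cds[37:38] <- c("A", "G")   # acceptor of the similar alternative splice
  cds <- paste(cds, collapse = "")
  s <- put(s, 6L, substr(cds, 1L, 34L))
  s <- put(s, 100L, substr(cds, 35L, 72L))
  s <- put(s, 40L, donor); s <- put(s, 98L, acceptor)
  s <- fix_u12(s, 40L, 100L, u12, pattern)
  e1 <- g_interval(seqid, off, off + 40L, "+")
  e2 <- g_interval(seqid, off + 100L, off + 160L, "+")
  e2b <- g_interval(seqid, off + 104L, off + 160L, "+")
  tr1 <- transcript_model(t1, gid, list(e1, e2),
    list(orf_annotation(gid, list(g_interval(seqid, off + 6L, off + 40L, "+"),
                                  g_interval(seqid, off + 100L, off + 138L,
                                             "+")))))
  tr2 <- if (with_alt) transcript_model(t2, gid, list(e1, e2b))
  key <- intron_key(g_interval(seqid, off + 40L, off + 100L, "+"))
  cls <- if (pair == "GT-AG") "canonical_GT_AG"
         else if (pair == "AT-AC") "noncanonical_AT_AC"
         else paste0("noncanonical:", pair)
  t1flags <- if (startsWith(cls, "noncanonical")) "non_canonical_splice_site"
             else character()
  jname <- sprintf("jx_%s_%s", gsub("-", "", pair),
                   if (u12) "u12" else "main")
  junctions <- list(list(name = jname, start = off + 40L, end = off + 100L,
                         strand = "+", count = 10L,
                         verdict = "matches_annotated"))
  if (pair == "GT-AT") {
    junctions <- c(junctions, list(
      list(name = "jx_stripped", start = off + 40L, end = off + 100L,
           strand = NA_character_, count = 9L,
           verdict = "strand_flip_gt_at")))
  }
  if (extras && with_alt) {
    junctions <- c(junctions, list(
      list(name = "jx_offbyone", start = off + 41L, end = off + 105L,
           strand = "+", count = 8L, verdict = "off_by_one_artifact"),
      list(name = "jx_lowfreq", start = off + 43L, end = off + 107L,
           strand = "+", count = 1L, verdict = "low_frequency"),
      list(name = "jx_far", start = off + 50L, end = off + 114L,
           strand = "+", count = 7L, verdict = "unsupported_noncanonical")))
  }
  tids <- c(t1, t2)
  tflags <- c(stats::setNames(list(t1flags), t1),
              if (with_alt) stats::setNames(list(character()), t2))
  arities <- c(stats::setNames(list(1L), t1),
               if (with_alt) stats::setNames(list(0L), t2))
  list(len = len, seq = s,
       transcripts = c(list(tr1), if (with_alt) list(tr2)),
       gene_flags = list(), junctions = junctions, editing = NULL,
       manifest = manifest_entry(paste0("splice_", pair,
                                        if (u12) "_U12" else ""),
         genes = gid, transcripts = tids,
         gene_so = stats::setNames(list(character()), gid),
         transcript_flags = tflags,
         intron_classes = stats::setNames(list(cls), key),
         u12 = stats::setNames(list(u12), key),
         peptides = stats::setNames(list(plant_peptide(cds, tab)),
                                    paste0(t1, ":", gid)),
         junction_verdicts = stats::setNames(
           lapply(junctions, `[[`, "verdict"),
           vapply(junctions, `[[`, character(1), "name")),
         arity = arities))
}

build_hac1 <- function(seqid, off, ids, tab, pattern) {
  gid <- next_gene(ids); tid <- next_tr(ids)
  len <- 130L
  s <- rnt(len)
  cds <- paste(c("ATG", rcod(12L, tab), "TAA"), collapse = "")  # 42 nt
  s <- put(s, 6L, cds)
  s <- put(s, 50L, "CA"); s <- put(s, 71L, "TG")
  e1 <- g_interval(seqid, off, off + 50L, "+")
  e2 <- g_interval(seqid, off + 73L, off + 130L, "+")
  tr <- transcript_model(tid, gid, list(e1, e2),
    list(orf_annotation(gid, list(g_interval(seqid, off + 6L, off + 48L,
                                             "+")))),
    declared_flags = "endonuclease_spliced_intron")
  key <- intron_key(g_interval(seqid, off + 50L, off + 73L, "+"))
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("hac1", genes = gid, transcripts = tid,
         gene_so = stats::setNames(list(character()), gid),
         transcript_flags = stats::setNames(
           list("endonuclease_spliced_intron"), tid),
         intron_classes = stats::setNames(list("endonuclease_spliced"), key),
         peptides = stats::setNames(list(plant_peptide(cds, tab)),
                                    paste0(tid, ":", gid)),
         arity = stats::setNames(list(1L), tid)))
}

build_trans_splice <- function(seqid, off, ids, tab) {
  gid <- next_gene(ids); tid <- next_tr(ids)
  len <- 260L
  s <- rnt(len)
  cds <- paste(c("ATG", rcod(14L, tab), "TAA"), collapse = "")  # 48 nt
  s <- put(s, 6L, cds)
  e1 <- g_interval(seqid, off, off + 60L, "+")
  e2 <- g_interval(seqid, off + 150L, off + 210L, "-")
  tr <- transcript_model(tid, gid, list(e1, e2),
    list(orf_annotation(gid, list(g_interval(seqid, off + 6L, off + 54L,
                                             "+")))),
    declared_flags = "trans_spliced_transcript")
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("trans_splice", genes = gid,
         transcripts = tid,
         gene_so = stats::setNames(list(so("gene_with_trans_spliced_transcript")),
                                   gid),
         transcript_flags = stats::setNames(list("trans_spliced_transcript"),
                                            tid),
         peptides = stats::setNames(list(plant_peptide(cds, tab)),
                                    paste0(tid, ":", gid)),
         arity = stats::setNames(list(1L), tid)))
}

build_mito <- function(seqid, off, ids, mito_tab) {
  gid <- next_gene(ids); tid <- next_tr(ids)
  u <- 4L
  codons <- c("ATG", "ATA", "TGA", rcod(8L, mito_tab))
  cds <- paste0(paste(codons, collapse = ""), "T")   # incomplete stop
  len <- u + nchar(cds) + 8L
  s <- put(rnt(len), u, cds)
  exon <- g_interval(seqid, off, off + len, "+")
  orf <- orf_annotation(gid,
                        list(g_interval(seqid, off + u, off + u + nchar(cds),
                                        "+")),
                        incomplete_stop = TRUE,
                        genetic_code = "invertebrate_mitochondrial")
  tr <- transcript_model(tid, gid, list(exon), list(orf))
  pep <- plant_peptide(paste0(paste(codons, collapse = ""), "TAA"), mito_tab)
  list(len = len, seq = s, transcripts = list(tr), gene_flags = list(),
       junctions = list(), editing = NULL,
       manifest = manifest_entry("mito_incomplete_stop", genes = gid,
         transcripts = tid,
         gene_so = stats::setNames(list(so("mt_gene")), gid),
         transcript_flags = stats::setNames(
           list(c("mitochondrial_genetic_code",
                  "mitochondrial_incomplete_stop_codon")), tid),
         peptides = stats::setNames(list(pep), paste0(tid, ":", gid)),
         arity = stats::setNames(list(1L), tid)))
}

build_edited <- function(seqid, off, ids, tab) {
  out <- build_simple(seqid, off, ids, tab, "mono")
  gid <- out$manifest$genes
  out$editing <- data.frame(seqid = seqid, pos = off + 20L,
                            stringsAsFactors = FALSE)
  out$manifest$category <- "edited"
  out$manifest$gene_so[[gid]] <- so("gene_with_edited_transcript")
  out
}

## ---- assembler ------------------------------------------------------------

#' Generate a synthetic genome + annotation fixture with ground truth
#'
#' @param spec a [fixture_spec].
#' @param config an [audit_config] (the generator avoids planting accidental
#'   matches to the configured U12 consensus).
#' @return list of class `annotation_fixture`: `genome` ([genome_seq]),
#'   `set` ([annotation_set]), `junctions` (list of [junction_call]),
#'   `editing_sites` (data.frame), `manifest` (list of planted-feature
#'   entries), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(),
                             config = audit_config()) {
  set.seed(spec$seed)
  tab <- Biostrings::getGeneticCode("1")
  mito_tab <- Biostrings::getGeneticCode("5")
  pattern <- config$u12_pattern
  ids <- new_ids()
  pad <- 150L
  seqid <- "chrA"

  plan <- list()
  rep_add <- function(n, f) for (k in seq_len(n)) plan[[length(plan) + 1L]] <<- f
  rep_add(spec$mono, function(off) build_simple(seqid, off, ids, tab, "mono"))
  rep_add(spec$dicistronic,
          function(off) build_polycistronic(seqid, off, ids, tab, 2L))
  rep_add(spec$tricistronic,
          function(off) build_polycistronic(seqid, off, ids, tab, 3L))
  rep_add(spec$tetracistronic,
          function(off) build_polycistronic(seqid, off, ids, tab, 4L))
  rep_add(spec$shared_5,
          function(off) build_shared5(seqid, off, ids, tab, pattern))
  rep_add(spec$shared_3,
          function(off) build_shared3(seqid, off, ids, tab, pattern))
  rep_add(spec$multiphasic_short,
          function(off) build_multiphasic_within(seqid, off, ids, tab,
                                                 pattern, long = FALSE))
  rep_add(spec$multiphasic_long,
          function(off) build_multiphasic_within(seqid, off, ids, tab,
                                                 pattern, long = TRUE))
  rep_add(spec$multiphasic_cross,
          function(off) build_multiphasic_cross(seqid, off, ids, tab))
  rep_add(spec$bidirectional,
          function(off) build_bidirectional(seqid, off, ids, tab))
  first_gt <- TRUE
  for (pair in names(spec$noncanonical)) {
    local({
      p <- pair
      n <- spec$noncanonical[[p]]
      for (k in seq_len(n)) {
        ex <- first_gt && p == "GT-AT"
        if (ex) first_gt <<- FALSE
        plan[[length(plan) + 1L]] <<-
          (function(pp, xx) function(off)
            build_splice(seqid, off, ids, tab, pattern, pp,
                         extras = xx))(p, ex)
      }
    })
  }
  rep_add(spec$at_ac_u12,
          function(off) build_splice(seqid, off, ids, tab, pattern, "AT-AC",
                                     u12 = TRUE))
  rep_add(spec$at_ac_u2,
          function(off) build_splice(seqid, off, ids, tab, pattern, "AT-AC",
                                     u12 = FALSE))
  rep_add(spec$gt_ag_u12,
          function(off) build_splice(seqid, off, ids, tab, pattern, "GT-AG",
                                     u12 = TRUE))
  rep_add(spec$hac1,
          function(off) build_hac1(seqid, off, ids, tab, pattern))
  rep_add(spec$trans_splice,
          function(off) build_trans_splice(seqid, off, ids, tab))
  rep_add(spec$cug_start,
          function(off) build_simple(seqid, off, ids, tab, "cug"))
  rep_add(spec$undetermined_start,
          function(off) build_simple(seqid, off, ids, tab, "undetermined"))
  rep_add(spec$sec, function(off) build_simple(seqid, off, ids, tab, "sec"))
  rep_add(spec$readthrough,
          function(off) build_simple(seqid, off, ids, tab, "readthrough"))
  rep_add(spec$double_readthrough,
          function(off) build_simple(seqid, off, ids, tab,
                                     "double_readthrough"))
  rep_add(spec$frameshift,
          function(off) build_frameshift(seqid, off, ids, tab))
  rep_add(spec$edited, function(off) build_edited(seqid, off, ids, tab))

  seq_parts <- character()
  cursor <- 0L
  transcripts <- list(); junctions <- list(); manifest <- list()
  editing <- data.frame(seqid = character(), pos = integer(),
                        stringsAsFactors = FALSE)
  for (f in plan) {
    seq_parts <- c(seq_parts, paste(rnt(pad), collapse = ""))
    cursor <- cursor + pad
    out <- f(cursor)
    seq_parts <- c(seq_parts, paste(out$seq, collapse = ""))
    cursor <- cursor + out$len
    transcripts <- c(transcripts, out$transcripts)
    junctions <- c(junctions, out$junctions)
    manifest[[length(manifest) + 1L]] <- out$manifest
    if (!is.null(out$editing)) editing <- rbind(editing, out$editing)
  }
  seq_parts <- c(seq_parts, paste(rnt(pad), collapse = ""))
  cursor <- cursor + pad
  main_seq <- paste(seq_parts, collapse = "")
  if (!is.null(spec$contig_length)) {
    if (spec$contig_length < cursor)
      stop("contig_length ", spec$contig_length, " too small for the ",
           "requested features (need ", cursor, " nt)")
    main_seq <- paste0(main_seq,
                       paste(rnt(spec$contig_length - cursor), collapse = ""))
  }
  records <- c(chrA = main_seq)
  circular <- character()
  if (spec$mito_incomplete_stop > 0L) {
    mcursor <- 0L; mparts <- character()
    for (k in seq_len(spec$mito_incomplete_stop)) {
      mparts <- c(mparts, paste(rnt(50L), collapse = ""))
      mcursor <- mcursor + 50L
      out <- build_mito("mito", mcursor, ids, mito_tab)
      mparts <- c(mparts, paste(out$seq, collapse = ""))
      mcursor <- mcursor + out$len
      transcripts <- c(transcripts, out$transcripts)
      manifest[[length(manifest) + 1L]] <- out$manifest
    }
    mparts <- c(mparts, paste(rnt(50L), collapse = ""))
    records <- c(records, mito = paste(mparts, collapse = ""))
    circular <- "mito"
  }
  g <- genome_seq(records, circular = circular)
  set <- annotation_set(transcripts)
  jx <- lapply(junctions, function(j)
    junction_call(seqid, j$start, j$end, strand = j$strand,
                  read_count = j$count, score = 1, name = j$name))
  structure(list(genome = g, set = set, junctions = jx,
                 editing_sites = editing, manifest = manifest, spec = spec),
            class = "annotation_fixture")
}

#' Write a fixture to disk
#'
#' Writes `genome.fasta`, `annotation.gff3`, `junctions.bed`,
#' `editing_sites.tsv` and `manifest.json`; outputs are byte-identical for a
#' fixed seed.
#'
#' @param fix an `annotation_fixture`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(fix$genome, file.path(dir, "genome.fasta"))
  write_annotation(fix$set, file.path(dir, "annotation.gff3"))
  bed <- vapply(fix$junctions, function(j)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", j$interval$seqid, j$interval$start,
            j$interval$end, j$name, j$read_count,
            if (j$stranded) j$interval$strand else "."), character(1))
  con <- file(file.path(dir, "junctions.bed"), "wb")
  writeLines(bed, con, sep = "\n"); close(con)
  ed <- fix$editing_sites
  ed$pos <- ed$pos + 1L  # 1-based on disk
  con <- file(file.path(dir, "editing_sites.tsv"), "wb")
  utils::write.table(ed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  close(con)
  jsonlite::write_json(fix$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "list")
  invisible(dir)
}

#' Verify an audit against a fixture manifest
#'
#' Compares every planted expectation (gene SO terms, transcript flags,
#' intron classifications and U12 tags, gene-model comments, overlap calls,
#' peptides, junction verdicts, intercistronic distances, cistronic arities)
#' against the audit, and additionally requires that *unplanted* genes and
#' transcripts carry no terms, flags or comments.
#'
#' @param audit an `annotation_audit`.
#' @param manifest the fixture's manifest.
#' @return list with `ok`, `n_checks`, `n_failed` and a `failures`
#'   data.frame.
#' @export
verify_audit <- function(audit, manifest) {
  checks <- list()
  add <- function(category, check, ok, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      category = category, check = check, ok = ok, detail = detail,
      stringsAsFactors = FALSE)
  seteq <- function(a, b) identical(sort(unique(a)), sort(unique(b)))

  exp_so <- list(); exp_flags <- list(); exp_comments <- list()
  for (m in manifest) {
    for (gid in names(m$gene_so))
      exp_so[[gid]] <- c(exp_so[[gid]], unlist(m$gene_so[[gid]]))
    for (tid in names(m$transcript_flags))
      exp_flags[[tid]] <- c(exp_flags[[tid]],
                            unlist(m$transcript_flags[[tid]]))
    for (gid in names(m$gene_comments))
      exp_comments[[gid]] <- c(exp_comments[[gid]],
                               unlist(m$gene_comments[[gid]]))
  }
  for (gid in names(audit$set$genes)) {
    actual <- audit$gene_so[[gid]]$so_id %||% character()
    add("gene_so", gid, seteq(actual, exp_so[[gid]] %||% character()),
        paste(actual, collapse = ";"))
    actual_cm <- unlist(audit$gene_comments[[gid]]) %||% character()
    add("gene_comments", gid,
        seteq(actual_cm, exp_comments[[gid]] %||% character()),
        paste(actual_cm, collapse = "|"))
  }
  for (tid in names(audit$set$transcripts)) {
    actual <- audit$transcript_flags[[tid]]$token %||% character()
    add("transcript_flags", tid,
        seteq(actual, exp_flags[[tid]] %||% character()),
        paste(actual, collapse = ";"))
  }
  it <- audit$intron_table
  for (m in manifest) {
    for (key in names(m$intron_classes)) {
      got <- it$classification[it$intron == key]
      add("intron_class", key,
          length(got) == 1L && got == m$intron_classes[[key]],
          paste(got, collapse = ";"))
    }
    for (key in names(m$u12)) {
      got <- it$u12[it$intron == key]
      add("u12", key, length(got) == 1L && got == m$u12[[key]])
    }
    for (ov in m$overlaps) {
      hit <- (audit$overlap_table$gene_a == ov$gene_a &
                audit$overlap_table$gene_b == ov$gene_b) |
             (audit$overlap_table$gene_a == ov$gene_b &
                audit$overlap_table$gene_b == ov$gene_a)
      add("overlap", paste(ov$gene_a, ov$gene_b, ov$category),
          any(audit$overlap_table$category[hit] == ov$category))
    }
    for (key in names(m$peptides)) {
      got <- audit$translations[[key]]$peptide
      add("peptide", key, identical(got, m$peptides[[key]]),
          got %||% "<missing>")
    }
    for (nm in names(m$junction_verdicts)) {
      got <- audit$junction_table$verdict[audit$junction_table$name == nm]
      add("junction", nm,
          length(got) == 1L && got == m$junction_verdicts[[nm]],
          paste(got, collapse = ";"))
    }
    for (key in names(m$intercistronic)) {
      p <- strsplit(key, ":", fixed = TRUE)[[1]]
      ct <- audit$cistron_table
      got <- ct$intercistronic_nt[ct$transcript_id == p[1] &
                                    ct$upstream_gene == p[2] &
                                    ct$downstream_gene == p[3]]
      add("intercistronic", key,
          length(got) == 1L && got == m$intercistronic[[key]],
          paste(got, collapse = ";"))
    }
    for (tid in names(m$arity)) {
      got <- cistronic_arity(audit$set$transcripts[[tid]])
      add("arity", tid, got == m$arity[[tid]], got)
    }
  }
  n_expected_overlaps <- sum(vapply(manifest, function(m)
    length(m$overlaps), integer(1)))
  add("overlap", "no_unplanted_overlap_rows",
      nrow(audit$overlap_table) == n_expected_overlaps,
      nrow(audit$overlap_table))
  df <- do.call(rbind, checks)
  list(ok = all(df$ok), n_checks = nrow(df), n_failed = sum(!df$ok),
       failures = df[!df$ok, , drop = FALSE])
}
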