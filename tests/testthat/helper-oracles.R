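## Shared helpers: tiny constructors and independent oracles.

## one-contig genome from a bare string
toy_genome <- function(seq, seqid = "chr1", circular = character()) {
  genome_seq(stats::setNames(seq, seqid), circular = circular)
}

## single-exon coding transcript over `cds` with flanking UTRs
toy_coding_transcript <- function(cds, utr5 = "", utr3 = "",
                                  seqid = "chr1", gene = "gX", tid = "tX",
                                  ...) {
  seq <- paste0(utr5, cds, utr3)
  exon <- g_interval(seqid, 0L, nchar(seq), "+")
  orf <- orf_annotation(gene,
                        list(g_interval(seqid, nchar(utr5),
                                        nchar(utr5) + nchar(cds), "+")), ...)
  list(genome = toy_genome(seq, seqid),
       transcript = transcript_model(tid, gene, list(exon), list(orf)))
}

## independent translation oracle: Biostrings' translator
oracle_translate <- function(cds) {
  p <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  sub("\\*$", "", p)
}

## random exception-free ORF: ATG + sense codons + stop
random_orf_cds <- function(n_aa) {
  tab <- Biostrings::getGeneticCode("1")
  sense <- names(tab)[tab != "*"]
  stops <- names(tab)[tab == "*"]
  paste(c("ATG", sample(sense, n_aa - 1L, replace = TRUE),
          sample(stops, 1L)), collapse = "")
}

## brute-force oracle for the candidate noncanonical splice-pair set:
## all 256 dinucleotide pairs, keep Hamming distance 1 from GT-AG with the
## donor G invariant, drop the canonical pairs
brute_force_candidate_pairs <- function() {
  b <- c("A", "C", "G", "T")
  out <- character()
  for (d1 in b) for (d2 in b) for (a1 in b) for (a2 in b) {
    pair <- c(d1, d2, a1, a2)
    if (sum(pair != c("G", "T", "A", "G")) != 1L) next
    if (d1 != "G") next
    lab <- paste0(d1, d2, "-", a1, a2)
    if (lab %in% c("GT-AG", "GC-AG")) next
    out <- c(out, lab)
  }
  sort(out)
}

census_fixture_path <- function() {
  system.file("extdata", "noncanonical_splice_census_r604.tsv",
              package = "GeneModelAudit")
}
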