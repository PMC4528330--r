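## Controlled vocabularies: gene-level Sequence Ontology terms, transcript-level
## flag tokens, and the standardized gene-model comments. Token strings are
## emitted character-for-character; note the hyphen/underscore mix in
## "non-canonical_start_codon" vs "non_canonical_splice_site" is deliberate and
## follows the curated flag vocabulary.

#' Gene-level Sequence Ontology vocabulary
#'
#' @return named character vector mapping SO term name to SO accession.
#' @export
gene_so_vocabulary <- function() {
  c(gene_with_dicistronic_mRNA                        = "SO:0000722",
    gene_with_polycistronic_transcript                = "SO:0000690",
    gene_with_trans_spliced_transcript                = "SO:0000459",
    gene_with_unconventional_translation_start_codon  = "SO:0001739",
    gene_with_translation_start_codon_CUG             = "SO:0001740",
    gene_with_stop_codon_redefined_as_selenocysteine  = "SO:0000710",
    gene_with_stop_codon_read_through                 = "SO:0000697",
    gene_with_transcript_with_translational_frameshift = "SO:0000712",
    mt_gene                                           = "SO:0000088",
    gene_with_edited_transcript                       = "SO:0000548",
    modified_RNA_base_feature                         = "SO:0000250")
}

#' Transcript-level flag vocabulary
#'
#' Tokens proposed for bulk-download FASTA headers, split by flag type.
#'
#' @return named character vector: token -> flag type.
#' @export
transcript_flag_vocabulary <- function() {
  c("dicistronic_mRNA"                       = "Transcript exception",
    "polycistronic_transcript"               = "Transcript exception",
    "non_canonical_splice_site"              = "Transcript exception",
    "endonuclease_spliced_intron"            = "Transcript exception",
    "trans_spliced_transcript"               = "Transcript exception",
    "non-canonical_start_codon"              = "Translation exception",
    "stop_codon_redefined_as_selenocysteine" = "Translation exception",
    "stop_codon_read_through"                = "Translation exception",
    "transcript_with_translational_frameshift" = "Translation exception",
    "mitochondrial_genetic_code"             = "Translation exception",
    "mitochondrial_incomplete_stop_codon"    = "Translation exception",
    "start_codon_not_determined"             = "Translation exception",
    "mutation in strain"                     = "Sequence alteration",
    "genomic sequence error or gap"          = "Sequence alteration")
}

## flags that may appear as *declared* passthroughs in annotation input
declared_flag_tokens <- function() {
  c("trans_spliced_transcript", "endonuclease_spliced_intron",
    "mutation in strain", "genomic sequence error or gap")
}

## standardized multiphasic / bidirectional / shared-exon comments
mp_comment <- function(which) {
  switch(which,
    alt_stop = paste0("Alternative translation stop created by use of ",
                      "multiphasic reading frames within coding region"),
    multiphase_exon = paste0("Multiphase exon postulated: exon reading frame ",
                             "differs in alternative transcripts"),
    first_coding_exon = paste0("Multiphase exon postulated: reading frame of ",
                               "first coding exon differs in alternative ",
                               "transcripts"),
    cross_gene = paste0("Multiphase exon postulated: this gene shares a ",
                        "region of coding sequence with an overlapping gene, ",
                        "but different reading frames are utilized in the ",
                        "overlapping coding region"),
    bidirectional = paste0("Bidirectional region of coding sequence ",
                           "postulated: a portion of the CDS of this gene ",
                           "overlaps a portion of the CDS of a gene on ",
                           "opposite strand."),
    stop("unknown comment key: ", which))
}

overlap_comment <- function(category) {
  switch(category,
    shared_5_exons      = "Shares 5\u2032 exon(s)",
    shared_5_utr        = "Shares 5\u2032 UTR",
    shared_3_utr        = "Shares 3\u2032 UTR",
    complex_atypical    = "Complex/atypical overlap",
    cds_overlap_same_frame = "Genes with CDS overlap",
    nested_unflagged    = NA_character_,
    utr_chain_unflagged = NA_character_,
    none                = NA_character_,
    stop("unknown overlap category: ", category))
}
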