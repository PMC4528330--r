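## Binding classifications to the controlled vocabularies and emitting
## reports / flagged FASTA.

flag_row <- function(target_id, level, token, so_id = NA_character_,
                     provenance = "detected") {
  data.frame(target_id = target_id, level = level, token = token,
             so_id = so_id, provenance = provenance, stringsAsFactors = FALSE)
}

empty_flags <- function() {
  data.frame(target_id = character(), level = character(), token = character(),
             so_id = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

#' Assign gene-level Sequence Ontology terms
#'
#' @param gene_id target gene.
#' @param classifications character vector of classification tokens computed
#'   upstream: `dicistronic`, `polycistronic`, `trans_spliced`,
#'   `non_aug_start`, `cug_start`, `selenocysteine`, `readthrough`,
#'   `frameshift`, `mitochondrial`, `edited`.
#' @return data.frame of flag assignments (`level = "gene_SO"`).
#' @export
assign_gene_so_terms <- function(gene_id, classifications) {
  voc <- gene_so_vocabulary()
  map <- list(
    dicistronic    = "gene_with_dicistronic_mRNA",
    polycistronic  = "gene_with_polycistronic_transcript",
    trans_spliced  = "gene_with_trans_spliced_transcript",
    non_aug_start  = "gene_with_unconventional_translation_start_codon",
    cug_start      = c("gene_with_unconventional_translation_start_codon",
                       "gene_with_translation_start_codon_CUG"),
    selenocysteine = "gene_with_stop_codon_redefined_as_selenocysteine",
    readthrough    = "gene_with_stop_codon_read_through",
    frameshift     = "gene_with_transcript_with_translational_frameshift",
    mitochondrial  = "mt_gene",
    edited         = "gene_with_edited_transcript")
  bad <- setdiff(classifications, names(map))
  if (length(bad)) stop("unknown gene classification token: ", bad[1])
  terms <- unique(unlist(map[classifications], use.names = FALSE))
  if (!length(terms)) return(empty_flags())
  do.call(rbind, lapply(terms, function(tm)
    flag_row(gene_id, "gene_SO", tm, so_id = unname(voc[tm]))))
}

## derive gene classification tokens from the annotation itself
gene_classification_tokens <- function(set, gene_id, edited_genes = character()) {
  g <- set$genes[[gene_id]]
  tok <- character()
  prof <- gene_cistronic_profile(gene_id, set)
  if (2L %in% prof$arity_set) tok <- c(tok, "dicistronic")
  if (any(prof$arity_set > 2L)) tok <- c(tok, "polycistronic")
  orfs <- gene_orfs(set, gene_id)
  for (tid in g$transcript_ids) {
    if (is_trans_spliced(set$transcripts[[tid]]))
      tok <- c(tok, "trans_spliced")
  }
  for (o in orfs) {
    k <- o$start_codon_kind
    if (!k %in% c("AUG", "undetermined"))
      tok <- c(tok, if (k == "CTG") "cug_start" else "non_aug_start")
    if (length(o$selenocysteine_positions)) tok <- c(tok, "selenocysteine")
    if (length(o$readthrough_positions)) tok <- c(tok, "readthrough")
    if (!is.null(o$frameshift)) tok <- c(tok, "frameshift")
    if (o$genetic_code == "invertebrate_mitochondrial")
      tok <- c(tok, "mitochondrial")
  }
  if (gene_id %in% edited_genes) tok <- c(tok, "edited")
  unique(tok)
}

#' Assign transcript-level flags
#'
#' Emits exactly the tokens of [transcript_flag_vocabulary]: structural flags
#' derived from the transcript (cistronic arity, noncanonical splice),
#' translation-exception flags derived from its ORF declarations, and the
#' declared passthrough flags verbatim.
#'
#' @param t a [transcript_model].
#' @param intron_classes classifications of this transcript's introns (from
#'   [classify_intron]).
#' @return data.frame of flag assignments (`level = "transcript_flag"`).
#' @export
assign_transcript_flags <- function(t, intron_classes = character()) {
  tok <- character()
  prov <- character()
  add <- function(token, provenance = "detected") {
    tok <<- c(tok, token); prov <<- c(prov, provenance)
  }
  arity <- cistronic_arity(t)
  if (arity == 2L) add("dicistronic_mRNA")
  if (arity > 2L) add("polycistronic_transcript")
  if (any(startsWith(intron_classes, "noncanonical")))
    add("non_canonical_splice_site")
  for (f in intersect(t$declared_flags, declared_flag_tokens()))
    add(f, "declared")
  for (o in t$orfs) {
    if (!o$start_codon_kind %in% c("AUG", "undetermined"))
      add("non-canonical_start_codon")
    if (identical(o$start_codon_kind, "undetermined"))
      add("start_codon_not_determined")
    if (length(o$selenocysteine_positions))
      add("stop_codon_redefined_as_selenocysteine")
    if (length(o$readthrough_positions)) add("stop_codon_read_through")
    if (!is.null(o$frameshift)) add("transcript_with_translational_frameshift")
    if (o$genetic_code == "invertebrate_mitochondrial")
      add("mitochondrial_genetic_code")
    if (o$incomplete_stop) add("mitochondrial_incomplete_stop_codon")
  }
  keep <- !duplicated(tok)
  tok <- tok[keep]; prov <- prov[keep]
  if (!length(tok)) return(empty_flags())
  do.call(rbind, Map(function(token, provenance)
    flag_row(t$transcript_id, "transcript_flag", token,
             provenance = provenance), tok, prov))
}

#' Emit flagged transcript and protein FASTA
#'
#' One nucleotide record per transcript and one protein record per ORF.
#' Headers are `identifier key=value ...` with a semicolon-joined `flags`
#' field (empty when the transcript is unexceptional); field order is fixed,
#' so output is byte-identical across runs. Protein sequences carry `U` at
#' selenocysteine positions and `X` at read-through stops.
#'
#' @param audit an `annotation_audit` (from [audit_annotation]).
#' @param dir output directory; writes `transcripts.fna` and `proteins.faa`.
#' @return invisibly, the two file paths.
#' @export
emit_flagged_fasta <- function(audit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set <- audit$set; g <- audit$genome
  nt_path <- file.path(dir, "transcripts.fna")
  aa_path <- file.path(dir, "proteins.faa")
  nt <- character(); aa <- character()
  for (tid in names(set$transcripts)) {
    t <- set$transcripts[[tid]]
    flags <- audit$transcript_flags[[tid]]
    flag_str <- if (is.null(flags) || !nrow(flags)) ""
                else paste(flags$token, collapse = ";")
    nt <- c(nt, sprintf(">%s type=%s genes=%s flags=%s", tid,
                        if (length(t$orfs)) "mRNA" else "ncRNA",
                        paste(t$gene_ids, collapse = ","), flag_str),
            wrap_seq(spliced_sequence(t, g)))
    for (o in t$orfs) {
      tr <- audit$translations[[paste0(tid, ":", o$gene_id)]]
      aa <- c(aa, sprintf(">%s:%s gene=%s transcript=%s flags=%s", tid,
                          o$gene_id, o$gene_id, tid, flag_str),
              wrap_seq(tr$peptide))
    }
  }
  for (p in list(list(nt_path, nt), list(aa_path, aa))) {
    con <- file(p[[1]], "wb")
    writeLines(p[[2]], con, sep = "\n")
    close(con)
  }
  invisible(c(nt_path, aa_path))
}

#' Emit the machine-readable audit report
#'
#' Writes one JSON document plus TSV tables (genes, transcripts, introns,
#' overlaps, junction audits, splice census) with stable ordering: re-running
#' on identical inputs produces byte-identical files.
#'
#' @param audit an `annotation_audit`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
emit_report <- function(audit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    con <- file(p, "wb")
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", eol = "\n")
    close(con)
    paths <<- c(paths, p)
  }
  wtsv(audit$gene_table, "genes.tsv")
  wtsv(audit$transcript_table, "transcripts.tsv")
  wtsv(audit$intron_table, "introns.tsv")
  wtsv(audit$overlap_table, "overlaps.tsv")
  wtsv(audit$junction_table, "junctions.tsv")
  wtsv(audit$census, "census.tsv")
  wtsv(audit$cistron_table, "cistrons.tsv")
  doc <- list(
    n_genes = length(audit$set$genes),
    n_transcripts = length(audit$set$transcripts),
    n_introns = length(audit$introns),
    gene_so = lapply(audit$gene_so, function(df)
      if (nrow(df)) stats::setNames(df$so_id, df$token) else list()),
    transcript_flags = lapply(audit$transcript_flags, function(df)
      if (nrow(df)) df$token else list()),
    gene_comments = audit$gene_comments,
    summary = audit$summary)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(doc, jp, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "list")
  paths <- c(paths, jp)
  invisible(paths)
}
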