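#' Full annotation audit
#'
#' Runs every classifier over an annotation: cistronic profiles and
#' intercistronic metrics, same- and opposite-strand overlap classification
#' (shared exons, same-frame CDS overlap, multiphasic and bidirectional
#' regions), intron classification with U12 tagging and
#' similar-alternative-splice lookup, junction auditing, exception-aware
#' translation of every ORF, and the binding of results to Sequence Ontology
#' terms, transcript flags and standardized gene-model comments.
#'
#' @param set an [annotation_set].
#' @param g a [genome_seq].
#' @param junctions list of [junction_call] (optional).
#' @param editing_sites data.frame with columns `seqid`, `pos` (0-based
#'   genomic position of an A-to-I editing site), as from
#'   [read_editing_sites] (optional).
#' @param config an [audit_config].
#' @return object of class `annotation_audit`.
#' @export
audit_annotation <- function(set, g, junctions = NULL, editing_sites = NULL,
                             config = audit_config()) {
  ## ---- introns -----------------------------------------------------------
  introns <- collect_introns(set, g)
  intron_rows <- list()
  intron_classes_by_t <- list()
  for (k in seq_along(introns)) {
    ir <- introns[[k]]
    flags <- unique(unlist(lapply(ir$transcript_ids, function(tid)
      set$transcripts[[tid]]$declared_flags)))
    cls <- classify_intron(ir, flags)
    introns[[k]]$classification <- cls
    u12 <- tag_u12(ir, g, config)
    simalt <- if (startsWith(cls, "noncanonical"))
      similar_alternative_splice(ir, set, g) else NULL
    intron_rows[[k]] <- data.frame(
      intron = intron_key(ir$interval), donor = ir$donor,
      acceptor = ir$acceptor, classification = cls, u12 = u12,
      similar_alternative = if (is.null(simalt)) NA_character_
                            else intron_key(simalt$interval),
      context = intron_context(ir, set),
      transcripts = paste(ir$transcript_ids, collapse = ","),
      stringsAsFactors = FALSE)
    for (tid in ir$transcript_ids)
      intron_classes_by_t[[tid]] <- c(intron_classes_by_t[[tid]], cls)
  }
  intron_table <- if (length(intron_rows)) do.call(rbind, intron_rows)
    else data.frame(intron = character(), donor = character(),
                    acceptor = character(), classification = character(),
                    u12 = logical(), similar_alternative = character(),
                    context = character(), transcripts = character(),
                    stringsAsFactors = FALSE)

  ## ---- cistrons ----------------------------------------------------------
  profiles <- lapply(names(set$genes), gene_cistronic_profile, set = set)
  names(profiles) <- names(set$genes)
  cistron_rows <- list()
  for (tid in names(set$transcripts)) {
    t <- set$transcripts[[tid]]
    if (cistronic_arity(t) < 2L) next
    for (i in seq_len(length(t$orfs) - 1L)) {
      cistron_rows[[length(cistron_rows) + 1L]] <- data.frame(
        transcript_id = tid,
        upstream_gene = t$orfs[[i]]$gene_id,
        downstream_gene = t$orfs[[i + 1L]]$gene_id,
        intercistronic_nt = intercistronic_distance(t$orfs[[i]],
                                                    t$orfs[[i + 1L]], t),
        stringsAsFactors = FALSE)
    }
  }
  cistron_table <- if (length(cistron_rows)) do.call(rbind, cistron_rows)
    else data.frame(transcript_id = character(), upstream_gene = character(),
                    downstream_gene = character(),
                    intercistronic_nt = integer(), stringsAsFactors = FALSE)

  ## ---- overlaps ----------------------------------------------------------
  gene_comments <- stats::setNames(vector("list", length(set$genes)),
                                   names(set$genes))
  overlap_rows <- list()
  add_overlap <- function(a, b, category, comment, length_nt = NA_integer_,
                          region = NA_character_, long_overlap = FALSE) {
    overlap_rows[[length(overlap_rows) + 1L]] <<- data.frame(
      gene_a = a, gene_b = b, category = category,
      region = region, length_nt = length_nt, long_overlap = long_overlap,
      comment = if (is.na(comment)) NA_character_ else comment,
      stringsAsFactors = FALSE)
    if (!is.na(comment)) {
      gene_comments[[a]] <<- unique(c(gene_comments[[a]], comment))
      if (b != a) gene_comments[[b]] <<- unique(c(gene_comments[[b]], comment))
    }
  }
  region_label <- function(iv)
    sprintf("%s:%d-%d", iv$seqid, iv$start + 1L, iv$end)  # 1-based output

  gids <- names(set$genes)
  share_tr <- function(a, b)
    length(intersect(set$genes[[a]]$transcript_ids,
                     set$genes[[b]]$transcript_ids)) > 0L
  spans_touch <- function(a, b, same_strand) {
    for (sa in set$genes[[a]]$spans) for (sb in set$genes[[b]]$spans) {
      if (sa$seqid != sb$seqid) next
      if (same_strand != (sa$strand == sb$strand)) next
      if (sa$start < sb$end && sb$start < sa$end) return(TRUE)
    }
    FALSE
  }

  ## cross-gene CDS comparisons + noncoding overlap classification
  if (length(gids) > 1L) for (ai in seq_len(length(gids) - 1L)) {
    for (bi in seq.int(ai + 1L, length(gids))) {
      a <- gids[ai]; b <- gids[bi]
      if (spans_touch(a, b, same_strand = TRUE)) {
        shared_cds <- FALSE
        seen_regions <- character()
        for (oa in gene_orfs(set, a)) for (ob in gene_orfs(set, b)) {
          moa <- codon_offset_map(oa); mob <- codon_offset_map(ob)
          if (moa$seqid != mob$seqid || moa$strand != mob$strand) next
          if (length(intersect(moa$pos, mob$pos))) shared_cds <- TRUE
          for (r in multiphasic_regions(oa, ob)) {
            key <- region_label(r$interval)
            if (key %in% seen_regions) next
            seen_regions <- c(seen_regions, key)
            cm <- classify_multiphasic(r, config)
            add_overlap(a, b, "multiphasic_cross_gene", cm$comment,
                        r$length_nt, key, cm$long_overlap)
          }
        }
        sf <- detect_cds_overlap_same_frame(a, b, set)
        if (!is.null(sf))
          add_overlap(a, b, "cds_overlap_same_frame", sf$comment,
                      sf$length_nt,
                      paste(vapply(sf$regions, region_label, character(1)),
                            collapse = ","))
        if (!shared_cds && !share_tr(a, b)) {
          call <- classify_noncoding_overlap(a, b, set)
          if (call$category != "none")
            add_overlap(a, b, call$category, call$comment)
        }
      }
      if (spans_touch(a, b, same_strand = FALSE)) {
        seen_regions <- character()
        for (oa in gene_orfs(set, a)) for (ob in gene_orfs(set, b)) {
          moa <- codon_offset_map(oa); mob <- codon_offset_map(ob)
          if (moa$seqid != mob$seqid || moa$strand == mob$strand) next
          bd <- detect_bidirectional(oa, ob)
          if (is.null(bd)) next
          key <- paste(vapply(bd$regions, region_label, character(1)),
                       collapse = ",")
          if (key %in% seen_regions) next
          seen_regions <- c(seen_regions, key)
          add_overlap(a, b, "bidirectional", bd$comment, bd$length_nt, key)
        }
      }
    }
  }

  ## within-gene multiphasic regions (alternative isoforms)
  for (gid in gids) {
    orfs <- gene_orfs(set, gid)
    if (length(orfs) < 2L) next
    seen_regions <- character()
    for (i in seq_len(length(orfs) - 1L)) for (j in seq.int(i + 1L,
                                                            length(orfs))) {
      ma <- codon_offset_map(orfs[[i]]); mb <- codon_offset_map(orfs[[j]])
      if (ma$seqid != mb$seqid || ma$strand != mb$strand) next
      for (r in multiphasic_regions(orfs[[i]], orfs[[j]],
                                    members = c(attr(orfs[[i]], "transcript_id"),
                                                attr(orfs[[j]], "transcript_id")))) {
        key <- region_label(r$interval)
        if (key %in% seen_regions) next
        seen_regions <- c(seen_regions, key)
        cm <- classify_multiphasic(r, config)
        add_overlap(gid, gid, "multiphasic_within_gene", cm$comment,
                    r$length_nt, key, cm$long_overlap)
      }
    }
  }
  overlap_table <- if (length(overlap_rows)) do.call(rbind, overlap_rows)
    else data.frame(gene_a = character(), gene_b = character(),
                    category = character(), region = character(),
                    length_nt = integer(), long_overlap = logical(),
                    comment = character(), stringsAsFactors = FALSE)

  ## ---- translation -------------------------------------------------------
  translations <- list()
  for (tid in names(set$transcripts)) {
    t <- set$transcripts[[tid]]
    for (o in t$orfs)
      translations[[paste0(tid, ":", o$gene_id)]] <- translate_orf(o, t, g)
  }

  ## ---- junctions ---------------------------------------------------------
  junction_rows <- list()
  if (!is.null(junctions)) for (k in seq_along(junctions)) {
    j <- junctions[[k]]
    d <- audit_junction(j, set, g, config, introns = introns)
    junction_rows[[k]] <- data.frame(
      name = if (is.na(j$name)) sprintf("junction_%03d", k) else j$name,
      junction = intron_key_unstranded(j$interval),
      strand = if (j$stranded) j$interval$strand else ".",
      read_count = j$read_count, score = j$score, verdict = d$verdict,
      nearest = d$nearest, offset = d$offset, stringsAsFactors = FALSE)
  }
  junction_table <- if (length(junction_rows)) do.call(rbind, junction_rows)
    else data.frame(name = character(), junction = character(),
                    strand = character(), read_count = integer(),
                    score = numeric(), verdict = character(),
                    nearest = character(), offset = integer(),
                    stringsAsFactors = FALSE)

  ## ---- A-to-I editing passthrough ---------------------------------------
  edited_genes <- character()
  site_flags <- empty_flags()
  if (!is.null(editing_sites) && nrow(editing_sites)) {
    for (k in seq_len(nrow(editing_sites))) {
      s <- editing_sites[k, ]
      hit <- Filter(function(gid) any(vapply(set$genes[[gid]]$spans,
        function(sp) sp$seqid == s$seqid && sp$start <= s$pos &&
          s$pos < sp$end, logical(1))), gids)
      edited_genes <- c(edited_genes, hit)
      site_flags <- rbind(site_flags,
        flag_row(sprintf("%s:%d", s$seqid, s$pos + 1L), "gene_SO",
                 "modified_RNA_base_feature",
                 so_id = unname(gene_so_vocabulary()["modified_RNA_base_feature"]),
                 provenance = "declared"))
    }
    edited_genes <- unique(edited_genes)
  }

  ## ---- flags -------------------------------------------------------------
  gene_so <- lapply(gids, function(gid)
    assign_gene_so_terms(gid, gene_classification_tokens(set, gid,
                                                         edited_genes)))
  names(gene_so) <- gids
  transcript_flags <- lapply(names(set$transcripts), function(tid)
    assign_transcript_flags(set$transcripts[[tid]],
                            intron_classes_by_t[[tid]] %||% character()))
  names(transcript_flags) <- names(set$transcripts)

  gene_table <- do.call(rbind, c(list(empty_gene_table()),
    lapply(gids, function(gid) {
      prof <- profiles[[gid]]
      data.frame(gene_id = gid,
                 arity_set = paste(prof$arity_set, collapse = ","),
                 exclusively_polycistronic = prof$exclusively_polycistronic,
                 so_terms = paste(gene_so[[gid]]$token, collapse = ";"),
                 so_ids = paste(gene_so[[gid]]$so_id, collapse = ";"),
                 comments = paste(gene_comments[[gid]], collapse = " | "),
                 stringsAsFactors = FALSE)
    })))
  transcript_table <- do.call(rbind, c(list(empty_transcript_table()),
    lapply(names(set$transcripts), function(tid) {
      t <- set$transcripts[[tid]]
      data.frame(transcript_id = tid,
                 genes = paste(t$gene_ids, collapse = ","),
                 arity = cistronic_arity(t),
                 flags = paste(transcript_flags[[tid]]$token, collapse = ";"),
                 stringsAsFactors = FALSE)
    })))

  census <- splice_summary(set, g, junctions, config)

  summary <- list(
    n_polycistronic_transcripts =
      sum(vapply(set$transcripts, function(t) cistronic_arity(t) > 1L,
                 logical(1))),
    n_exclusively_polycistronic_genes =
      sum(vapply(profiles, `[[`, logical(1), "exclusively_polycistronic")),
    n_noncanonical_introns =
      sum(startsWith(intron_table$classification, "noncanonical")),
    n_readthrough_genes = sum(vapply(gene_so, function(df)
      "gene_with_stop_codon_read_through" %in% df$token, logical(1))),
    n_edited_genes = length(edited_genes))

  structure(list(set = set, genome = g, config = config,
                 profiles = profiles, introns = introns,
                 intron_table = intron_table, cistron_table = cistron_table,
                 overlap_table = overlap_table, gene_comments = gene_comments,
                 translations = translations,
                 junction_table = junction_table, census = census,
                 gene_so = gene_so, transcript_flags = transcript_flags,
                 site_flags = site_flags, edited_genes = edited_genes,
                 gene_table = gene_table,
                 transcript_table = transcript_table,
                 summary = summary),
            class = "annotation_audit")
}

empty_gene_table <- function()
  data.frame(gene_id = character(), arity_set = character(),
             exclusively_polycistronic = logical(), so_terms = character(),
             so_ids = character(), comments = character(),
             stringsAsFactors = FALSE)

empty_transcript_table <- function()
  data.frame(transcript_id = character(), genes = character(),
             arity = integer(), flags = character(), stringsAsFactors = FALSE)

#' @export
print.annotation_audit <- function(x, ...) {
  cat("annotation_audit\n")
  cat("  genes:", length(x$set$genes),
      " transcripts:", length(x$set$transcripts),
      " introns:", length(x$introns), "\n")
  cat("  polycistronic transcripts:",
      x$summary$n_polycistronic_transcripts, "\n")
  cat("  noncanonical introns:", x$summary$n_noncanonical_introns, "\n")
  cat("  genes with SO terms:",
      sum(vapply(x$gene_so, nrow, integer(1)) > 0L), "\n")
  cat("  flagged transcripts:",
      sum(vapply(x$transcript_flags, nrow, integer(1)) > 0L), "\n")
  invisible(x)
}

#' Read A-to-I editing sites
#'
#' Tab-separated file with columns `seqid` and `pos` (1-based genomic
#' position of the edited adenosine); positions are converted to the
#' package's 0-based convention.
#'
#' @param path TSV file.
#' @return data.frame with `seqid`, `pos` (0-based).
#' @export
read_editing_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("seqid", "pos") %in% names(df)))
    stop("editing site file needs 'seqid' and 'pos' columns")
  data.frame(seqid = as.character(df$seqid), pos = as.integer(df$pos) - 1L,
             stringsAsFactors = FALSE)
}
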