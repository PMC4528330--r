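## GFF3 input/output.
##
## Standard GFF3 cannot bind two CDS groups of one mRNA to two distinct genes,
## so multi-gene (dicistronic/polycistronic) transcripts use a small documented
## dialect on top of plain GFF3:
##   * the mRNA feature carries a comma-separated Parent naming every owning
##     gene, in cistron order;
##   * every CDS feature carries a `gene=` attribute naming the gene its CDS
##     group belongs to;
##   * exon features carry `exon_order=` giving 5'->3' transcript order (this
##     is what makes trans-spliced, mixed-strand transcripts unambiguous);
##   * declared exceptions are attributes on the first CDS line of a group:
##     `start_codon=` (a codon or "undetermined"), `readthrough_codons=`,
##     `selenocysteine_codons=` (1-based codon indices), `frameshift_codon=`,
##     `incomplete_stop=true`, `genetic_code=invertebrate_mitochondrial`;
##   * passthrough flags sit in a `flags=` attribute on the mRNA (or gene).
## File coordinates are 1-based inclusive; in memory everything is 0-based
## half-open.

#' Read gene models from GFF3
#'
#' @param path GFF3 file following the dialect described in the package
#'   documentation (plain single-gene GFF3 with gene/mRNA/exon/CDS features is
#'   a special case of it).
#' @return an [annotation_set].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  for (col in c("seqid", "type", "strand")) gff[[col]] <- as.character(gff[[col]])
  att <- function(row, name, default = NULL) {
    if (!name %in% names(gff)) return(default)
    v <- gff[[name]][[row]]
    if (is.list(v)) v <- unlist(v)
    v <- as.character(v)
    v <- v[!is.na(v)]
    if (!length(v)) default else v
  }

  parent_of <- lapply(seq_len(nrow(gff)), function(i)
    att(i, "Parent", character()))

  g_rows <- which(gff$type == "gene")
  gene_ids <- vapply(g_rows, function(r) att(r, "ID", NA_character_)[1],
                     character(1))
  if (anyNA(gene_ids)) stop("gene feature without ID")
  gene_flags <- stats::setNames(lapply(g_rows, function(r)
    att(r, "flags", character())), gene_ids)

  t_rows <- which(gff$type %in% c("mRNA", "ncRNA", "transcript"))
  transcripts <- list()
  for (r in t_rows) {
    tid <- att(r, "ID", NA_character_)[1]
    if (is.na(tid)) stop("transcript feature without ID")
    parents <- att(r, "Parent", character())
    if (!length(parents)) stop("transcript ", tid, " has no Parent gene")
    unknown <- setdiff(parents, gene_ids)
    if (length(unknown))
      stop("transcript ", tid, " names undeclared gene: ", unknown[1])
    flags <- att(r, "flags", character())
    bad <- setdiff(flags, names(transcript_flag_vocabulary()))
    if (length(bad))
      stop("unknown exception token on transcript ", tid, ": ", bad[1])

    ex_rows <- which(gff$type == "exon" &
                       vapply(parent_of, function(p) tid %in% p, logical(1)))
    if (!length(ex_rows)) stop("transcript ", tid, " has no exons")
    ord <- vapply(ex_rows, function(i)
      as.integer(att(i, "exon_order", NA_character_)[1]), integer(1))
    if (all(!is.na(ord))) {
      ex_rows <- ex_rows[order(ord)]
    } else {
      str <- unique(gff$strand[ex_rows])
      if (length(str) > 1L)
        stop("mixed-strand exons on ", tid, " require exon_order attributes")
      ex_rows <- ex_rows[order(gff$start[ex_rows],
                               decreasing = (str == "-"))]
    }
    exons <- lapply(ex_rows, function(i)
      g_interval(gff$seqid[i], gff$start[i] - 1L, gff$end[i], gff$strand[i]))

    cds_rows <- which(gff$type == "CDS" &
                        vapply(parent_of, function(p) tid %in% p, logical(1)))
    orfs <- list()
    if (length(cds_rows)) {
      owner <- vapply(cds_rows, function(i) {
        v <- att(i, "gene", NA_character_)[1]
        if (is.na(v) && length(parents) == 1L) parents else v
      }, character(1))
      if (anyNA(owner))
        stop("CDS of multi-gene transcript ", tid,
             " lacks an owning-gene attribute")
      unknown <- setdiff(owner, parents)
      if (length(unknown))
        stop("CDS on ", tid, " names gene ", unknown[1],
             " which is not a Parent of the transcript")
      for (gid in unique(owner)) {
        rows <- cds_rows[owner == gid]
        segs <- lapply(rows, function(i)
          g_interval(gff$seqid[i], gff$start[i] - 1L, gff$end[i],
                     gff$strand[i]))
        ## order segments 5'->3' on their strand
        if (length(segs) > 1L) {
          st <- vapply(segs, `[[`, integer(1), "start")
          segs <- segs[order(st, decreasing = (segs[[1]]$strand == "-"))]
        }
        first_of <- function(name) {
          for (i in rows) {
            v <- att(i, name, NULL)
            if (!is.null(v)) return(v)
          }
          NULL
        }
        fs_codon <- first_of("frameshift_codon")
        orfs[[length(orfs) + 1L]] <- orf_annotation(
          gene_id = gid, cds_segments = segs,
          start_codon_kind = first_of("start_codon") %||% "AUG",
          readthrough_positions =
            as.integer(first_of("readthrough_codons") %||% integer()),
          selenocysteine_positions =
            as.integer(first_of("selenocysteine_codons") %||% integer()),
          frameshift = if (is.null(fs_codon)) NULL
                       else list(codon_index = as.integer(fs_codon), shift = 1L),
          incomplete_stop =
            tolower(first_of("incomplete_stop") %||% "false") %in%
              c("true", "1"),
          genetic_code = first_of("genetic_code") %||% "standard")
      }
    }
    t_tmp <- structure(list(transcript_id = tid, gene_ids = parents,
                            exons = exons, orfs = list(),
                            declared_flags = flags),
                       class = "transcript_model")
    ## order ORFs 5'->3' by their first CDS base in transcript coordinates
    if (length(orfs) > 1L) {
      firsts <- vapply(orfs, function(o) {
        t2 <- t_tmp; t2$orfs <- list(o)
        orf_transcript_span(o, t2)[["first"]]
      }, numeric(1))
      orfs <- orfs[order(firsts)]
    }
    transcripts[[length(transcripts) + 1L]] <-
      transcript_model(tid, parents, exons, orfs, flags)
  }
  set <- annotation_set(transcripts,
                        gene_flags = gene_flags[vapply(gene_flags, length,
                                                       integer(1)) > 0])
  orphan <- setdiff(gene_ids, names(set$genes))
  if (length(orphan)) stop("gene ", orphan[1], " has no transcript")
  set
}

#' Write gene models to GFF3
#'
#' Emits the same dialect [read_annotation] consumes;
#' `read_annotation(write_annotation(set, f))` is the identity on every field.
#'
#' @param set an [annotation_set].
#' @param path output path.
#' @export
write_annotation <- function(set, path) {
  esc <- function(x) x  # token vocabulary contains no ';', '=', ',' or '%'
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, start, end, strand, phase, attrs) {
    sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t%s\t%s", seqid, type, start + 1L, end,
            strand, phase, attrs)
  }
  for (gid in names(set$genes)) {
    g <- set$genes[[gid]]
    sp <- g$spans[[1]]
    attrs <- paste0("ID=", gid)
    if (length(g$flags))
      attrs <- paste0(attrs, ";flags=", paste(esc(g$flags), collapse = ","))
    lines <- c(lines, fmt(sp$seqid, "gene", sp$start, sp$end, sp$strand, ".",
                          attrs))
  }
  for (tid in names(set$transcripts)) {
    t <- set$transcripts[[tid]]
    seqids <- unique(vapply(t$exons, `[[`, character(1), "seqid"))
    strands <- unique(vapply(t$exons, `[[`, character(1), "strand"))
    b_seqid <- seqids[1]
    b_strand <- if (length(strands) == 1L && length(seqids) == 1L) strands
                else "."
    onb <- vapply(t$exons, function(e) e$seqid == b_seqid, logical(1))
    b_start <- min(vapply(t$exons[onb], `[[`, integer(1), "start"))
    b_end <- max(vapply(t$exons[onb], `[[`, integer(1), "end"))
    ttype <- if (length(t$orfs)) "mRNA" else "ncRNA"
    attrs <- paste0("ID=", tid, ";Parent=", paste(t$gene_ids, collapse = ","))
    if (length(t$declared_flags))
      attrs <- paste0(attrs, ";flags=",
                      paste(esc(t$declared_flags), collapse = ","))
    lines <- c(lines, fmt(b_seqid, ttype, b_start, b_end, b_strand, ".", attrs))
    for (i in seq_along(t$exons)) {
      e <- t$exons[[i]]
      lines <- c(lines, fmt(e$seqid, "exon", e$start, e$end, e$strand, ".",
                            paste0("Parent=", tid, ";exon_order=", i)))
    }
    for (o in t$orfs) {
      cum <- 0L
      for (i in seq_along(o$cds_segments)) {
        s <- o$cds_segments[[i]]
        phase <- (3L - (cum %% 3L)) %% 3L
        attrs <- paste0("Parent=", tid, ";gene=", o$gene_id)
        if (i == 1L) {
          if (!identical(o$start_codon_kind, "AUG"))
            attrs <- paste0(attrs, ";start_codon=", o$start_codon_kind)
          if (length(o$readthrough_positions))
            attrs <- paste0(attrs, ";readthrough_codons=",
                            paste(o$readthrough_positions, collapse = ","))
          if (length(o$selenocysteine_positions))
            attrs <- paste0(attrs, ";selenocysteine_codons=",
                            paste(o$selenocysteine_positions, collapse = ","))
          if (!is.null(o$frameshift))
            attrs <- paste0(attrs, ";frameshift_codon=",
                            o$frameshift$codon_index)
          if (o$incomplete_stop)
            attrs <- paste0(attrs, ";incomplete_stop=true")
          if (o$genetic_code != "standard")
            attrs <- paste0(attrs, ";genetic_code=", o$genetic_code)
        }
        lines <- c(lines, fmt(s$seqid, "CDS", s$start, s$end, s$strand,
                              as.character(phase), attrs))
        cum <- cum + interval_len(s)
      }
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
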