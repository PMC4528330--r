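test_that("gene classifications map to their Sequence Ontology accessions", {
  di <- assign_gene_so_terms("gA", "dicistronic")
  expect_equal(di$so_id, "SO:0000722")
  expect_equal(di$token, "gene_with_dicistronic_mRNA")

  cug <- assign_gene_so_terms("gB", "cug_start")
  expect_setequal(cug$so_id, c("SO:0001739", "SO:0001740"))

  expect_equal(nrow(assign_gene_so_terms("gC", character())), 0L)
  expect_error(assign_gene_so_terms("gD", "blorp"), "unknown gene")

  poly <- assign_gene_so_terms("gE", c("polycistronic", "readthrough"))
  expect_setequal(poly$so_id, c("SO:0000690", "SO:0000697"))
})

test_that("transcript flags use the curated vocabulary tokens verbatim", {
  voc <- transcript_flag_vocabulary()
  ## the vocabulary mixes hyphen and underscore deliberately
  expect_true("non-canonical_start_codon" %in% names(voc))
  expect_true("non_canonical_splice_site" %in% names(voc))
  expect_true("mutation in strain" %in% names(voc))
  expect_equal(unname(voc["stop_codon_read_through"]),
               "Translation exception")

  t <- transcript_model("t1", "g1", list(g_interval("chr1", 0, 100, "+")),
    list(orf_annotation("g1", list(g_interval("chr1", 6, 66, "+")))))
  fl <- assign_transcript_flags(t, intron_classes = "noncanonical:GT-AT")
  expect_equal(fl$token, "non_canonical_splice_site")

  mito <- transcript_model("t2", "g2", list(g_interval("mt", 0, 40, "+")),
    list(orf_annotation("g2", list(g_interval("mt", 2, 39, "+")),
                        incomplete_stop = TRUE,
                        genetic_code = "invertebrate_mitochondrial")))
  fl2 <- assign_transcript_flags(mito)
  expect_setequal(fl2$token, c("mitochondrial_genetic_code",
                               "mitochondrial_incomplete_stop_codon"))

  plain <- transcript_model("t3", "g3", list(g_interval("chr1", 0, 60, "+")),
    list(orf_annotation("g3", list(g_interval("chr1", 6, 36, "+")))))
  expect_equal(nrow(assign_transcript_flags(plain)), 0L)

  ## every emitted token is drawn from the vocabulary
  fix <- generate_fixture(fixture_spec(seed = 1))
  aud <- audit_annotation(fix$set, fix$genome)
  for (df in aud$transcript_flags)
    expect_true(all(df$token %in% names(voc)))
})

test_that("gene- and transcript-level flags stay consistent", {
  fix <- generate_fixture(fixture_spec(seed = 9))
  aud <- audit_annotation(fix$set, fix$genome)
  pairings <- list(
    c("SO:0000697", "stop_codon_read_through"),
    c("SO:0000710", "stop_codon_redefined_as_selenocysteine"),
    c("SO:0000712", "transcript_with_translational_frameshift"),
    c("SO:0000459", "trans_spliced_transcript"),
    c("SO:0000722", "dicistronic_mRNA"))
  for (gid in names(aud$set$genes)) {
    tids <- aud$set$genes[[gid]]$transcript_ids
    tr_tokens <- unique(unlist(lapply(aud$transcript_flags[tids],
                                      `[[`, "token")))
    for (p in pairings) {
      expect_equal(p[1] %in% aud$gene_so[[gid]]$so_id, p[2] %in% tr_tokens,
                   info = paste(gid, p[1]))
    }
  }
})

test_that("flagged FASTA carries exception marks and is deterministic", {
  fix <- generate_fixture(fixture_spec(seed = 1))
  aud <- audit_annotation(fix$set, fix$genome, junctions = fix$junctions,
                          editing_sites = fix$editing_sites)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_flagged_fasta(aud, d1)
  emit_flagged_fasta(aud, d2)
  faa <- readLines(file.path(d1, "proteins.faa"))
  rt <- Filter(function(m) m$category == "readthrough", fix$manifest)[[1]]
  hdr_i <- grep(paste0("^>", rt$transcripts[1], ":"), faa)
  expect_match(faa[hdr_i], "stop_codon_read_through")
  expect_match(faa[hdr_i + 1L], "X")
  ## unexceptional transcripts carry an empty flag field
  mono <- Filter(function(m) m$category == "mono", fix$manifest)[[1]]
  fna <- readLines(file.path(d1, "transcripts.fna"))
  expect_match(fna[grep(paste0("^>", mono$transcripts[1], " "), fna)],
               "flags=$")
  for (f in c("transcripts.fna", "proteins.faa"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("reports are machine-readable, complete and byte-stable", {
  fix <- generate_fixture(fixture_spec(seed = 2))
  aud <- audit_annotation(fix$set, fix$genome, junctions = fix$junctions,
                          editing_sites = fix$editing_sites)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_report(aud, d1)
  emit_report(aud, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  doc <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(doc$n_genes, length(fix$set$genes))
  ed <- Filter(function(m) m$category == "edited", fix$manifest)[[1]]
  expect_true("SO:0000548" %in% unlist(doc$gene_so[[ed$genes[1]]]))

  ## empty annotation: zero-count report
  aud0 <- audit_annotation(annotation_set(list()),
                           toy_genome("ACGT", seqid = "chrA"))
  d0 <- withr::local_tempdir()
  emit_report(aud0, d0)
  doc0 <- jsonlite::read_json(file.path(d0, "report.json"))
  expect_equal(doc0$n_genes, 0L)
  expect_equal(doc0$n_introns, 0L)
})
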