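test_that("FASTA reading normalizes case and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), f)
  g <- read_genome(f)
  expect_equal(unname(g$records["chr1"]), "ACGT")
  expect_equal(nchar(g$records[["chr1"]]), 4L)

  writeLines(c(">a", "ACGT", ">a", "AC"), f)
  expect_error(read_genome(f), "duplicate")

  writeLines(c(">a", "ACGRT"), f)
  expect_error(read_genome(f), "position 4")
})

test_that("fixture genome matches its manifest contig inventory", {
  fix <- generate_fixture(fixture_spec(seed = 1))
  ## main contig plus one mitochondrial contig
  expect_equal(length(fix$genome$records), 2L)
  expect_setequal(names(fix$genome$records), c("chrA", "mito"))
  expect_equal(fix$genome$circular, "mito")
})

test_that("GFF3 coordinates convert to zero-based half-open", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t30\t.\t+\t.\tID=gA",
               "chr1\t.\tmRNA\t1\t30\t.\t+\t.\tID=t1;Parent=gA",
               "chr1\t.\texon\t10\t20\t.\t+\t.\tParent=t1"), f)
  set <- read_annotation(f)
  ex <- set$transcripts[["t1"]]$exons[[1]]
  expect_equal(ex$start, 9L)
  expect_equal(ex$end, 20L)
})

test_that("a dicistronic mRNA reads as one transcript owning two genes", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t60\t.\t+\t.\tID=gA",
               "chr1\t.\tgene\t1\t60\t.\t+\t.\tID=gB",
               "chr1\t.\tmRNA\t1\t60\t.\t+\t.\tID=t1;Parent=gA,gB",
               "chr1\t.\texon\t1\t60\t.\t+\t.\tParent=t1",
               "chr1\t.\tCDS\t4\t12\t.\t+\t0\tParent=t1;gene=gA",
               "chr1\t.\tCDS\t31\t39\t.\t+\t0\tParent=t1;gene=gB"), f)
  set <- read_annotation(f)
  t1 <- set$transcripts[["t1"]]
  expect_equal(t1$gene_ids, c("gA", "gB"))
  expect_length(t1$orfs, 2L)
  expect_equal(vapply(t1$orfs, `[[`, character(1), "gene_id"), c("gA", "gB"))
})

test_that("annotation reading rejects inconsistent input", {
  f <- withr::local_tempfile(fileext = ".gff3")
  ## mRNA naming an undeclared parent gene
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t30\t.\t+\t.\tID=gA",
               "chr1\t.\tmRNA\t1\t30\t.\t+\t.\tID=t1;Parent=gA,gZ",
               "chr1\t.\texon\t1\t30\t.\t+\t.\tParent=t1"), f)
  expect_error(read_annotation(f), "undeclared gene")
  ## unknown exception token
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t30\t.\t+\t.\tID=gA",
               "chr1\t.\tmRNA\t1\t30\t.\t+\t.\tID=t1;Parent=gA;flags=wibble",
               "chr1\t.\texon\t1\t30\t.\t+\t.\tParent=t1"), f)
  expect_error(read_annotation(f), "unknown exception token")
  ## CDS outside the exon union
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t30\t.\t+\t.\tID=gA",
               "chr1\t.\tmRNA\t1\t30\t.\t+\t.\tID=t1;Parent=gA",
               "chr1\t.\texon\t1\t20\t.\t+\t.\tParent=t1",
               "chr1\t.\tCDS\t10\t24\t.\t+\t0\tParent=t1;gene=gA"), f)
  expect_error(read_annotation(f), "outside the exon union")
})

test_that("write/read round-trip is the identity on a full fixture", {
  fix <- generate_fixture(fixture_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(fix$set, f)
  expect_identical(read_annotation(f), fix$set)
})

test_that("spliced sequence is strand-aware and excises introns", {
  g <- toy_genome("ATGTAA")
  t <- transcript_model("t", "g", list(g_interval("chr1", 0, 6, "+")))
  expect_equal(spliced_sequence(t, g), "ATGTAA")

  g2 <- toy_genome("ATG")
  t2 <- transcript_model("t", "g", list(g_interval("chr1", 0, 3, "-")))
  expect_equal(spliced_sequence(t2, g2), "CAT")

  ## two exons around a known intron
  g3 <- toy_genome("ATGGTNNNAGTAA")
  t3 <- transcript_model("t", "g", list(g_interval("chr1", 0, 3, "+"),
                                        g_interval("chr1", 10, 13, "+")))
  expect_equal(spliced_sequence(t3, g3), "ATGTAA")
  ## exon beyond the contig end errors on a linear contig
  bad <- transcript_model("t", "g", list(g_interval("chr1", 10, 20, "+")))
  expect_error(spliced_sequence(bad, g3), "beyond")
})

test_that("exon lengths always sum to the spliced-sequence length", {
  fix <- generate_fixture(fixture_spec(seed = 2))
  for (t in fix$set$transcripts) {
    expect_equal(sum(vapply(t$exons, function(e) e$end - e$start, integer(1))),
                 nchar(spliced_sequence(t, fix$genome)))
  }
})

test_that("intron boundaries read on the transcript strand", {
  g <- toy_genome("ATGGTCCCAGTAA")
  t <- transcript_model("t", "g", list(g_interval("chr1", 0, 3, "+"),
                                       g_interval("chr1", 10, 13, "+")))
  ir <- introns_of(t, g)
  expect_length(ir, 1L)
  expect_equal(ir[[1]]$donor, "GT")
  expect_equal(ir[[1]]$acceptor, "AG")
  expect_equal(ir[[1]]$interval$start, 3L)
  expect_equal(ir[[1]]$interval$end, 10L)
})

test_that("introns are strand-symmetric under reverse complement", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60L
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    g <- toy_genome(seq)
    t <- transcript_model("t", "g", list(g_interval("chr1", 0, 10, "+"),
                                         g_interval("chr1", 30, 40, "+")))
    fwd <- introns_of(t, g)
    ## reverse-complement the contig and flip all coordinates/strands
    grc <- toy_genome(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq))))
    trc <- transcript_model("t", "g",
      list(g_interval("chr1", n - 10, n, "-"),
           g_interval("chr1", n - 40, n - 30, "-")))
    rev <- introns_of(trc, grc)
    expect_equal(rev[[1]]$donor, fwd[[1]]$donor)
    expect_equal(rev[[1]]$acceptor, fwd[[1]]$acceptor)
  }
})

test_that("the endonuclease-processed intron fixture is 23 nt with CA-TG ends", {
  fix <- generate_fixture(fixture_spec(seed = 1))
  hac <- Filter(function(m) m$category == "hac1", fix$manifest)[[1]]
  tid <- hac$transcripts[1]
  ir <- introns_of(fix$set$transcripts[[tid]], fix$genome)
  expect_length(ir, 1L)
  expect_equal(ir[[1]]$donor, "CA")
  expect_equal(ir[[1]]$acceptor, "TG")
  expect_equal(ir[[1]]$interval$end - ir[[1]]$interval$start, 23L)
})

test_that("trans-splicing is opt-in and skips cross-strand gaps", {
  exons <- list(g_interval("chr1", 0, 10, "+"), g_interval("chr1", 30, 40, "-"))
  expect_error(transcript_model("t", "g", exons),
               "trans_spliced_transcript")
  t <- transcript_model("t", "g", exons,
                        declared_flags = "trans_spliced_transcript")
  g <- toy_genome(strrep("A", 50))
  ir <- introns_of(t, g)
  expect_length(ir, 0L)
  expect_equal(attr(ir, "skipped_gaps"), 1L)
})

test_that("very short introns are rejected", {
  g <- toy_genome("ATGGTAGTAAAAA")
  t <- transcript_model("t", "g", list(g_interval("chr1", 0, 3, "+"),
                                       g_interval("chr1", 6, 9, "+")))
  expect_error(introns_of(t, g), "shorter than 4")
})
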