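test_that("genetic code tables carry the expected recodings", {
  std <- genetic_code("standard")
  expect_true("TGA" %in% std$stops)
  mito <- genetic_code("invertebrate_mitochondrial")
  expect_equal(unname(mito$table["TGA"]), "W")
  expect_equal(unname(mito$table["ATA"]), "M")
  expect_equal(unname(mito$table["AGA"]), "S")
  expect_false("TGA" %in% mito$stops)
  expect_equal(unname(std$table["ATG"]), "M")
  expect_equal(unname(mito$table["ATG"]), "M")
  expect_error(genetic_code("martian"), "unknown genetic code")
})

test_that("worked translation-exception examples give the expected peptides", {
  run <- function(cds, ...) {
    w <- toy_coding_transcript(cds, ...)
    translate_orf(w$transcript$orfs[[1]], w$transcript, w$genome)
  }
  expect_equal(run("ATGGCTTAA")$peptide, "MA")
  expect_equal(run("CTGGCTTAA", start_codon_kind = "CTG")$peptide, "MA")
  expect_equal(run("ATGTGAGCTTAA", readthrough_positions = 2)$peptide, "MXA")
  expect_equal(run("ATGTGATAA", selenocysteine_positions = 2)$peptide, "MU")
  dbl <- run("ATGTGAGCTTAGGCTTAA", readthrough_positions = c(2, 4))
  expect_equal(dbl$peptide, "MXAXA")
  expect_equal(sum(dbl$events$type == "stop_codon_read_through"), 2L)
})

test_that("the +1 frameshift reframes the coding sequence", {
  expect_equal(apply_frameshift("ATGAAACGGTTAG",
                                list(codon_index = 2, shift = 1)),
               "ATGAAAGGTTAG")
  w <- toy_coding_transcript("ATGAAACGGTTAG",
                             frameshift = list(codon_index = 2, shift = 1))
  expect_equal(translate_orf(w$transcript$orfs[[1]], w$transcript,
                             w$genome)$peptide, "MKG")
  expect_equal(apply_frameshift("ATGTAA", NULL), "ATGTAA")
  expect_error(apply_frameshift("ATGTAA", list(codon_index = 2, shift = 1)),
               "no sequence to resume")
  expect_error(apply_frameshift("ATGAAACGGTTAG",
                                list(codon_index = 2, shift = 2)),
               "\\+1")
})

test_that("incomplete stop codons complete to TAA by polyadenylation only", {
  expect_equal(complete_incomplete_stop("ATGAAAT")$cds, "ATGAAATAA")
  expect_equal(complete_incomplete_stop("ATGAAATA")$cds, "ATGAAATAA")
  expect_error(complete_incomplete_stop("ATGAAAGG"), "cannot be completed")
  expect_error(complete_incomplete_stop("ATGTAA"), "multiple of 3")
})

test_that("a mitochondrial ORF translates under table 5 with stop completion", {
  w <- toy_coding_transcript("ATGATATGAAGAT", incomplete_stop = TRUE,
                             genetic_code = "invertebrate_mitochondrial")
  res <- translate_orf(w$transcript$orfs[[1]], w$transcript, w$genome)
  expect_equal(res$peptide, "MMWS")   # ATA->M, TGA->W, AGA->S
  expect_true(res$completed_stop)
})

test_that("annotation inconsistencies are rejected with codon positions", {
  w <- toy_coding_transcript("ATGTGAGCTTAA")  # undeclared internal stop
  expect_error(translate_orf(w$transcript$orfs[[1]], w$transcript, w$genome),
               "codon 2")
  w2 <- toy_coding_transcript("ATGGCTGCTTAA", readthrough_positions = 2)
  expect_error(translate_orf(w2$transcript$orfs[[1]], w2$transcript,
                             w2$genome), "not a stop codon")
  ## declared non-AUG start must match the genomic codon
  w3 <- toy_coding_transcript("ATGGCTTAA", start_codon_kind = "CTG")
  expect_error(translate_orf(w3$transcript$orfs[[1]], w3$transcript,
                             w3$genome), "does not match")
})

test_that("undetermined starts translate as annotated and record the caveat", {
  w <- toy_coding_transcript("GTTGCTTAA", start_codon_kind = "undetermined")
  res <- translate_orf(w$transcript$orfs[[1]], w$transcript, w$genome)
  expect_equal(res$peptide, "VA")
  expect_true("start_codon_not_determined" %in% res$events$type)
})

test_that("codons containing N translate to X", {
  g <- genome_seq(c(chr1 = "ATGGNTTAA"))
  t <- transcript_model("t", "g", list(g_interval("chr1", 0, 9, "+")),
                        list(orf_annotation("g",
                          list(g_interval("chr1", 0, 9, "+")))))
  expect_equal(translate_orf(t$orfs[[1]], t, g)$peptide, "MX")
})

test_that("exception-free translation agrees with an independent oracle", {
  set.seed(99)
  for (rep in 1:200) {
    cds <- random_orf_cds(sample(5:60, 1))
    w <- toy_coding_transcript(cds, utr5 = "ACGT", utr3 = "AA")
    got <- translate_orf(w$transcript$orfs[[1]], w$transcript, w$genome)
    expect_identical(got$peptide, oracle_translate(cds))
  }
})

test_that("peptide length bookkeeping holds across fixture exceptions", {
  fix <- generate_fixture(fixture_spec(seed = 8))
  aud <- audit_annotation(fix$set, fix$genome)
  for (tid in names(fix$set$transcripts)) {
    for (o in fix$set$transcripts[[tid]]$orfs) {
      res <- aud$translations[[paste0(tid, ":", o$gene_id)]]
      len <- sum(vapply(o$cds_segments, function(s) s$end - s$start,
                        integer(1)))
      if (!is.null(o$frameshift)) len <- len - 1L
      if (o$incomplete_stop) len <- len + (3L - len %% 3L)
      expect_equal(nchar(res$peptide), (len - 3L) %/% 3L)
      ## U and X appear exactly at declared positions
      expect_equal(which(strsplit(res$peptide, "")[[1]] == "U"),
                   o$selenocysteine_positions)
      expect_equal(which(strsplit(res$peptide, "")[[1]] == "X"),
                   o$readthrough_positions)
    }
  }
})

test_that("readthrough extension candidates find the next in-frame stop", {
  ## CDS ends at a stop; next in-frame stop lies 3 codons later
  g <- toy_genome(paste0("ATGGCTTAA", "GCTGCTGCA", "TAG", strrep("C", 20)))
  t <- transcript_model("t", "g", list(g_interval("chr1", 0, 40, "+")),
                        list(orf_annotation("g",
                          list(g_interval("chr1", 0, 9, "+")))))
  expect_equal(readthrough_extension_candidate(t$orfs[[1]], t, g), 3L)
})
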