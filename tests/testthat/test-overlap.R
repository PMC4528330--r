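orf_at <- function(spans, gene = "gA", strand = "+") {
  orf_annotation(gene, lapply(spans, function(sp)
    g_interval("chr1", sp[1], sp[2], strand)))
}

test_that("codon offsets track the spliced CDS across introns and strands", {
  m <- codon_offset_map(orf_at(list(c(0, 6))))
  expect_equal(m$pos, 0:5)
  expect_equal(m$offset, c(0L, 1L, 2L, 0L, 1L, 2L))

  ## two-exon CDS split mid-codon: offsets continue across the intron
  m2 <- codon_offset_map(orf_at(list(c(0, 4), c(10, 15))))
  expect_equal(m2$pos, c(0:3, 10:14))
  expect_equal(m2$offset, c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L))

  ## minus strand: offsets increase 5'->3', i.e. with decreasing coordinate
  m3 <- codon_offset_map(orf_at(list(c(0, 6)), strand = "-"))
  expect_equal(m3$pos, 5:0)
  expect_equal(m3$offset, c(0L, 1L, 2L, 0L, 1L, 2L))
})

test_that("multiphasic regions are frame conflicts only, symmetric in inputs", {
  a <- orf_at(list(c(0, 60)))
  expect_length(multiphasic_regions(a, a), 0L)

  b <- orf_at(list(c(20, 80)), gene = "gB")   # 20 = 2 mod 3: frames differ
  r <- multiphasic_regions(a, b)
  expect_length(r, 1L)
  expect_equal(r[[1]]$length_nt, 40L)
  expect_equal(r[[1]]$interval$start, 20L)
  expect_true(r[[1]]$cross_gene)
  r2 <- multiphasic_regions(b, a)
  expect_equal(r2[[1]]$interval, r[[1]]$interval)

  same_frame <- orf_at(list(c(21, 81)), gene = "gB")  # 21 = 0 mod 3
  expect_length(multiphasic_regions(a, same_frame), 0L)

  minus <- orf_at(list(c(20, 80)), gene = "gB", strand = "-")
  expect_error(multiphasic_regions(a, minus), "opposite strands")
})

test_that("the planted within-gene multiphasic region is recovered exactly", {
  fix <- generate_fixture(fixture_spec(seed = 1))
  m <- Filter(function(x) x$category == "multiphasic_short", fix$manifest)[[1]]
  orfs <- lapply(m$transcripts, function(tid)
    fix$set$transcripts[[tid]]$orfs[[1]])
  r <- multiphasic_regions(orfs[[1]], orfs[[2]])
  expect_length(r, 1L)
  expect_equal(r[[1]]$length_nt, 30L)
  expect_true(r[[1]]$includes_stop)
  expect_false(r[[1]]$cross_gene)
  expect_false(r[[1]]$involves_first_coding_exon)
})

test_that("multiphasic classification follows the 40/63 nt rules", {
  mk <- function(len, cross = FALSE, first = FALSE, stop = TRUE)
    structure(list(interval = g_interval("chr1", 100, 100 + len, "+"),
                   length_nt = len, members = c("a", "b"),
                   involves_first_coding_exon = first, cross_gene = cross,
                   includes_stop = stop), class = "multiphasic_region")
  short <- classify_multiphasic(mk(30))
  expect_match(short$comment, "^Alternative translation stop")
  expect_false(short$long_overlap)

  long <- classify_multiphasic(mk(80))
  expect_match(long$comment, "^Multiphase exon postulated: exon reading frame")
  expect_true(long$long_overlap)

  cross <- classify_multiphasic(mk(553, cross = TRUE))
  expect_match(cross$comment, "overlapping gene")
  expect_true(cross$long_overlap)

  ## first-coding-exon involvement takes precedence over the short rule
  first <- classify_multiphasic(mk(30, first = TRUE))
  expect_match(first$comment, "first coding exon")

  ## 63 nt itself is not a long overlap
  expect_false(classify_multiphasic(mk(63))$long_overlap)
})

test_that("the 40-nt multiphasic rule implies a strict 13-aa bound", {
  expect_equal(multiphasic_aa_bound(40L), 13L)
  max_aa <- function(nt) (nt - 3L) %/% 3L   # stop codon included in extent
  expect_true(all(vapply(4:39, max_aa, integer(1)) < 13L))
  expect_false(max_aa(42L) < 13L)
})

test_that("bidirectional detection needs opposite strands and shared bases", {
  plus <- orf_at(list(c(0, 60)))
  minus_far <- orf_at(list(c(100, 160)), gene = "gB", strand = "-")
  expect_null(detect_bidirectional(plus, minus_far))

  minus <- orf_at(list(c(10, 100)), gene = "gB", strand = "-")
  bd <- detect_bidirectional(plus, minus)
  expect_equal(bd$length_nt, 50L)
  expect_match(bd$comment, "^Bidirectional region")

  abutting <- orf_at(list(c(60, 120)), gene = "gB", strand = "-")
  expect_null(detect_bidirectional(plus, abutting))

  expect_error(detect_bidirectional(plus, orf_at(list(c(10, 100)), "gB")),
               "same strand")
})

test_that("same-frame CDS overlap reports in-frame runs only", {
  t1 <- transcript_model("t1", "gA", list(g_interval("chr1", 0, 400, "+")),
    list(orf_at(list(c(6, 306)))))
  t2 <- transcript_model("t2", "gB", list(g_interval("chr1", 0, 500, "+")),
    list(orf_at(list(c(6, 246), c(310, 370)), gene = "gB")))
  set <- annotation_set(list(t1, t2))
  sf <- detect_cds_overlap_same_frame("gA", "gB", set)
  expect_equal(sf$length_nt, 240L)
  expect_match(sf$comment, "^Genes with CDS overlap")

  ## different frames route to multiphasic, not same-frame
  t3 <- transcript_model("t3", "gC", list(g_interval("chr1", 0, 400, "+")),
    list(orf_at(list(c(7, 307)), gene = "gC")))
  set2 <- annotation_set(list(t1, t3))
  expect_null(detect_cds_overlap_same_frame("gA", "gC", set2))
})

test_that("every shared coding base is same-frame xor multiphasic", {
  set.seed(11)
  for (rep in 1:20) {
    s1 <- sample(0:20, 1) * 3 + 6
    s2 <- sample(0:40, 1) + 6
    a <- orf_at(list(c(s1, s1 + 90)))
    b <- orf_at(list(c(s2, s2 + 90)), gene = "gB")
    shared <- intersect(codon_offset_map(a)$pos, codon_offset_map(b)$pos)
    mp <- unlist(lapply(multiphasic_regions(a, b), function(r)
      seq.int(r$interval$start, r$interval$end - 1L)))
    set <- annotation_set(list(
      transcript_model("t1", "gA", list(g_interval("chr1", 0, 200, "+")),
                       list(a)),
      transcript_model("t2", "gB", list(g_interval("chr1", 0, 200, "+")),
                       list(b))))
    sf <- detect_cds_overlap_same_frame("gA", "gB", set)
    sfpos <- if (is.null(sf)) integer() else
      unlist(lapply(sf$regions, function(r) seq.int(r$start, r$end - 1L)))
    expect_setequal(c(mp, sfpos), shared)
    expect_length(intersect(mp, sfpos), 0L)
  }
})

test_that("noncoding overlap categories classify shared terminal exons", {
  fix <- generate_fixture(fixture_spec(seed = 1))
  m5 <- Filter(function(x) x$category == "shared_5", fix$manifest)[[1]]
  call5 <- classify_noncoding_overlap(m5$genes[1], m5$genes[2], fix$set)
  expect_equal(call5$category, "shared_5_exons")
  expect_equal(call5$comment, "Shares 5\u2032 exon(s)")

  m3 <- Filter(function(x) x$category == "shared_3", fix$manifest)[[1]]
  call3 <- classify_noncoding_overlap(m3$genes[1], m3$genes[2], fix$set)
  expect_equal(call3$category, "shared_3_utr")
  expect_equal(call3$comment, "Shares 3\u2032 UTR")
})

test_that("a gene nested in an intron on the same strand is left unflagged", {
  outer <- transcript_model("to", "gOut",
    list(g_interval("chr1", 0, 50, "+"), g_interval("chr1", 200, 260, "+")),
    list(orf_annotation("gOut", list(g_interval("chr1", 6, 48, "+"),
                                     g_interval("chr1", 200, 245, "+")))))
  inner <- transcript_model("ti", "gIn",
    list(g_interval("chr1", 80, 150, "+")),
    list(orf_annotation("gIn", list(g_interval("chr1", 90, 135, "+")))))
  set <- annotation_set(list(outer, inner))
  call <- classify_noncoding_overlap("gOut", "gIn", set)
  expect_equal(call$category, "nested_unflagged")
  expect_true(is.na(call$comment))
})
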