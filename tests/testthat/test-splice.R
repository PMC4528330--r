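mk_intron <- function(donor, acceptor, start = 100L, end = 160L,
                      strand = "+", tids = "t1") {
  structure(list(interval = g_interval("chrA", start, end, strand),
                 donor = donor, acceptor = acceptor, transcript_ids = tids,
                 classification = character()), class = "intron_record")
}

test_that("candidate noncanonical pairs equal the exhaustive oracle", {
  got <- enumerate_candidate_noncanonical_pairs()
  expect_length(got, 8L)
  expect_false(any(c("GT-AG", "GC-AG") %in% got))
  expect_identical(got, brute_force_candidate_pairs())
})

test_that("intron classification covers canonical, candidate and gated classes", {
  expect_equal(classify_intron(mk_intron("GT", "AG")), "canonical_GT_AG")
  expect_equal(classify_intron(mk_intron("GC", "AG")), "canonical_GC_AG")
  expect_equal(classify_intron(mk_intron("GT", "AT")), "noncanonical:GT-AT")
  expect_equal(classify_intron(mk_intron("AT", "AC")), "noncanonical_AT_AC")
  expect_equal(classify_intron(mk_intron("CA", "TG"),
                               "endonuclease_spliced_intron"),
               "endonuclease_spliced")
  expect_equal(classify_intron(mk_intron("CA", "TG")), "other_nonconforming")
  expect_equal(classify_intron(mk_intron("CA", "TG"),
                               "genomic sequence error or gap"),
               "convenience")
  ## every noncanonical:<pair> label carries a pair from the candidate set
  for (p in enumerate_candidate_noncanonical_pairs()) {
    cls <- classify_intron(mk_intron(substr(p, 1, 2), substr(p, 4, 5)))
    expect_equal(cls, paste0("noncanonical:", p))
  }
})

test_that("U12 tagging matches the configured 5' consensus", {
  g <- toy_genome(paste0(strrep("C", 100), "GTATCCTTAAACCCCCCAG",
                         strrep("C", 50)), seqid = "chrA")
  i <- mk_intron("GT", "AG", 100L, 119L)
  expect_true(tag_u12(i, g))

  g2 <- toy_genome(paste0(strrep("C", 100), "GTAAGTTTAAACCCCCCAG",
                          strrep("C", 50)), seqid = "chrA")
  expect_false(tag_u12(i, g2))

  g3 <- toy_genome(paste0(strrep("C", 100), "ATATCCTTAAACCCCCCAC",
                          strrep("C", 50)), seqid = "chrA")
  i3 <- mk_intron("AT", "AC", 100L, 119L)
  expect_true(tag_u12(i3, g3))
  expect_equal(classify_intron(i3), "noncanonical_AT_AC")
})

test_that("similar alternative splice shares one boundary, upstream on ties", {
  ## gene with a noncanonical intron and canonical alternatives around it
  mkgene <- function(acceptors) {
    seqlen <- 400L
    s <- rep("C", seqlen)
    s[101:102] <- c("G", "T")
    for (a in acceptors) s[(a - 1L):a] <- c("A", "G")
    s[199:200] <- c("T", "G")   # the noncanonical acceptor (TG) at [198,200)
    g <- toy_genome(paste(s, collapse = ""), seqid = "chrA")
    trs <- list(transcript_model("t0", "gA",
      list(g_interval("chrA", 0, 100, "+"),
           g_interval("chrA", 200, 240, "+"))))
    for (k in seq_along(acceptors)) {
      trs[[k + 1L]] <- transcript_model(paste0("t", k), "gA",
        list(g_interval("chrA", 0, 100, "+"),
             g_interval("chrA", acceptors[k], acceptors[k] + 40L, "+")))
    }
    list(g = g, set = annotation_set(trs))
  }
  ## one canonical acceptor 4 nt before the noncanonical one
  w <- mkgene(196L)
  i <- introns_of(w$set$transcripts[["t0"]], w$g)[[1]]
  expect_equal(classify_intron(i), "noncanonical:GT-TG")
  alt <- similar_alternative_splice(i, w$set, w$g)
  expect_equal(alt$interval$end, 196L)
  expect_equal(alt$acceptor, "AG")

  ## equidistant alternatives: the upstream one wins
  w2 <- mkgene(c(196L, 204L))
  i2 <- introns_of(w2$set$transcripts[["t0"]], w2$g)[[1]]
  alt2 <- similar_alternative_splice(i2, w2$set, w2$g)
  expect_equal(alt2$interval$end, 196L)

  ## single-intron gene with no alternative
  w3 <- mkgene(integer())
  i3 <- introns_of(w3$set$transcripts[["t0"]], w3$g)[[1]]
  expect_null(similar_alternative_splice(i3, w3$set, w3$g))
})

test_that("junction audits recognize the artifact classes", {
  fix <- generate_fixture(fixture_spec(seed = 1))
  aud <- audit_annotation(fix$set, fix$genome, junctions = fix$junctions)
  jt <- aud$junction_table
  expect_equal(jt$verdict[jt$name == "jx_GTAT_main"], "matches_annotated")
  expect_equal(jt$offset[jt$name == "jx_GTAT_main"], 0L)
  expect_equal(jt$verdict[jt$name == "jx_stripped"], "strand_flip_gt_at")
  expect_equal(jt$verdict[jt$name == "jx_offbyone"], "off_by_one_artifact")
  expect_equal(jt$verdict[jt$name == "jx_lowfreq"], "low_frequency")
  expect_equal(jt$verdict[jt$name == "jx_far"], "unsupported_noncanonical")
  ## offset is 0 exactly for coordinate-true matches
  expect_equal(jt$verdict == "matches_annotated",
               !is.na(jt$offset) & jt$offset == 0L)
})

test_that("BED junctions round-trip through the documented dialect", {
  fix <- generate_fixture(fixture_spec(seed = 4))
  td <- withr::local_tempdir()
  write_fixture(fix, td)
  jx <- read_junctions(file.path(td, "junctions.bed"))
  expect_length(jx, length(fix$junctions))
  for (k in seq_along(jx)) {
    expect_equal(jx[[k]]$interval$start, fix$junctions[[k]]$interval$start)
    expect_equal(jx[[k]]$interval$end, fix$junctions[[k]]$interval$end)
    expect_equal(jx[[k]]$stranded, fix$junctions[[k]]$stranded)
    expect_equal(jx[[k]]$read_count, fix$junctions[[k]]$read_count)
  }
})

test_that("the census total row equals its column sums, always", {
  fix <- generate_fixture(fixture_spec(seed = 6))
  cen <- audit_annotation(fix$set, fix$genome,
                          junctions = fix$junctions)$census
  main <- cen[cen$pair %in% setdiff(cen$pair, c("Total", "GT-AG (U12)",
                                                "GC-AG (U12)")), ]
  tot <- cen[cen$pair == "Total", ]
  for (col in names(cen)[-1])
    expect_equal(tot[[col]], sum(main[[col]], na.rm = TRUE))
  ## planted noncanonical introns all appear with junction support
  expect_equal(tot$n_introns, 10L)          # 8 candidate pairs + 2 AT-AC
  expect_equal(tot$n_junction_support, 10L)
  ## GT-donor pairs have a similar alternative; GA/GG/AT donors do not
  expect_equal(cen$n_similar_alternative[cen$pair == "GT-TG"], 1L)
  expect_equal(cen$n_similar_alternative[cen$pair == "GA-AG"], 0L)
  expect_equal(cen$n_introns[cen$pair == "AT-AC (U12)"], 1L)
  expect_equal(cen$n_introns[cen$pair == "AT-AC (U2)"], 1L)
  expect_equal(cen$n_introns[cen$pair == "GT-AG (U12)"], 1L)
})

test_that("an empty annotation yields an all-zero census", {
  cen <- splice_summary(annotation_set(list()),
                        toy_genome("ACGTACGT", seqid = "chrA"))
  expect_true(all(cen$n_introns == 0L))
  expect_equal(cen$n_introns[cen$pair == "Total"], 0L)
})
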