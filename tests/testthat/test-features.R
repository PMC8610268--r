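test_that("the MD caller reproduces hand-traced mismatches including the leading-zero dialect", {
  # perfect match
  expect_equal(nrow(call_md_variants("150", "150M", strrep("A", 150), 0)), 0L)
  # single mismatch at offset 10, alignment starting at 100
  seq1 <- paste0(strrep("T", 10), "G", strrep("T", 139))
  v1 <- call_md_variants("10A139", "150M", seq1, 100)
  expect_equal(v1, data.frame(position = 110L, ref = "A", alt = "G",
                              stringsAsFactors = FALSE))
  # two leading mismatches, leading-zero MD form
  seq2 <- paste0("GA", strrep("T", 148))
  v2 <- call_md_variants("0C0T148", "150M", seq2, 0)
  expect_equal(v2$position, c(0L, 1L))
  expect_equal(v2$ref, c("C", "T"))
  expect_equal(v2$alt, c("G", "A"))
  # MD/CIGAR length disagreement is a hard error
  expect_error(call_md_variants("140", "150M", strrep("A", 150), 0),
               "inconsistent")
  expect_error(call_md_variants("10A145", "150M", strrep("G", 150), 0),
               "inconsistent")
})

test_that("the MD caller matches an independent construction oracle over randomized gapped alignments", {
  set.seed(2024)
  for (i in 1:400) {
    a <- random_alignment()
    got <- call_md_variants(a$md, a$cigar, a$seq, a$start)
    expect_equal(got$position, a$expected$position,
                 info = paste("MD:", a$md, "CIGAR:", a$cigar))
    expect_equal(got$ref, a$expected$ref)
    expect_equal(got$alt, a$expected$alt)
  }
})

test_that("the LD fragment score is neutral below two variants and the minimum pairwise r2 above", {
  ld <- make_ld(data.frame(
    pos_i = c(10L, 10L, 20L), alt_i = c("A", "A", "G"),
    pos_j = c(20L, 30L, 30L), alt_j = c("G", "T", "T"),
    r2 = c(0.9, 0.8, 0.1), stringsAsFactors = FALSE))
  no_vars <- data.frame(position = integer(0), alt = character(0))
  expect_equal(ld_fragment_score(no_vars, ld), 1.0)
  one <- data.frame(position = 10L, alt = "A")
  expect_equal(ld_fragment_score(one, ld), 1.0)
  two_perfect <- data.frame(position = c(10L, 20L), alt = c("A", "G"))
  ld1 <- make_ld(data.frame(pos_i = 10L, alt_i = "A", pos_j = 20L,
                            alt_j = "G", r2 = 1.0))
  expect_equal(ld_fragment_score(two_perfect, ld1), 1.0)
  three <- data.frame(position = c(10L, 20L, 30L), alt = c("A", "G", "T"))
  expect_equal(ld_fragment_score(three, ld), 0.1)  # min over {0.9, 0.8, 0.1}
  # duplicated variant across mates counts once
  dup <- rbind(two_perfect, two_perfect[1, ])
  expect_equal(ld_fragment_score(dup, ld1), 1.0)
  # unseen pair takes the configured unseen score
  unseen <- data.frame(position = c(10L, 99L), alt = c("A", "A"))
  expect_equal(ld_fragment_score(unseen, ld, unseen_score = 0), 0)
  expect_equal(ld_fragment_score(unseen, ld, unseen_score = 0.5), 0.5)
})

test_that("NUMT overlap fractions match the interval-union oracle and its invariances", {
  frag <- data.frame(start = 0L, end = 300L)
  none <- data.frame(start = 500L, end = 900L)
  expect_equal(numt_overlap_fraction(frag, none), 0.0)
  inside <- data.frame(start = 100L, end = 200L)
  big <- data.frame(start = 0L, end = 500L)
  expect_equal(numt_overlap_fraction(inside, big), 1.0)
  two <- data.frame(start = c(250L, 280L), end = c(400L, 320L))
  expect_equal(numt_overlap_fraction(frag, two), 50 / 300)
  # splitting a NUMT into adjacent pieces changes nothing
  split2 <- data.frame(start = c(250L, 300L, 280L), end = c(300L, 400L, 320L))
  expect_equal(numt_overlap_fraction(frag, split2),
               numt_overlap_fraction(frag, two))
  # fragment sub-interval order is irrelevant (circular-origin case)
  fragAB <- data.frame(start = c(2900L, 0L), end = c(3000L, 100L))
  fragBA <- fragAB[2:1, ]
  numts <- data.frame(start = 2950L, end = 3000L)
  expect_equal(numt_overlap_fraction(fragAB, numts),
               numt_overlap_fraction(fragBA, numts))
  expect_equal(numt_overlap_fraction(fragAB, numts), 50 / 200)
  expect_error(numt_overlap_fraction(data.frame(start = integer(0),
                                                end = integer(0)), big),
               "empty fragment")
})

test_that("featurize produces the expected vector for a clean mtDNA-only pair", {
  recs <- rbind(
    sam_record("r1", 100L, strrep("A", 150), md = "150", flag = 99L),
    sam_record("r1", 300L, strrep("A", 150), md = "150", flag = 147L))
  sam <- write_sam_bam(recs, c(chrM = 3000L))
  ld <- make_ld(data.frame(pos_i = integer(0), alt_i = character(0),
                           pos_j = integer(0), alt_j = character(0),
                           r2 = numeric(0)))
  fxv <- featurize(load_pairs(sam), ld, numts = NULL)
  expect_equal(fxv$mt_edit_distance, 0)
  expect_equal(fxv$nuc_edit_distance, 300)   # read-pair-length sentinel
  expect_equal(fxv$nuc_alignments, 0L)
  expect_equal(fxv$mt_ld, 1.0)
  expect_equal(fxv$numt_overlap, 0)
})

test_that("feature distributions on simulator output separate the classes as planted", {
  fx <- shared_fixture()
  pairs <- load_pairs(fx$mix$mt_sam, fx$mix$nuc_sam)
  labels <- setNames(fx$mix$truth$label, fx$mix$truth$read_id)
  feats <- featurize(pairs, fx$ld, fx$numt_bed, labels = labels)
  expect_equal(nrow(feats), nrow(fx$mix$truth))
  is_numt <- feats$label == "NUMT"
  # NUMT divergence (10%) far exceeds the sequencing error rate
  expect_gt(mean(feats$mt_edit_distance[is_numt]),
            mean(feats$mt_edit_distance[!is_numt]))
  expect_lt(mean(feats$nuc_edit_distance[is_numt]),
            mean(feats$nuc_edit_distance[!is_numt]))
  expect_true(all(feats$numt_overlap[is_numt] == 1))
  expect_true(all(feats$mt_ld >= 0 & feats$mt_ld <= 1))
  expect_true(all(is.finite(as.matrix(feats[, final_model_features()]))))
})

test_that("multiple nuclear hits collapse to the best (minimum) nuclear edit distance", {
  recs <- sam_record("r1", 100L, strrep("A", 100), flag = 99L)
  mt_sam <- write_sam_bam(recs, c(chrM = 3000L))
  nuc <- rbind(
    sam_record("r1", 10L, strrep("A", 100), rname = "chr1", nm = 7L,
               md = "x", nh = 2L),
    sam_record("r1", 900L, strrep("A", 100), rname = "chr1", nm = 2L,
               md = "x", nh = 2L, flag = 256L))
  nuc$md <- NULL  # rely on NM tags only
  nuc_sam <- write_sam_bam(nuc, c(chr1 = 5000L))
  ld <- make_ld(data.frame(pos_i = integer(0), alt_i = character(0),
                           pos_j = integer(0), alt_j = character(0),
                           r2 = numeric(0)))
  fxv <- featurize(load_pairs(mt_sam, nuc_sam), ld)
  expect_equal(fxv$nuc_edit_distance, 2)
  expect_equal(fxv$nuc_alignments, 2L)
})
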