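test_that("heteroplasmy error is benchmark minus tool, with absent calls at zero", {
  expect_equal(heteroplasmy_error(0.5, 0.5), 0.0)
  expect_equal(heteroplasmy_error(0.3, 0), 0.3)    # tool missed the variant
  expect_equal(heteroplasmy_error(0.2, 0.45), -0.25)
  # antisymmetry
  for (p in list(c(0.1, 0.9), c(0.5, 0.2), c(0, 1))) {
    expect_equal(heteroplasmy_error(p[1], p[2]),
                 -heteroplasmy_error(p[2], p[1]))
  }
})

test_that("scaled heteroplasmy error divides by p(1-p) and is undefined at the boundaries", {
  expect_equal(scaled_heteroplasmy_error(0.1, 0.5), 0.4)
  expect_equal(scaled_heteroplasmy_error(0, 0.25), 0)
  expect_equal(scaled_heteroplasmy_error(0.09, 0.1), 1.0)
  expect_true(is.na(scaled_heteroplasmy_error(0.2, 0)))
  expect_true(is.na(scaled_heteroplasmy_error(0.2, 1)))
})

test_that("the tolerance rule reproduces the worked match/false-negative/false-positive boundaries", {
  expect_equal(classify_variant(0.5, 0.31), "match")
  expect_equal(classify_variant(0.5, 0.29), "false_negative")
  expect_equal(classify_variant(0.0, 0.25), "false_positive")
  expect_equal(classify_variant(0.0, 0.20), "match")
  expect_equal(classify_variant(0.5, 0.30), "match")  # boundary inclusive
  # exhaustive and mutually exclusive over a grid
  g <- expand.grid(b = seq(0, 1, 0.05), t = seq(0, 1, 0.05))
  cls <- classify_variant(g$b, g$t)
  expect_true(all(cls %in% c("match", "false_negative", "false_positive")))
  fn <- g$t < g$b - 0.2; fp <- g$t > g$b + 0.2
  expect_equal(cls == "false_negative", fn)
  expect_equal(cls == "false_positive", fp)
})

test_that("minor allele frequency folds heteroplasmy at one half", {
  expect_equal(maf(0.3), 0.3)
  expect_equal(maf(0.7), 0.3)
  expect_equal(maf(0.5), 0.5)
  expect_equal(maf(c(0, 1)), c(0, 0))
  p <- seq(0, 1, 0.01)
  expect_true(all(maf(p) <= 0.5))
})

vs <- function(position, alt, p) {
  data.frame(position = position, alt = alt, heteroplasmy = p,
             stringsAsFactors = FALSE)
}

test_that("comparing a variant set against itself is the zero report", {
  s <- vs(c(100L, 200L, 300L), c("A", "G", "T"), c(0.05, 0.5, 0.95))
  rep0 <- compare_variant_sets(s, s)
  expect_equal(rep0$n_misclassifications, 0L)
  expect_equal(rep0$n_false_positives, 0L)
  expect_equal(rep0$n_false_negatives, 0L)
  expect_equal(rep0$n_homoplasmic_errors, 0L)
  expect_equal(rep0$max_abs_heteroplasmy_error, 0)
})

test_that("the comparison report applies the definitions: missing homoplasmic call, tolerated low-level call, allele mismatch", {
  bench <- vs(c(100L, 200L), c("A", "G"), c(0.9, 0.4))
  tool <- vs(c(200L, 300L), c("G", "T"), c(0.45, 0.15))
  rep <- compare_variant_sets(bench, tool)
  # bench-only homoplasmic variant: FN + homoplasmic error, max error 0.9
  expect_equal(rep$n_false_negatives, 1L)
  expect_equal(rep$n_homoplasmic_errors, 1L)
  expect_equal(rep$max_abs_heteroplasmy_error, 0.9)
  # tool-only low-level call within tolerance is a match
  expect_equal(rep$n_false_positives, 0L)
  expect_equal(rep$n_misclassifications, 1L)
  # a different alternate at the same position is one FN plus one FP
  bench2 <- vs(500L, "A", 0.8)
  tool2 <- vs(500L, "C", 0.8)
  rep2 <- compare_variant_sets(bench2, tool2)
  expect_equal(rep2$n_false_negatives, 1L)
  expect_equal(rep2$n_false_positives, 1L)
  expect_equal(rep2$n_homoplasmic_errors, 2L)
  # misclassification count identity and duplicate-key error
  expect_equal(rep2$n_misclassifications,
               rep2$n_false_positives + rep2$n_false_negatives)
  expect_error(compare_variant_sets(rbind(bench2, bench2), tool2),
               "duplicate")
})

test_that("swapping benchmark and tool exchanges false positives and false negatives", {
  set.seed(4)
  a <- vs(seq(100L, 1000L, 100L), sample(c("A", "C", "G", "T"), 10, TRUE),
          runif(10))
  b <- vs(seq(100L, 1300L, 100L), sample(c("A", "C", "G", "T"), 13, TRUE),
          runif(13))
  r_ab <- compare_variant_sets(a, b)
  r_ba <- compare_variant_sets(b, a)
  expect_equal(r_ab$n_false_positives, r_ba$n_false_negatives)
  expect_equal(r_ab$n_false_negatives, r_ba$n_false_positives)
  expect_equal(r_ab$max_abs_heteroplasmy_error,
               r_ba$max_abs_heteroplasmy_error)
})

test_that("the detection curve counts benchmark variants recoverable at each threshold", {
  bench <- vs(c(10L, 20L, 30L), c("A", "C", "G"), c(0.05, 0.3, 0.8))
  # identical tool set: fully detected everywhere
  full <- detection_curve(bench, bench, thresholds = c(0.01, 0.1, 0.5))
  expect_true(all(full$fraction == 1.0))
  # empty tool set: nothing detected (every variant above tol is an FN);
  # the 0.05 variant is within tolerance of 0 and so never an FN
  none <- detection_curve(bench, bench[0, ], thresholds = c(0.1, 0.5))
  expect_true(all(none$fraction == 0))
  # constructed: tool recovers the 0.3 and 0.8 variants only
  tool <- vs(c(20L, 30L), c("C", "G"), c(0.3, 0.8))
  got <- detection_curve(bench, tool, thresholds = c(0.01, 0.1),
                         strict = TRUE)
  expect_equal(got$fraction, c(2 / 3, 1.0))
  expect_equal(got$n_bench, c(3L, 2L))
  # thresholds with no qualifying benchmark variant are dropped
  sparse <- detection_curve(bench, tool, thresholds = c(0.9, 0.5))
  expect_equal(sparse$threshold, 0.5)
})

test_that("variant tables round-trip through the minimal VCF and TSV emitters", {
  calls <- data.frame(position = c(5L, 42L), ref = c("A", "C"),
                      alt = c("G", "T"), depth = c(100L, 250L),
                      alt_count = c(10L, 125L),
                      heteroplasmy = c(0.1, 0.5), stringsAsFactors = FALSE)
  vcf <- tempfile(fileext = ".vcf")
  write_variant_vcf(calls, vcf, chrom = "chrM", ref_length = 500L)
  back <- read_variant_table(vcf)
  expect_equal(back$position, calls$position)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$heteroplasmy, calls$heteroplasmy, tolerance = 1e-6)
  expect_equal(back$depth, calls$depth)
  tsv <- tempfile(fileext = ".tsv")
  write_variant_tsv(calls, tsv)
  back2 <- read_variant_table(tsv)
  expect_equal(back2, calls)
})
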