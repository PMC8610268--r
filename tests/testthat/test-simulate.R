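test_that("configuration validation enforces NUMT biology and fraction ranges", {
  ref <- mt_reference(2000L)
  expect_error(sim_config(mt_reference = ref,
                          numt_spec = data.frame(start = 0L, end = 39L,
                                                 identity = 0.9)),
               "40 bp")
  expect_error(sim_config(mt_reference = ref,
                          numt_spec = data.frame(start = 0L, end = 500L,
                                                 identity = 0.5)),
               "identity")
  expect_error(sim_config(mt_reference = ref,
                          numt_spec = data.frame(start = 1500L, end = 2500L,
                                                 identity = 0.9)),
               "outside")
  expect_error(sim_config(mt_reference = ref,
                          heteroplasmies = data.frame(position = 10L,
                                                      alt = "A",
                                                      fraction = 1.5)))
})

test_that("realised NUMT identity lands within a percentage point of the target", {
  ref <- mt_reference(3000L)
  cfg <- sim_config(seed = 3, mt_reference = ref,
                    numt_spec = data.frame(start = c(0L, 1200L),
                                           end = c(1000L, 1400L),
                                           identity = c(0.9, 0.75)))
  numts <- simulate_numt_sequences(cfg)
  expect_equal(numts$truth$identity_realized,
               numts$truth$identity_target, tolerance = 0.01)
  # a 1000 bp interval at identity 0.9 carries 100 planted substitutions
  expect_equal(nrow(numts$substitutions[[1]]), 100L)
  # identity 1.0 reproduces the mitochondrial slice exactly
  cfg2 <- sim_config(seed = 3, mt_reference = ref,
                     numt_spec = data.frame(start = 100L, end = 600L,
                                            identity = 1.0))
  n2 <- simulate_numt_sequences(cfg2)
  slice <- strsplit(substr(as.character(ref[[1]]), 101, 600), "")[[1]]
  expect_identical(n2$numt_chars[[1]], slice)
})

test_that("a rho-zero library contains no mtDNA-labelled fragment and all fragments cross-map", {
  fx <- shared_fixture()
  expect_equal(sum(fx$rho$truth$label == "mtDNA"), 0L)
  expect_true(all(fx$rho$truth$label == "NUMT"))
  expect_true(all(fx$rho$truth$has_nuclear))
})

test_that("error-free reads from identity-1 NUMTs are indistinguishable from mtDNA slices", {
  ref <- mt_reference(2000L)
  cfg <- sim_config(seed = 5, mt_reference = ref,
                    numt_spec = data.frame(start = 200L, end = 1400L,
                                           identity = 1.0),
                    depth = 10, error_rate = 0)
  sim <- simulate_reads(cfg, "numt")
  recs <- read_alignment_records(sim$mt_sam)
  expect_true(all(recs$nm == 0L))
  rstr <- as.character(ref[[1]])
  expect_true(all(recs$seq ==
                  substring(rstr, recs$start + 1L, recs$end)))
})

test_that("planted heteroplasmic alleles appear in the expected fraction of covering fragments", {
  ref <- mt_reference(2000L)
  alt <- pick_alt(ref, 1000L)
  cfg <- sim_config(seed = 8, mt_reference = ref,
                    heteroplasmies = data.frame(position = 1000L, alt = alt,
                                                fraction = 0.5),
                    depth = 500)
  sim <- simulate_reads(cfg, "mtDNA")
  cover <- sim$truth$frag_start <= 1000L & sim$truth$frag_end > 1000L
  carrier <- sim$truth$read_id %in% sim$het_truth$read_id
  n_cov <- sum(cover)
  frac <- sum(carrier & cover) / n_cov
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_cov))
})

test_that("every simulated fragment carries exactly one truth label", {
  fx <- shared_fixture()
  for (sim in list(fx$mix, fx$pure, fx$rho)) {
    expect_false(any(duplicated(sim$truth$read_id)))
    expect_true(all(sim$truth$label %in% c("mtDNA", "NUMT")))
  }
})

test_that("simulation is deterministic per seed and differs across seeds", {
  ref <- mt_reference(1500L)
  mk <- function(seed, dir) {
    cfg <- sim_config(seed = seed, mt_reference = ref,
                      numt_spec = data.frame(start = 100L, end = 700L,
                                             identity = 0.9),
                      depth = 8)
    simulate_reads(cfg, "mixture", out_dir = dir)
  }
  s1 <- mk(21, tempfile()); s2 <- mk(21, tempfile()); s3 <- mk(22, tempfile())
  expect_identical(s1$truth, s2$truth)
  expect_identical(readLines(s1$mt_sam), readLines(s2$mt_sam))
  expect_false(identical(readLines(s1$mt_sam), readLines(s3$mt_sam)))
  # schema is unchanged across seeds
  expect_identical(names(s1$truth), names(s3$truth))
})

test_that("the fixture suite writes a manifest that is byte-identical per seed and consistent with the truth tables", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- make_fixture_suite(17, d1)
  m2 <- make_fixture_suite(17, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  for (lib in names(m1$counts)) {
    truth <- read.delim(file.path(d1, paste0(lib, "_truth.tsv")))
    expect_equal(nrow(truth), m1$counts[[lib]]$n_fragments)
    expect_equal(sum(truth$label == "NUMT"), m1$counts[[lib]]$n_NUMT)
  }
  expect_true(file.exists(file.path(d1, "numts.bed")))
  expect_true(file.exists(file.path(d1, "mixture_mt.bam")))
})
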