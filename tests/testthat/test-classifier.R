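# small separable / null synthetic designs used across blocks
sep_data <- function(n = 200, seed = 5) {
  set.seed(seed)
  lab <- rep(c("mtDNA", "NUMT"), each = n / 2)
  data.frame(
    mt_edit_distance = ifelse(lab == "mtDNA", rnorm(n, 1, 0.5),
                              rnorm(n, 20, 2)),
    nuc_edit_distance = ifelse(lab == "mtDNA", rnorm(n, 200, 10),
                               rnorm(n, 1, 0.5)),
    mt_ld = ifelse(lab == "mtDNA", 1, 0),
    numt_overlap = ifelse(lab == "mtDNA", runif(n, 0, 0.3),
                          runif(n, 0.8, 1)),
    label = lab, stringsAsFactors = FALSE)
}

null_data <- function(n = 400, seed = 6) {
  set.seed(seed)
  data.frame(mt_edit_distance = rnorm(n), nuc_edit_distance = rnorm(n),
             mt_ld = runif(n), numt_overlap = runif(n),
             label = rep(c("mtDNA", "NUMT"), each = n / 2),
             stringsAsFactors = FALSE)
}

test_that("F1 is the harmonic mean of precision and recall with the degenerate cases pinned", {
  expect_equal(f1(0.8, 0.8), 0.8)
  expect_equal(f1(1, 0), 0)
  expect_equal(f1(0.9, 0.6), 0.72)
  expect_equal(f1(0, 0), 0)
  expect_equal(f1(0.3, 0.7), f1(0.7, 0.3))  # symmetric
})

test_that("training demands both classes, matching features, and finite values", {
  d <- sep_data()
  expect_error(numt_rf(d[d$label == "mtDNA", ]), "both classes")
  expect_error(numt_rf(d, features = c("mt_edit_distance", "nope")), "nope")
  d2 <- d; d2$mt_ld[1] <- NA
  expect_error(numt_rf(d2), "non-finite")
  expect_error(predict(numt_rf(d), d[, 1:2]), "missing feature")
})

test_that("a linearly separable problem is learned essentially perfectly", {
  d <- sep_data()
  cv <- cross_validate(d, k = 5, seed = 3)
  expect_gte(cv$pooled_f1, 0.99)
})

test_that("stratified folds partition the data with every row tested exactly once", {
  d <- sep_data(n = 100)
  cv <- cross_validate(d, k = 5, seed = 7)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(as.integer(table(cv$folds)), rep(20L, 5))  # 80%/20% split
  expect_length(cv$folds, 100L)
  expect_error(cross_validate(d[c(1:3, 51:99), ], k = 5), "too small")
})

test_that("label permutation drives cross-validated F1 to chance", {
  d <- null_data()
  cv <- cross_validate(d, k = 5, seed = 8)
  expect_gt(cv$pooled_f1, 0.35)
  expect_lt(cv$pooled_f1, 0.65)
})

test_that("model fits and predictions are deterministic given the seed", {
  d <- sep_data()
  m1 <- numt_rf(d, seed = 42)
  m2 <- numt_rf(d, seed = 42)
  expect_identical(predict(m1, d), predict(m2, d))
  expect_identical(feature_importances(m1), feature_importances(m2))
  p1 <- predict(m1, d)
  expect_identical(p1, predict(m1, d))  # repeated prediction is stable
})

test_that("feature importances are nonnegative, sum to one, and rank a planted signal first", {
  set.seed(12)
  n <- 300
  d <- data.frame(signal = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
                  noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
                  label = rep(c("NUMT", "mtDNA"), each = n / 2),
                  stringsAsFactors = FALSE)
  m <- numt_rf(d, features = c("signal", "noise1", "noise2", "noise3"),
               seed = 9)
  imp <- feature_importances(m)
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(names(which.max(imp)), "signal")
})

test_that("lowering the classification threshold never decreases recall (and keeps precision on separable data)", {
  d <- sep_data(n = 300, seed = 21)
  train <- d[seq(1, 300, 2), ]
  test <- d[seq(2, 300, 2), ]
  m <- numt_rf(train, seed = 4)
  p <- predict(m, test)
  truth <- test$label
  thresholds <- seq(0.9, 0.1, by = -0.2)
  recalls <- precisions <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pred <- ifelse(p >= thresholds[i], "mtDNA", "NUMT")
    tp <- sum(pred == "mtDNA" & truth == "mtDNA")
    recalls[i] <- tp / sum(truth == "mtDNA")
    precisions[i] <- if (sum(pred == "mtDNA") == 0) 1 else
      tp / sum(pred == "mtDNA")
  }
  expect_true(all(diff(recalls) >= 0))
  expect_true(all(diff(precisions) <= 0))
})

test_that("a persisted model bundle predicts identically after reload", {
  d <- sep_data()
  m <- numt_rf(d, seed = 2)
  p <- tempfile(fileext = ".rds")
  write_model(m, p)
  m2 <- read_model(p)
  expect_identical(predict(m2, d), predict(m, d))
  expect_identical(m2$features, m$features)
})

test_that("classifier performance degrades to chance as NUMT divergence vanishes and grows with it", {
  ref <- mt_reference(2000L)
  f1_at <- function(identity, seed) {
    cfg <- sim_config(seed = seed, mt_reference = ref,
                      numt_spec = data.frame(start = 300L, end = 1500L,
                                             identity = identity),
                      depth = 25, error_rate = 0.002)
    mix <- simulate_reads(cfg, "mixture", numt_fraction = 0.5)
    pairs <- load_pairs(mix$mt_sam, mix$nuc_sam)
    labels <- setNames(mix$truth$label, mix$truth$read_id)
    ld <- make_ld(data.frame(pos_i = integer(0), alt_i = character(0),
                             pos_j = integer(0), alt_j = character(0),
                             r2 = numeric(0)))
    feats <- featurize(pairs, ld, numts = NULL, labels = labels)
    # nuclear evidence and NUMT-list features withheld: only the
    # divergence-driven edit distance separates the classes
    cross_validate(feats, k = 3, seed = seed,
                   features = "mt_edit_distance", ntree = 64)$pooled_f1
  }
  low <- f1_at(1.0, 31)    # no divergence: mt edit distance uninformative
  high <- f1_at(0.9, 33)   # 10% divergence: strongly informative
  expect_gt(high, 0.9)
  expect_lt(low, 0.75)
  expect_gt(high, low)
})
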