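#' F1 score
#'
#' Harmonic mean of precision and recall, `2PR/(P+R)`; defined as 0 when
#' both are 0. Vectorised.
#'
#' @param precision,recall Numbers in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @examples
#' f1(0.9, 0.6)  # 0.72
#' @export
f1 <- function(precision, recall) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  out <- ifelse(precision + recall == 0, 0,
                2 * precision * recall / (precision + recall))
  out
}

#' Fit the mtDNA-vs-NUMT random forest read classifier
#'
#' The central model of the package: a random forest (128 trees by default)
#' over the alignment-derived read-pair features, trained on labelled
#' fragments from an mtDNA-enriched (positive) and a rho-zero-derived
#' (negative) library, which assigns each ambiguous fragment a probability
#' of being genuine mtDNA. The default feature set is the final-model set:
#' mitochondrial edit distance, nuclear edit distance, LD co-occurrence
#' score and NUMT overlap ([final_model_features()]); the remaining
#' alignment features can be included for model-selection experiments.
#'
#' @param x data.frame holding the feature columns and, unless `labels` is
#'   given, a `label` column with values `"mtDNA"`/`"NUMT"`.
#' @param labels Optional factor/character vector of labels overriding
#'   `x$label`.
#' @param features Character vector of feature column names (order is fixed
#'   at fit time and enforced at predict time).
#' @param ntree Number of trees (default 128).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed RNG seed; fits are deterministic given `seed` and data.
#' @param ... Further arguments to [randomForest::randomForest()].
#' @return An object of class `numt_rf` with components `forest`,
#'   `features`, `ntree`, `seed`, `class_counts` and `importance`
#'   (normalised to sum to 1).
#' @seealso [predict.numt_rf()], [cross_validate()], [feature_importances()]
#' @export
numt_rf <- function(x, labels = NULL, features = final_model_features(),
                    ntree = 128, mtry = NULL, seed = 1, ...) {
  if (is.null(labels)) {
    if (!"label" %in% names(x)) stop("no labels: supply `labels` or x$label")
    labels <- x$label
  }
  y <- factor(as.character(labels), levels = c("NUMT", "mtDNA"))
  if (any(is.na(y))) stop("labels must be 'mtDNA' or 'NUMT'")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  missing_cols <- setdiff(features, names(x))
  if (length(missing_cols)) {
    stop("feature column(s) absent from x: ",
         paste(missing_cols, collapse = ", "))
  }
  xm <- as.matrix(x[, features, drop = FALSE])
  if (!all(is.finite(xm))) stop("non-finite feature values in training data")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(features))))
  fit <- with_local_seed(seed,
    randomForest::randomForest(x = xm, y = y, ntree = ntree, mtry = mtry,
                               importance = FALSE, ...))
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp),
                                                   length(imp))
  structure(list(forest = fit, features = features, ntree = ntree,
                 mtry = mtry, seed = seed,
                 class_counts = table(y), importance = imp,
                 call = match.call()),
            class = "numt_rf")
}

#' @export
print.numt_rf <- function(x, ...) {
  cat("numt_rf: random-forest mtDNA/NUMT read classifier\n")
  cat("  trees: ", x$ntree, ", mtry: ", x$mtry, ", seed: ", x$seed, "\n",
      sep = "")
  cat("  features: ", paste(x$features, collapse = ", "), "\n", sep = "")
  cat("  training fragments: ",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.numt_rf <- function(object, ...) {
  print(object)
  cat("  OOB error: ",
      signif(object$forest$err.rate[object$ntree, "OOB"], 3), "\n", sep = "")
  cat("  feature importances (sum to 1):\n")
  imp <- sort(object$importance, decreasing = TRUE)
  for (nm in names(imp)) cat(sprintf("    %-18s %.3f\n", nm, imp[nm]))
  invisible(object)
}

#' Predict mtDNA probabilities or classes for read pairs
#'
#' @param object A fitted `numt_rf`.
#' @param newdata data.frame containing the model's feature columns.
#' @param type `"prob"` for the probability that each fragment is mtDNA,
#'   `"class"` for thresholded labels.
#' @param threshold Classification threshold; a fragment with probability
#'   `>= threshold` is called mtDNA (inclusive tie rule, favouring
#'   retention).
#' @param ... Unused.
#' @return Numeric probabilities, or a character vector of
#'   `"mtDNA"`/`"NUMT"`.
#' @export
predict.numt_rf <- function(object, newdata, type = c("prob", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  xm <- as.matrix(newdata[, object$features, drop = FALSE])
  p <- stats::predict(object$forest, xm, type = "prob")[, "mtDNA"]
  p <- unname(p)
  if (type == "prob") p else ifelse(p >= threshold, "mtDNA", "NUMT")
}

#' Normalised feature importances of a fitted classifier
#'
#' Gini-based variable importances rescaled to sum to one.
#'
#' @param model A fitted `numt_rf`.
#' @return Named numeric vector, nonnegative, summing to 1.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "numt_rf"))
  model$importance
}

#' Save / load a fitted classifier bundle
#'
#' The on-disk bundle is a single RDS file embedding the forest together
#' with its metadata (feature order, seed, training class counts), so a
#' restored model predicts identically.
#'
#' @param model A `numt_rf`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "numt_rf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "numt_rf")) stop("not a numt_rf model bundle: ", path)
  model
}

#' Stratified k-fold cross-validation of the read classifier
#'
#' Random stratified partition into k folds (an 80%/20% train/validation
#' split corresponds to k = 5: four folds train, one tests); per-fold
#' precision, recall and F1 for the mtDNA class, plus the pooled F1 from
#' the pooled confusion counts.
#'
#' @param x Feature data.frame with a `label` column (or `labels` given).
#' @param labels Optional label vector.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the fold assignment and fits.
#' @param features,ntree,... Passed to [numt_rf()].
#' @param threshold Classification threshold.
#' @return An object of class `cv_report`: list with `k`, `folds`
#'   (assignment per row), `per_fold` (data.frame precision/recall/F1) and
#'   `pooled_f1`.
#' @export
cross_validate <- function(x, labels = NULL, k = 5, seed = 1,
                           features = final_model_features(), ntree = 128,
                           threshold = 0.5, ...) {
  stopifnot(k >= 2)
  if (is.null(labels)) labels <- x$label
  y <- factor(as.character(labels), levels = c("NUMT", "mtDNA"))
  if (min(table(y)) < k) stop("a class is too small to stratify into ", k,
                              " folds")
  folds <- integer(length(y))
  folds[] <- with_local_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  per_fold <- data.frame(fold = seq_len(k), precision = NA_real_,
                         recall = NA_real_, f1 = NA_real_)
  tp <- fp <- fn <- 0L
  for (i in seq_len(k)) {
    test <- folds == i
    fit <- numt_rf(x[!test, , drop = FALSE], labels = y[!test],
                   features = features, ntree = ntree, seed = seed + i, ...)
    pred <- predict(fit, x[test, , drop = FALSE], type = "class",
                    threshold = threshold)
    truth <- as.character(y[test])
    tpi <- sum(pred == "mtDNA" & truth == "mtDNA")
    fpi <- sum(pred == "mtDNA" & truth == "NUMT")
    fni <- sum(pred == "NUMT" & truth == "mtDNA")
    prec <- if (tpi + fpi == 0) 0 else tpi / (tpi + fpi)
    rec <- if (tpi + fni == 0) 0 else tpi / (tpi + fni)
    per_fold$precision[i] <- prec
    per_fold$recall[i] <- rec
    per_fold$f1[i] <- f1(prec, rec)
    tp <- tp + tpi; fp <- fp + fpi; fn <- fn + fni
  }
  pooled_prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  pooled_rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(k = k, folds = folds, per_fold = per_fold,
                 pooled_precision = pooled_prec, pooled_recall = pooled_rec,
                 pooled_f1 = f1(pooled_prec, pooled_rec), seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report: ", x$k, "-fold stratified cross-validation\n", sep = "")
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("pooled: precision %.3f, recall %.3f, F1 %.3f\n",
              x$pooled_precision, x$pooled_recall, x$pooled_f1))
  invisible(x)
}
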