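#' Heteroplasmy error between a benchmark call and a tool call
#'
#' Defined as benchmark heteroplasmy minus tool heteroplasmy; a variant
#' absent from one set is treated as heteroplasmy 0 on that side, so a
#' positive error indicates under-calling (toward false negatives) and a
#' negative error over-calling. Vectorised; antisymmetric in its arguments.
#'
#' @param p_bench,p_tool Heteroplasmy fractions in \[0, 1\].
#' @return `p_bench - p_tool`, in \[-1, 1\].
#' @export
heteroplasmy_error <- function(p_bench, p_tool) {
  stopifnot(all(p_bench >= 0 & p_bench <= 1),
            all(p_tool >= 0 & p_tool <= 1))
  p_bench - p_tool
}

#' Variance-scaled heteroplasmy error
#'
#' Divides the raw error by `p(1-p)` of the benchmark heteroplasmy to
#' account for the binomial sampling variance growing with `p(1-p)`.
#' Undefined (returned as `NA`) when the benchmark heteroplasmy is exactly
#' 0 or 1.
#'
#' @param error Raw heteroplasmy error.
#' @param p_bench Benchmark heteroplasmy in \[0, 1\].
#' @return `error / (p_bench * (1 - p_bench))`, or `NA` at `p_bench` 0 or 1.
#' @examples
#' scaled_heteroplasmy_error(0.1, 0.5)   # 0.4
#' @export
scaled_heteroplasmy_error <- function(error, p_bench) {
  stopifnot(all(p_bench >= 0 & p_bench <= 1))
  ifelse(p_bench <= 0 | p_bench >= 1, NA_real_,
         error / (p_bench * (1 - p_bench)))
}

#' Classify a variant call against its benchmark value
#'
#' The tolerance rule of the benchmark comparison: a call is a false
#' negative when the tool heteroplasmy falls more than `tol` below the
#' benchmark value (`p_tool < p_bench - tol`), a false positive when it
#' exceeds the benchmark value by more than `tol`
#' (`p_tool > p_bench + tol`), and a match otherwise. With the default
#' `tol = 0.2`, a benchmark heteroplasmy of 0.5 requires a tool value
#' greater than 0.3 for a match. Absent calls enter as 0 on the missing
#' side. Vectorised; the three outcomes are exhaustive and mutually
#' exclusive.
#'
#' @param p_bench,p_tool Heteroplasmy fractions in \[0, 1\].
#' @param tol Tolerance in (0, 1); default 0.2.
#' @return Character vector over `"match"`, `"false_negative"`,
#'   `"false_positive"`.
#' @examples
#' classify_variant(0.5, 0.31)  # match
#' classify_variant(0.5, 0.29)  # false_negative
#' classify_variant(0.0, 0.25)  # false_positive
#' @export
classify_variant <- function(p_bench, p_tool, tol = 0.2) {
  stopifnot(tol > 0, tol < 1)
  ifelse(p_tool < p_bench - tol, "false_negative",
         ifelse(p_tool > p_bench + tol, "false_positive", "match"))
}

#' Compare a tool's variant set against a benchmark set
#'
#' Joins the two call sets on variant identity `(position, alt)`, applies
#' the tolerance rule to every variant in the union (absent calls at
#' heteroplasmy 0), and tallies the benchmark-comparison statistics:
#' misclassifications (false positives + false negatives), homoplasmic
#' variant errors — misclassified variants whose governing heteroplasmy
#' (benchmark side for false negatives, tool side for false positives)
#' exceeds 0.5 — and the maximum absolute heteroplasmy error over the
#' union. A tool calling a different alternate allele at a benchmark
#' position counts as one false negative plus one false positive.
#'
#' @param bench,tool data.frames with columns `position`, `alt`,
#'   `heteroplasmy` (e.g. from [pileup_heteroplasmy()] or
#'   [read_variant_table()]). Duplicate `(position, alt)` keys within one
#'   set are an error.
#' @param tol Tolerance for [classify_variant()].
#' @return An object of class `eval_report`: list with the counts
#'   `n_misclassifications`, `n_false_positives`, `n_false_negatives`,
#'   `n_homoplasmic_errors`, `max_abs_heteroplasmy_error`, and `variants`,
#'   the per-variant table (position, alt, p_bench, p_tool, error,
#'   scaled_error, scaled_defined, class).
#' @export
compare_variant_sets <- function(bench, tool, tol = 0.2) {
  key <- function(df) paste0(df$position, ":", df$alt)
  for (nm in c("bench", "tool")) {
    df <- get(nm)
    if (anyDuplicated(key(df))) {
      stop("duplicate (position, alt) key in ", nm, " set")
    }
  }
  all_keys <- union(key(bench), key(tool))
  bi <- match(all_keys, key(bench))
  ti <- match(all_keys, key(tool))
  p_bench <- ifelse(is.na(bi), 0, bench$heteroplasmy[bi])
  p_tool <- ifelse(is.na(ti), 0, tool$heteroplasmy[ti])
  pos <- ifelse(is.na(bi), tool$position[ti], bench$position[bi])
  alt <- ifelse(is.na(bi), tool$alt[ti], bench$alt[bi])
  cls <- classify_variant(p_bench, p_tool, tol = tol)
  err <- heteroplasmy_error(p_bench, p_tool)
  sc <- scaled_heteroplasmy_error(err, p_bench)
  variants <- data.frame(position = pos, alt = alt, p_bench = p_bench,
                         p_tool = p_tool, error = err, scaled_error = sc,
                         scaled_defined = !is.na(sc), class = cls,
                         stringsAsFactors = FALSE)
  n_fp <- sum(cls == "false_positive")
  n_fn <- sum(cls == "false_negative")
  n_homo <- sum((cls == "false_negative" & p_bench > 0.5) |
                (cls == "false_positive" & p_tool > 0.5))
  structure(list(n_misclassifications = n_fp + n_fn,
                 n_false_positives = n_fp,
                 n_false_negatives = n_fn,
                 n_homoplasmic_errors = n_homo,
                 max_abs_heteroplasmy_error =
                   if (nrow(variants)) max(abs(err)) else 0,
                 tol = tol,
                 variants = variants),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (tolerance ", x$tol, "):\n", sep = "")
  cat("  misclassifications:           ", x$n_misclassifications, "\n")
  cat("  false positives:              ", x$n_false_positives, "\n")
  cat("  false negatives:              ", x$n_false_negatives, "\n")
  cat("  homoplasmic variant errors:   ", x$n_homoplasmic_errors, "\n")
  cat("  max |heteroplasmy error|:     ",
      signif(x$max_abs_heteroplasmy_error, 3), "\n")
  invisible(x)
}

#' Minor allele frequency of a heteroplasmy value
#'
#' `min(p, 1 - p)`: equal to the heteroplasmy below 0.5 and to its
#' complement above.
#'
#' @param p Heteroplasmy in \[0, 1\]. Vectorised.
#' @return Value in \[0, 0.5\].
#' @export
maf <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  pmin(p, 1 - p)
}

#' Fraction of benchmark variants detected at heteroplasmy thresholds
#'
#' For each threshold t, the fraction of benchmark variants with
#' heteroplasmy at least t that the tool detects. Under the default
#' tolerance criterion a variant is detected when it is not a false
#' negative of [classify_variant()]; `strict = TRUE` instead requires mere
#' presence of the `(position, alt)` key in the tool set. Thresholds with
#' no qualifying benchmark variant are dropped from the result.
#'
#' @param bench,tool Variant data.frames as in [compare_variant_sets()].
#' @param thresholds Numeric vector in (0, 1\].
#' @param tol Tolerance for the detection criterion.
#' @param strict Use strict key presence instead of the tolerance rule.
#' @return data.frame with columns `threshold`, `n_bench`, `fraction`.
#' @export
detection_curve <- function(bench, tool, thresholds, tol = 0.2,
                            strict = FALSE) {
  stopifnot(all(thresholds > 0 & thresholds <= 1))
  tk <- paste0(tool$position, ":", tool$alt)
  bk <- paste0(bench$position, ":", bench$alt)
  ti <- match(bk, tk)
  p_tool <- ifelse(is.na(ti), 0, tool$heteroplasmy[ti])
  detected <- if (strict) !is.na(ti) else
    classify_variant(bench$heteroplasmy, p_tool, tol = tol) != "false_negative"
  rows <- lapply(thresholds, function(t) {
    idx <- bench$heteroplasmy >= t
    if (!any(idx)) return(NULL)
    data.frame(threshold = t, n_bench = sum(idx),
               fraction = mean(detected[idx]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(threshold = numeric(0), n_bench = integer(0),
                      fraction = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Read a variant table from VCF or TSV
#'
#' Accepts either a VCF (heteroplasmy taken from the `AF` INFO field, depth
#' from `DP`) or a TSV with columns `position` (0-based), `ref`, `alt` and
#' `heteroplasmy` (optionally `depth`, `alt_count`).
#'
#' @param path Input file; format chosen by extension (`.vcf` vs anything
#'   else).
#' @return data.frame with columns `position` (0-based), `ref`, `alt`,
#'   `heteroplasmy` and `depth` when available.
#' @export
read_variant_table <- function(path) {
  if (tolower(tools::file_ext(path)) == "vcf") {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    af <- if ("AF" %in% names(info)) as.numeric(unlist(info$AF)) else
      rep(NA_real_, length(rr))
    dp <- if ("DP" %in% names(info)) as.integer(info$DP) else
      rep(NA_integer_, length(rr))
    data.frame(position = GenomicRanges::start(rr) - 1L,
               ref = as.character(rr$REF),
               alt = as.character(unlist(rr$ALT)),
               heteroplasmy = af,
               depth = dp,
               stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
}

#' Write variant calls as minimal VCF and/or TSV
#'
#' The VCF carries `CHROM/POS/REF/ALT` plus `DP` and `AF` INFO fields; the
#' TSV mirrors the input data.frame.
#'
#' @param calls data.frame with `position` (0-based), `ref`, `alt`,
#'   `heteroplasmy`, optionally `depth`/`alt_count`.
#' @param path Output path.
#' @param chrom Contig name for the VCF CHROM column.
#' @param ref_length Contig length for the VCF header.
#' @export
write_variant_vcf <- function(calls, path, chrom = "chrM",
                              ref_length = 16569L) {
  dp <- if ("depth" %in% names(calls)) calls$depth else
    rep(NA_integer_, nrow(calls))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom,
                   as.integer(ref_length)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction (heteroplasmy)\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    o <- order(calls$position, calls$alt)
    calls <- calls[o, , drop = FALSE]; dp <- dp[o]
    info <- ifelse(is.na(dp),
                   sprintf("AF=%.6g", calls$heteroplasmy),
                   sprintf("DP=%d;AF=%.6g", dp, calls$heteroplasmy))
    paste(chrom, calls$position + 1L, ".", calls$ref, calls$alt, ".",
          "PASS", info, sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
write_variant_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
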