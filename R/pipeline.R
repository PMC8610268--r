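#' Build the positive (mtDNA) training set
#'
#' Featurizes every fragment of an mtDNA-enriched library's alignment to
#' the mitochondrial reference and labels it `"mtDNA"`. Such libraries are
#' produced by long-range PCR amplification of the mitochondrial genome, so
#' every aligned fragment is genuine mtDNA.
#'
#' @param path_mt SAM/BAM of the enriched library vs the mitochondrial
#'   reference.
#' @param ld,numts,... Passed to [featurize()].
#' @return Feature data.frame with `label = "mtDNA"`.
#' @export
build_positive_training_set <- function(path_mt, ld, numts = NULL, ...) {
  pairs <- load_pairs(path_mt, NULL)
  fx <- featurize(pairs, ld, numts, ...)
  if (nrow(fx)) fx$label <- "mtDNA" else fx$label <- character(0)
  fx
}

#' Build the negative (NUMT) training set from a rho-zero library
#'
#' Rho-zero cells carry no mitochondrial DNA, so any of their reads that
#' aligns to the mitochondrial reference *and* re-aligns to the nuclear
#' genome must derive from a NUMT. Only fragments with both mitochondrial
#' and nuclear alignments are emitted, labelled `"NUMT"`.
#'
#' @param path_mt SAM/BAM of the rho-zero library vs the mitochondrial
#'   reference.
#' @param path_nuc SAM/BAM of those reads re-aligned to the nuclear genome.
#' @param ld,numts,... Passed to [featurize()].
#' @return Feature data.frame with `label = "NUMT"`.
#' @export
build_negative_training_set <- function(path_mt, path_nuc, ld, numts = NULL,
                                        ...) {
  pairs <- load_pairs(path_mt, path_nuc)
  with_nuc <- if (is.null(pairs$nuc)) character(0) else
    unique(pairs$nuc$read_id)
  keep <- pairs$ids %in% with_nuc
  pairs$mt <- pairs$mt[pairs$mt$read_id %in% pairs$ids[keep], , drop = FALSE]
  pairs$ids <- pairs$ids[keep]
  pairs$single_mate <- pairs$single_mate[keep]
  fx <- featurize(pairs, ld, numts, ...)
  if (nrow(fx) == 0) {
    warning("no fragments with both mitochondrial and nuclear alignments; ",
            "negative training set is empty")
    fx$label <- character(0)
  } else {
    fx$label <- "NUMT"
  }
  fx
}

#' Retain reads with a minimum aligned length
#'
#' The stringent benchmark filter: keeps records whose reference-consuming
#' aligned base count (CIGAR `M`/`=`/`X`) is at least `min_aligned_bases`
#' (default 270 bp, i.e. >90% of a 300 bp read).
#'
#' @param records Alignment record data.frame ([read_alignment_records()]).
#' @param min_aligned_bases Threshold in bp.
#' @return The retained subset of `records`.
#' @export
benchmark_filter <- function(records, min_aligned_bases = 270) {
  lens <- GenomicAlignments::explodeCigarOpLengths(records$cigar,
                                                   ops = c("M", "=", "X"))
  aligned <- vapply(lens, sum, numeric(1))
  records[aligned >= min_aligned_bases, , drop = FALSE]
}

#' Classify a sample's mitochondrially-aligned fragments
#'
#' The central step of the four-step workflow: featurizes every fragment of
#' the mitochondrial alignment (with its nuclear re-alignment evidence),
#' applies the fitted classifier, and splits the alignment into a retained
#' (mtDNA) and a rejected (NUMT) set at the probability threshold.
#' Fragments with probability `>= threshold` are retained (inclusive tie
#' rule). Rejected reads are written out, not dropped, so they can be
#' audited. Each output record carries the fragment probability in the
#' `XP` tag and a `PASS`/`FAIL` flag in the `XF` tag (names configurable).
#'
#' @param path_mt,path_nuc SAM/BAM inputs (nuclear may be `NULL`).
#' @param model Fitted [numt_rf()].
#' @param ld An `ld_table`.
#' @param numts NUMT regions ([read_numt_bed()]).
#' @param threshold Retention threshold (default 0.5, the operating point).
#' @param out_dir Output directory for `retained`/`rejected` files; `NULL`
#'   suppresses file output.
#' @param as_bam Convert the SAM outputs to sorted, indexed BAM.
#' @param prob_tag,flag_tag Names of the probability and pass/fail tags.
#' @param fast_path_no_nuc Auto-accept fragments lacking any nuclear
#'   alignment (probability forced to 1) instead of scoring them.
#' @param ... Passed to [featurize()].
#' @return An object of class `classify_result`: list with `features`
#'   (feature table plus `prob` and `retained` columns), `report` (counts),
#'   `retained_ids`, `rejected_ids` and output paths when written.
#' @export
classify_run <- function(path_mt, path_nuc, model, ld, numts = NULL,
                         threshold = 0.5, out_dir = NULL, as_bam = TRUE,
                         prob_tag = "XP", flag_tag = "XF",
                         fast_path_no_nuc = FALSE, ...) {
  pairs <- load_pairs(path_mt, path_nuc)
  fx <- featurize(pairs, ld, numts, ...)
  prob <- predict(model, fx, type = "prob")
  if (fast_path_no_nuc) {
    no_nuc <- fx$nuc_alignments == 0L
    prob[no_nuc] <- 1
  }
  retained <- prob >= threshold
  fx$prob <- prob
  fx$retained <- retained
  retained_ids <- fx$read_id[retained]
  rejected_ids <- fx$read_id[!retained]
  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    recs <- pairs$mt
    pr <- prob[match(recs$read_id, fx$read_id)]
    tags <- sprintf("%s:f:%.4f\t%s:Z:%s", prob_tag, pr, flag_tag,
                    ifelse(pr >= threshold, "PASS", "FAIL"))
    rl <- stats::setNames(pairs$ref_length, pairs$ref_name)
    for (set in c("retained", "rejected")) {
      idx <- if (set == "retained") recs$read_id %in% retained_ids else
        recs$read_id %in% rejected_ids
      sam <- file.path(out_dir, paste0(set, ".sam"))
      write_sam(recs[idx, , drop = FALSE], rl, sam,
                extra_tags = tags[idx])
      paths[[set]] <- if (as_bam) sam_to_bam(sam) else sam
    }
  }
  report <- list(n_input = length(pairs$ids),
                 n_retained = length(retained_ids),
                 n_rejected = length(rejected_ids),
                 threshold = threshold)
  structure(list(features = fx, report = report,
                 retained_ids = retained_ids, rejected_ids = rejected_ids,
                 paths = paths, ref_name = pairs$ref_name,
                 ref_length = pairs$ref_length),
            class = "classify_result")
}

#' @export
print.classify_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("classify_result: %d fragment(s); %d retained, ",
                     "%d rejected at threshold %.2f\n"),
              r$n_input, r$n_retained, r$n_rejected, r$threshold))
  invisible(x)
}

#' Pileup heteroplasmy estimator
#'
#' A self-contained per-site allele-fraction estimator over a classified
#' (retained) mitochondrial alignment: depth is the read coverage at each
#' site, alternate counts come from the MD-called mismatches, and
#' heteroplasmy is `alt_count / depth`. One call is emitted per
#' non-reference allele with at least one supporting read at a site with
#' depth at least `min_depth`. Deliberately simple — no strand-bias or
#' base-quality filtering; a dedicated variant caller is expected
#' downstream in production use.
#'
#' @param x An `aligned_pairs` object, a `classify_result` (its retained
#'   set is used), or a SAM/BAM path.
#' @param reference Optional [Biostrings::DNAStringSet]; when given, the
#'   contig name must match the alignment reference, and MD-reported
#'   reference bases are checked against it.
#' @param min_depth Minimum site depth for a call (default 10).
#' @return data.frame of variant calls: `position` (0-based), `ref`, `alt`,
#'   `depth`, `alt_count`, `heteroplasmy`.
#' @export
pileup_heteroplasmy <- function(x, reference = NULL, min_depth = 10) {
  if (inherits(x, "classify_result")) {
    path <- x$paths$retained
    if (is.null(path)) stop("classify_result carries no retained output file")
    x <- load_pairs(path)
  } else if (is.character(x)) {
    x <- load_pairs(x)
  }
  stopifnot(inherits(x, "aligned_pairs"))
  recs <- x$mt
  if (!is.null(reference)) {
    if (!identical(ref_name(reference), x$ref_name)) {
      stop("reference contig '", ref_name(reference),
           "' does not match alignment contig '", x$ref_name, "'")
    }
  }
  empty <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      alt_count = integer(0), heteroplasmy = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(recs) == 0) return(empty)
  cov <- IRanges::coverage(IRanges::IRanges(start = recs$start + 1L,
                                            end = recs$end),
                           width = x$ref_length)
  vars <- records_md_variants(recs)
  if (nrow(vars) == 0) return(empty)
  alt <- position <- NULL
  vars <- vars[alt != "N"]
  counts <- vars[, list(alt_count = .N, ref = ref[1]),
                 by = list(position, alt)]
  counts$depth <- as.integer(as.numeric(cov[counts$position + 1L]))
  if (!is.null(reference)) {
    ref_chars <- ref_as_chars(reference)
    bad <- which(counts$ref != ref_chars[counts$position + 1L])
    if (length(bad)) {
      stop("MD-reported reference base disagrees with the reference at ",
           "position(s) ", paste(utils::head(counts$position[bad], 3),
                                 collapse = ", "))
    }
  }
  counts <- counts[counts$depth >= min_depth & counts$alt_count >= 1L, ]
  out <- data.frame(position = counts$position, ref = counts$ref,
                    alt = counts$alt, depth = counts$depth,
                    alt_count = counts$alt_count,
                    heteroplasmy = counts$alt_count / counts$depth,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mitochondrial copy-number estimate
#'
#' The ratio of mitochondrially-aligned reads to nuclear reads on the
#' autosomes (chromosomes 1-22). An optional normalised mode additionally
#' corrects for reference lengths and autosomal ploidy, giving mtDNA copies
#' per diploid nuclear genome; the raw ratio is the default.
#'
#' @param mt_read_count Number of mtDNA-classified reads.
#' @param nuclear_read_count Number of reads on chromosomes 1-22.
#' @param normalize Apply length/ploidy normalisation.
#' @param mt_length,nuclear_length Reference lengths used when
#'   `normalize = TRUE`.
#' @param ploidy Autosomal ploidy (default 2).
#' @return Numeric scalar.
#' @export
mtdna_copy_number <- function(mt_read_count, nuclear_read_count,
                              normalize = FALSE, mt_length = 16569,
                              nuclear_length = 2.875e9, ploidy = 2) {
  if (nuclear_read_count <= 0) stop("nuclear read count must be positive")
  ratio <- mt_read_count / nuclear_read_count
  if (!normalize) return(ratio)
  ratio * (nuclear_length / mt_length) * ploidy
}

#' Count mapped reads for copy-number estimation from BAM files
#'
#' Uses the BAM index statistics to count reads mapped to the mitochondrial
#' contig and to the autosomes, matching both `"1"`- and `"chr1"`-style
#' chromosome names.
#'
#' @param mt_bam BAM of classified mtDNA alignments.
#' @param wgs_bam BAM of the whole-genome alignment.
#' @param mt_name Mitochondrial contig name(s) to match.
#' @param autosomes Autosome name list; default covers both dialects.
#' @param ... Passed to [mtdna_copy_number()].
#' @return As [mtdna_copy_number()].
#' @export
copy_number_from_bams <- function(mt_bam, wgs_bam,
                                  mt_name = c("chrM", "MT", "chrMT", "M"),
                                  autosomes = c(as.character(1:22),
                                                paste0("chr", 1:22)), ...) {
  mt_stats <- Rsamtools::idxstatsBam(mt_bam)
  wgs_stats <- Rsamtools::idxstatsBam(wgs_bam)
  mt_n <- sum(mt_stats$mapped[mt_stats$seqnames %in% mt_name])
  nuc_n <- sum(wgs_stats$mapped[wgs_stats$seqnames %in% autosomes])
  mtdna_copy_number(mt_n, nuc_n, ...)
}
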