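#' Read alignment records from a SAM/BAM file
#'
#' Loads per-read alignment records into a flat table using
#' [Rsamtools::scanBam()], extracting the auxiliary tags the NUMT features
#' need: `NM` (edit distance), `NH` (number of reported alignments), `XQ`
#' (aligner mapping score) and `MD` (mismatch positions). Coordinates are
#' converted to 0-based half-open.
#'
#' Aligner-dependent tags are imputed when absent: a missing `NM` is
#' recomputed from the `MD` tag plus the CIGAR (mismatches + inserted +
#' deleted bases); if both `NM` and `MD` are missing the record is rejected.
#' A missing `NH` falls back to the number of records observed for the same
#' read id and mate in the file; a missing `XQ` falls back to the mapping
#' quality.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param include_duplicates,include_qcfail Keep duplicate-marked /
#'   QC-fail-flagged records (default: drop them).
#' @return data.frame with columns `read_id`, `rname`, `start`, `end`
#'   (0-based half-open), `strand`, `mapq`, `cigar`, `seq`, `qual`, `flag`,
#'   `mate` (1 or 2), `secondary`, `nm`, `nh`, `xq`, `md`.
#' @export
read_alignment_records <- function(path, include_duplicates = FALSE,
                                   include_qcfail = FALSE) {
  if (tolower(tools::file_ext(path)) == "sam") {
    path <- sam_to_bam(path, tempfile())
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand",
             "seq", "qual"),
    tag = c("NM", "MD", "NH", "XQ"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$qname)
  tag_or_na <- function(tag, na) {
    v <- res$tag[[tag]]
    if (is.null(v) || length(v) == 0) rep(na, n) else v
  }
  df <- data.frame(
    read_id = res$qname,
    rname = as.character(res$rname),
    start = res$pos - 1L,
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    strand = as.character(res$strand),
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    flag = res$flag,
    stringsAsFactors = FALSE)
  df$end <- df$start + GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  df$mate <- ifelse(bitwAnd(df$flag, 128L) > 0L, 2L, 1L)
  df$secondary <- bitwAnd(df$flag, 256L) > 0L | bitwAnd(df$flag, 2048L) > 0L
  df$nm <- suppressWarnings(as.integer(tag_or_na("NM", NA_integer_)))
  df$md <- as.character(tag_or_na("MD", NA_character_))
  df$nh <- suppressWarnings(as.integer(tag_or_na("NH", NA_integer_)))
  df$xq <- suppressWarnings(as.integer(tag_or_na("XQ", NA_integer_)))

  if (!include_duplicates) df <- df[bitwAnd(df$flag, 1024L) == 0L, ]
  if (!include_qcfail) df <- df[bitwAnd(df$flag, 512L) == 0L, ]

  # NM fallback from MD + CIGAR
  miss_nm <- is.na(df$nm)
  if (any(miss_nm)) {
    no_md <- miss_nm & is.na(df$md)
    if (any(no_md)) {
      stop("record(s) without NM or MD tag, cannot determine edit distance: ",
           paste(utils::head(df$read_id[no_md], 3), collapse = ", "))
    }
    df$nm[miss_nm] <- vapply(which(miss_nm), function(i) {
      nm_from_md_cigar(df$md[i], df$cigar[i])
    }, integer(1))
  }
  # NH fallback: records per (read_id, mate) in this file
  miss_nh <- is.na(df$nh)
  if (any(miss_nh)) {
    key <- paste(df$read_id, df$mate)
    cnt <- table(key)
    df$nh[miss_nh] <- as.integer(cnt[key[miss_nh]])
  }
  # XQ fallback: mapping quality
  df$xq[is.na(df$xq)] <- df$mapq[is.na(df$xq)]
  rownames(df) <- NULL
  df
}

# Edit distance implied by MD (mismatches + deletions) and CIGAR (insertions).
nm_from_md_cigar <- function(md, cigar) {
  dels <- regmatches(md, gregexpr("\\^[A-Z]+", md))[[1]]
  n_del <- sum(nchar(dels) - 1L)
  md_wo_del <- gsub("\\^[A-Z]+", "", md)
  n_mm <- sum(gregexpr("[A-Z]", md_wo_del)[[1]] > 0)
  ops <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = "I")[[1]]
  as.integer(n_mm + n_del + sum(ops))
}

#' Load and pair mitochondrial / nuclear alignments
#'
#' Collates the two alignment sets of the workflow — the sample aligned to
#' the mitochondrial reference, and the mitochondrially-aligned reads
#' re-aligned to the nuclear genome — into one fragment-level container.
#' Every read id with a primary mitochondrial alignment yields exactly one
#' pair; nuclear evidence is attached when the same read id appears in the
#' nuclear file. Secondary/supplementary records never form pairs themselves
#' but are retained on the nuclear side so that the "best nuclear
#' explanation" (minimum edit distance over all nuclear hits) is available
#' to the features.
#'
#' Fragments with a single aligned mate are retained and flagged
#' (`single_mate`), not dropped.
#'
#' @param path_mt SAM/BAM aligned to the mitochondrial reference.
#' @param path_nuc Optional SAM/BAM of the same reads re-aligned to the
#'   nuclear genome.
#' @param ... Passed to [read_alignment_records()].
#' @return An object of class `aligned_pairs`: a list with elements `mt`
#'   (primary mitochondrial records), `nuc` (nuclear records), `ids`
#'   (fragment read ids), `single_mate` (named logical), `ref_name` and
#'   `ref_length` (from the mitochondrial BAM header).
#' @export
load_pairs <- function(path_mt, path_nuc = NULL, ...) {
  mt <- read_alignment_records(path_mt, ...)
  hdr_path <- if (tolower(tools::file_ext(path_mt)) == "sam") {
    sam_to_bam(path_mt, tempfile())
  } else path_mt
  targets <- Rsamtools::scanBamHeader(hdr_path)[[1]]$targets
  mt_primary <- mt[!mt$secondary, , drop = FALSE]
  ids <- unique(mt_primary$read_id)
  nuc <- NULL
  if (!is.null(path_nuc)) {
    nuc <- read_alignment_records(path_nuc, ...)
    nuc <- nuc[nuc$read_id %in% ids, , drop = FALSE]
  }
  mates_per_id <- table(paste(mt_primary$read_id))
  single <- as.integer(mates_per_id[ids]) < 2L
  names(single) <- ids
  rn <- if (nrow(mt_primary) > 0) mt_primary$rname[1] else names(targets)[1]
  structure(list(mt = mt_primary, nuc = nuc, ids = ids,
                 single_mate = single,
                 ref_name = rn,
                 ref_length = unname(targets[rn])),
            class = "aligned_pairs")
}

#' @export
length.aligned_pairs <- function(x) length(x$ids)

#' @export
print.aligned_pairs <- function(x, ...) {
  n_nuc <- if (is.null(x$nuc)) 0L else length(unique(x$nuc$read_id))
  cat("aligned_pairs: ", length(x$ids), " fragment(s) on '", x$ref_name,
      "' (", x$ref_length, " bp); ", n_nuc,
      " with nuclear evidence; ", sum(x$single_mate), " single-mate\n",
      sep = "")
  invisible(x)
}

#' Reference interval(s) spanned by a read pair
#'
#' Returns the minimal interval covering both mates of a fragment on its
#' reference. On a circular reference a fragment whose mates straddle the
#' origin is returned as two intervals (the tail of the reference and the
#' head); the interpretation — linear span versus wrap-around — is chosen as
#' whichever implies the shorter fragment.
#'
#' @param starts,ends 0-based half-open mate intervals (length 1 or 2).
#' @param ref_length Reference length in bp.
#' @param circular Is the reference circular?
#' @return data.frame with columns `start`, `end` (one or two rows).
#' @examples
#' fragment_interval(c(100, 300), c(250, 450), 16569)          # one interval
#' fragment_interval(c(16400, 0), c(16569, 150), 16569)        # wraps origin
#' @export
fragment_interval <- function(starts, ends, ref_length, circular = TRUE) {
  stopifnot(length(starts) == length(ends), length(starts) %in% 1:2,
            all(starts < ends), all(ends <= ref_length))
  if (length(starts) == 1L) {
    return(data.frame(start = starts, end = ends))
  }
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  linear <- max(e) - s[1]
  wrap <- (ref_length - s[2]) + e[1]
  if (circular && wrap < linear) {
    data.frame(start = c(s[2], 0L), end = c(ref_length, e[1]))
  } else {
    data.frame(start = s[1], end = max(e))
  }
}
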