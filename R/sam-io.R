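#' Write alignment records to a SAM file
#'
#' Serialises a record table (the internal representation used by
#' [read_alignment_records()] and produced by the simulator) to plain-text
#' SAM. Internal coordinates are 0-based half-open and are converted to the
#' 1-based SAM convention on output. Optional `NM`, `MD`, `NH` and `XQ`
#' columns become the corresponding auxiliary tags; extra per-read tags can
#' be supplied through `extra_tags`.
#'
#' @param records data.frame with at least `read_id`, `flag`, `rname`,
#'   `start` (0-based), `mapq`, `cigar`, `seq`, `qual`; optionally `rnext`,
#'   `pnext` (0-based), `tlen`, `nm`, `md`, `nh`, `xq`.
#' @param ref_lengths Named integer vector of reference sequence lengths for
#'   the `@SQ` header lines.
#' @param path Output SAM path.
#' @param extra_tags Optional character vector, one fully formatted tag
#'   string per record (e.g. `"XP:f:0.93\tXF:Z:PASS"`), appended verbatim.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_lengths, path, extra_tags = NULL) {
  stopifnot(is.data.frame(records), !is.null(names(ref_lengths)))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  n <- nrow(records)
  col_or <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, n)
  }
  rnext <- col_or("rnext", "*")
  pnext <- col_or("pnext", NA_integer_)
  tlen <- col_or("tlen", 0L)
  body <- character(0)
  if (n > 0) {
    tags <- character(n)
    add_tag <- function(tags, col, fmt, conv = identity) {
      if (!col %in% names(records)) return(tags)
      v <- records[[col]]
      ok <- !is.na(v)
      tags[ok] <- paste0(tags[ok], sprintf(fmt, conv(v[ok])))
      tags
    }
    tags <- add_tag(tags, "nm", "\tNM:i:%d", as.integer)
    tags <- add_tag(tags, "md", "\tMD:Z:%s", as.character)
    tags <- add_tag(tags, "nh", "\tNH:i:%d", as.integer)
    tags <- add_tag(tags, "xq", "\tXQ:i:%d", as.integer)
    if (!is.null(extra_tags)) {
      ok <- !is.na(extra_tags) & nzchar(extra_tags)
      tags[ok] <- paste0(tags[ok], "\t", extra_tags[ok])
    }
    body <- paste(records$read_id,
                  as.integer(records$flag),
                  records$rname,
                  as.integer(records$start) + 1L,
                  as.integer(records$mapq),
                  records$cigar,
                  rnext,
                  ifelse(is.na(pnext), 0L, as.integer(pnext) + 1L),
                  as.integer(tlen),
                  records$seq,
                  records$qual,
                  sep = "\t")
    body <- paste0(body, tags)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a SAM file to a sorted, indexed BAM
#'
#' Thin wrapper over [Rsamtools::asBam()].
#'
#' @param sam_path Input SAM path.
#' @param bam_path Output path without the `.bam` extension; defaults to the
#'   SAM path with its extension dropped.
#' @return Path of the BAM file created.
#' @export
sam_to_bam <- function(sam_path, bam_path = NULL) {
  if (is.null(bam_path)) {
    bam_path <- tools::file_path_sans_ext(sam_path)
  }
  Rsamtools::asBam(sam_path, destination = bam_path, overwrite = TRUE,
                   indexDestination = TRUE)
}
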