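#' Call mismatch variants from a SAM MD tag
#'
#' The basic variant caller used to obtain the per-read variant set for the
#' LD co-occurrence feature: reference mismatches are reconstructed from the
#' MD auxiliary tag, with the reference base taken from the tag and the
#' alternate base from the read sequence at the CIGAR-mapped offset.
#' Insertions produce no call (MD cannot encode them); deleted reference
#' bases (MD `^` syntax) are consumed without a call. SNV-only by design —
#' the LD table is keyed on substitutions.
#'
#' @param md MD tag string (e.g. `"10A139"`).
#' @param cigar CIGAR string.
#' @param seq Read sequence.
#' @param start 0-based reference start of the alignment.
#' @return data.frame with columns `position` (0-based reference locus),
#'   `ref`, `alt`; zero rows for a perfect match.
#' @examples
#' call_md_variants("150", "150M", strrep("A", 150), 0)     # no mismatch
#' @export
call_md_variants <- function(md, cigar, seq, start) {
  # fast path: pure-number MD with match-only CIGAR of the same length
  if (grepl("^[0-9]+$", md) && grepl("^[0-9]+[M=]$", cigar) &&
      as.integer(md) == as.integer(sub("[M=]$", "", cigar))) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_pos <- integer(0)   # reference position of each aligned (M) base
  read_off <- integer(0)  # 1-based read offset of each aligned base
  rp <- as.integer(start); ro <- 1L; n_del <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, rp + seq_len(len) - 1L)
      read_off <- c(read_off, ro + seq_len(len) - 1L)
      rp <- rp + len; ro <- ro + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len; if (op == "D") n_del <- n_del + len
    } else if (op %in% c("I", "S")) {
      ro <- ro + len
    } # H, P consume nothing
  }
  tokens <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  k <- 0L; n_md_del <- 0L
  out_pos <- integer(0); out_ref <- character(0); out_alt <- character(0)
  for (tok in tokens) {
    if (grepl("^[0-9]+$", tok)) {
      k <- k + as.integer(tok)
    } else if (startsWith(tok, "^")) {
      n_md_del <- n_md_del + nchar(tok) - 1L
    } else {
      k <- k + 1L
      if (k > length(ref_pos)) {
        stop("MD tag inconsistent with CIGAR (MD longer): MD=", md,
             " CIGAR=", cigar)
      }
      alt <- substr(seq, read_off[k], read_off[k])
      if (alt == tok) {
        stop("MD tag inconsistent with read sequence (ref == alt) at ",
             ref_pos[k], ": MD=", md)
      }
      out_pos <- c(out_pos, ref_pos[k])
      out_ref <- c(out_ref, tok)
      out_alt <- c(out_alt, alt)
    }
  }
  if (k != length(ref_pos) || n_md_del != n_del) {
    stop("MD tag inconsistent with CIGAR (aligned length ", length(ref_pos),
         ", MD covers ", k, "; deletions CIGAR ", n_del, " vs MD ",
         n_md_del, "): MD=", md, " CIGAR=", cigar)
  }
  data.frame(position = out_pos, ref = out_ref, alt = out_alt,
             stringsAsFactors = FALSE)
}

# MD-variant calls for a whole record table; returns a data.table with
# read_id, mate, position, ref, alt. Clean records are skipped wholesale.
records_md_variants <- function(records) {
  clean <- grepl("^[0-9]+$", records$md) &
    grepl("^[0-9]+[M=]$", records$cigar) &
    records$md == sub("[M=]$", "", records$cigar)
  need <- which(!clean)
  if (length(need) == 0) {
    return(data.table::data.table(read_id = character(0), mate = integer(0),
                                  position = integer(0), ref = character(0),
                                  alt = character(0)))
  }
  res <- lapply(need, function(i) {
    v <- call_md_variants(records$md[i], records$cigar[i], records$seq[i],
                          records$start[i])
    if (nrow(v) == 0) return(NULL)
    data.table::data.table(read_id = records$read_id[i],
                           mate = records$mate[i], v)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.table::data.table(read_id = character(0), mate = integer(0),
                                  position = integer(0), ref = character(0),
                                  alt = character(0)))
  }
  data.table::rbindlist(res)
}

#' LD co-occurrence score of the variants on a read pair
#'
#' The probability-of-co-occurrence summary of the fragment's variant set:
#' with fewer than two (deduplicated) variants there is no co-occurrence
#' evidence and the neutral score 1 is returned; with two or more, the score
#' is the minimum pairwise r² over all variant pairs, taking the configured
#' unseen-pair score for pairs absent from the table. A low score indicates
#' a variant combination never observed on real mitochondrial haplotypes —
#' the signature of a NUMT read.
#'
#' @param variants data.frame with columns `position`, `alt` (one row per
#'   variant on the fragment; duplicates across mates are collapsed).
#' @param ld An `ld_table`.
#' @param unseen_score Score for variant pairs not in the table (default 0,
#'   the most suspicious value).
#' @param neutral Score when fewer than 2 variants (default 1).
#' @return Numeric scalar in \[0, 1\].
#' @export
ld_fragment_score <- function(variants, ld, unseen_score = 0, neutral = 1) {
  if (is.null(variants) || nrow(variants) == 0) return(neutral)
  variants <- unique(variants[, c("position", "alt")])
  m <- nrow(variants)
  if (m < 2L) return(neutral)
  idx <- utils::combn(m, 2)
  keys <- paste0(variants$position[idx[1, ]], ":", variants$alt[idx[1, ]],
                 "|", variants$position[idx[2, ]], ":",
                 variants$alt[idx[2, ]])
  vals <- unlist(mget(keys, envir = ld$lookup, ifnotfound = unseen_score),
                 use.names = FALSE)
  min(vals)
}

#' Read a NUMT region list from BED
#'
#' The BED gives, per NUMT, the *mitochondrial* interval the NUMT mirrors
#' (the coordinates in which fragment overlap is computable); the name
#' column identifies the NUMT and an optional fifth column may carry the
#' nuclear locus for reporting. Coordinates are BED-standard 0-based
#' half-open.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name` and, when
#'   present, `nuclear_locus`.
#' @export
read_numt_bed <- function(path) {
  first <- readLines(path, n = 1)
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  extra <- if (ncol >= 5) c(nuclear_locus = "character") else character(0)
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else
                     paste0("numt", seq_along(gr)),
                   stringsAsFactors = FALSE)
  if (ncol >= 5) df$nuclear_locus <- gr$nuclear_locus
  df
}

#' Fraction of a fragment overlapped by known NUMT regions
#'
#' Computes |fragment ∩ union(NUMT intervals)| / |fragment| on the
#' mitochondrial reference. Origin-spanning fragments are handled through
#' their two sub-intervals. Invariant under splitting NUMT intervals into
#' adjacent pieces and under fragment interval order.
#'
#' @param fragment data.frame of 0-based half-open intervals (`start`,
#'   `end`), as returned by [fragment_interval()].
#' @param numts data.frame of NUMT mitochondrial intervals (`start`, `end`,
#'   0-based half-open; see [read_numt_bed()]).
#' @return Numeric in \[0, 1\].
#' @export
numt_overlap_fraction <- function(fragment, numts) {
  if (is.null(fragment) || nrow(fragment) == 0 ||
      sum(fragment$end - fragment$start) <= 0) {
    stop("empty fragment interval")
  }
  frag <- IRanges::IRanges(start = fragment$start + 1L, end = fragment$end)
  if (is.null(numts) || nrow(numts) == 0) return(0)
  nr <- IRanges::reduce(IRanges::IRanges(start = numts$start + 1L,
                                         end = numts$end))
  ov <- sum(IRanges::width(IRanges::intersect(frag, nr)))
  ov / sum(IRanges::width(frag))
}

#' Feature matrix for classified read pairs
#'
#' Turns an `aligned_pairs` container into the per-fragment feature table
#' the random forest consumes. Features per fragment:
#' \describe{
#'   \item{mt_edit_distance}{Sum of mitochondrial `NM` over the mates.}
#'   \item{nuc_edit_distance}{Best nuclear explanation: per mate, the
#'     minimum `NM` over that mate's nuclear alignments, summed over mates.
#'     A mate (or fragment) without any nuclear alignment contributes its
#'     read length — the no-nuclear-hit sentinel, maximally unlike a NUMT.}
#'   \item{mt_alignments, nuc_alignments}{Alignment counts (`NH`); 0 when
#'     absent on the nuclear side.}
#'   \item{mapping_score, mapping_quality}{Mean `XQ` / mapping quality over
#'     the mitochondrial mates.}
#'   \item{mt_ld}{[ld_fragment_score()] of the fragment's MD-called
#'     variants.}
#'   \item{numt_overlap}{[numt_overlap_fraction()] of the fragment span.}
#' }
#'
#' @param pairs An `aligned_pairs` object from [load_pairs()].
#' @param ld An `ld_table`.
#' @param numts NUMT region data.frame ([read_numt_bed()]), or `NULL`.
#' @param unseen_score Unseen-pair score for [ld_fragment_score()].
#' @param nuc_sentinel No-nuclear-hit sentinel for `nuc_edit_distance`;
#'   default `NULL` uses each fragment's read-pair length.
#' @param labels Optional named character vector (`read_id` -> class label
#'   `"mtDNA"`/`"NUMT"`) attached as a `label` column.
#' @param circular Treat the mitochondrial reference as circular when
#'   computing fragment spans.
#' @return data.frame, one row per fragment: `read_id`, the eight features
#'   and optionally `label`.
#' @export
featurize <- function(pairs, ld, numts = NULL, unseen_score = 0,
                      nuc_sentinel = NULL, labels = NULL, circular = TRUE) {
  stopifnot(inherits(pairs, "aligned_pairs"))
  mt <- data.table::as.data.table(pairs$mt)
  if (nrow(mt) == 0) {
    out <- data.frame(read_id = character(0), mt_edit_distance = numeric(0),
                      nuc_edit_distance = numeric(0),
                      mt_alignments = integer(0), nuc_alignments = integer(0),
                      mapping_score = numeric(0), mapping_quality = numeric(0),
                      mt_ld = numeric(0), numt_overlap = numeric(0))
    if (!is.null(labels)) out$label <- character(0)
    return(out)
  }
  read_id <- position <- alt <- nm <- nh <- mapq <- xq <- seqlen <- NULL
  mt[, seqlen := nchar(seq)]
  agg <- mt[, list(mt_edit_distance = sum(nm),
                   mt_alignments = max(nh),
                   mapping_score = mean(xq),
                   mapping_quality = mean(mapq),
                   pair_len = sum(seqlen),
                   n_mates = .N), by = read_id]

  # nuclear side: per-mate best alignment, summed; missing mates penalised
  mate_len <- mt[, list(len = nchar(seq)[1]),
                 by = list(read_id, mate)]
  if (!is.null(pairs$nuc) && nrow(pairs$nuc) > 0) {
    nuc <- data.table::as.data.table(pairs$nuc)
    nuc_mate <- nuc[, list(nuc_nm = min(nm), nuc_nh = max(nh)),
                    by = list(read_id, mate)]
  } else {
    nuc_mate <- data.table::data.table(read_id = character(0),
                                       mate = integer(0),
                                       nuc_nm = integer(0),
                                       nuc_nh = integer(0))
  }
  mm <- merge(mate_len, nuc_mate, by = c("read_id", "mate"), all.x = TRUE)
  sent_default <- is.null(nuc_sentinel)
  nuc_nm <- nuc_nh <- len <- NULL
  mm[, nuc_nm := ifelse(is.na(nuc_nm),
                        if (sent_default) len else NA_real_, nuc_nm)]
  nuc_agg <- mm[, list(
    nuc_edit_distance = if (sent_default) sum(nuc_nm) else {
      if (all(is.na(nuc_nm))) nuc_sentinel else
        sum(ifelse(is.na(nuc_nm), nuc_sentinel / length(nuc_nm), nuc_nm))
    },
    nuc_alignments = sum(nuc_nh, na.rm = TRUE)), by = read_id]
  agg <- merge(agg, nuc_agg, by = "read_id", all.x = TRUE)

  # fragment spans (vectorised linear-vs-wrap choice)
  L <- pairs$ref_length
  sp <- mt[, {
    if (.N == 1L) list(start = start, end = end) else {
      o <- order(start)
      s <- start[o]; e <- end[o]
      linear <- max(e) - s[1]
      wrap <- (L - s[2]) + e[1]
      if (circular && wrap < linear) {
        list(start = c(s[2], 0L), end = c(L, e[1]))
      } else list(start = s[1], end = max(e))
    }
  }, by = read_id]

  # NUMT overlap per fragment via interval intersection
  if (!is.null(numts) && nrow(numts) > 0) {
    nr <- IRanges::reduce(IRanges::IRanges(start = numts$start + 1L,
                                           end = numts$end))
    frag_ir <- IRanges::IRanges(start = sp$start + 1L, end = sp$end)
    hits <- IRanges::findOverlaps(frag_ir, nr)
    ovw <- numeric(nrow(sp))
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      w <- pmin(IRanges::end(frag_ir)[qi], IRanges::end(nr)[si]) -
        pmax(IRanges::start(frag_ir)[qi], IRanges::start(nr)[si]) + 1L
      for (k in seq_along(qi)) ovw[qi[k]] <- ovw[qi[k]] + w[k]
    }
    sp$ov <- ovw
    ov_dt <- data.table::as.data.table(sp)[, list(
      numt_overlap = sum(ov) / sum(end - start)), by = read_id]
  } else {
    ov_dt <- data.table::data.table(read_id = agg$read_id, numt_overlap = 0)
  }
  agg <- merge(agg, ov_dt, by = "read_id", all.x = TRUE)

  # LD co-occurrence score from deduplicated MD variants
  vars <- records_md_variants(pairs$mt)
  ld_score <- rep(1, nrow(agg))
  names(ld_score) <- agg$read_id
  if (nrow(vars) > 0) {
    vars <- vars[alt != "N"]
    vars <- unique(vars[, list(read_id, position, alt)])
    counts <- vars[, .N, by = read_id]
    multi <- counts$read_id[counts$N >= 2L]
    if (length(multi)) {
      vs <- split(vars[read_id %in% multi], by = "read_id")
      for (id in names(vs)) {
        ld_score[[id]] <- ld_fragment_score(as.data.frame(vs[[id]]), ld,
                                            unseen_score = unseen_score)
      }
    }
  }
  agg$mt_ld <- unname(ld_score[agg$read_id])

  out <- data.frame(read_id = agg$read_id,
                    mt_edit_distance = as.numeric(agg$mt_edit_distance),
                    nuc_edit_distance = as.numeric(agg$nuc_edit_distance),
                    mt_alignments = as.integer(agg$mt_alignments),
                    nuc_alignments = as.integer(ifelse(
                      is.na(agg$nuc_alignments), 0L, agg$nuc_alignments)),
                    mapping_score = agg$mapping_score,
                    mapping_quality = agg$mapping_quality,
                    mt_ld = agg$mt_ld,
                    numt_overlap = agg$numt_overlap,
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- unname(labels[out$read_id])
  stopifnot(all(is.finite(as.matrix(out[, feature_names_all()]))))
  out
}

# canonical feature name sets
feature_names_all <- function() {
  c("mt_edit_distance", "nuc_edit_distance", "mt_alignments",
    "nuc_alignments", "mapping_score", "mapping_quality", "mt_ld",
    "numt_overlap")
}

#' @rdname featurize
#' @export
final_model_features <- function() {
  c("mt_edit_distance", "nuc_edit_distance", "mt_ld", "numt_overlap")
}

#' Write a feature matrix as TSV
#'
#' @param features data.frame from [featurize()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
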