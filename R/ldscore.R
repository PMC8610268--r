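#' Haploid linkage-disequilibrium r-squared between two sites
#'
#' Computes the standard haploid LD statistic r² = D² / (p_i q_i p_j q_j)
#' with D = p_ij − p_i p_j, over pairwise-complete (both non-missing)
#' samples. Mitochondrial DNA is effectively haploid, so allele-level r² is
#' used rather than genotype r²; for 0/1 vectors it equals the squared
#' Pearson correlation.
#'
#' @param x,y Numeric or integer vectors of allele codes (0 = reference,
#'   1 = alternate, `NA` = missing), same length.
#' @return r² in \[0, 1\], or `NA_real_` when either site is monomorphic
#'   after removal of missing entries (r² is then undefined).
#' @examples
#' r2(c(0, 0, 1, 1), c(0, 1, 0, 1))  # independent by construction: 0
#' r2(c(0, 1, 0, 1), c(0, 1, 0, 1))  # identical: 1
#' @export
r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  pi_ <- mean(x); pj <- mean(y)
  if (length(x) < 2L || pi_ %in% c(0, 1) || pj %in% c(0, 1)) return(NA_real_)
  d <- mean(x * y) - pi_ * pj
  val <- d^2 / (pi_ * (1 - pi_) * pj * (1 - pj))
  min(max(val, 0), 1)
}

#' Build a haplotype matrix from an aligned multi-FASTA panel
#'
#' Calls per-column alleles of a pre-aligned panel of full-length
#' mitochondrial sequences against a reference. Columns whose non-reference
#' content is a single substitution become biallelic sites; multi-allelic
#' columns are split into one biallelic site per alternate allele (samples
#' carrying a different alternate are coded missing at that site). Gap and
#' `N` characters are coded missing.
#'
#' @param path Aligned multi-FASTA; every sequence must have the reference
#'   length.
#' @param reference [Biostrings::DNAStringSet] of length 1 (see
#'   [mt_reference()]).
#' @return An object of class `haplotype_matrix`: list with `alleles`
#'   (samples x sites matrix of 0/1/NA), `sites` (data.frame `position`
#'   (0-based), `ref`, `alt`) and `n_samples`.
#' @export
read_haplotype_fasta <- function(path, reference) {
  seqs <- Biostrings::readDNAStringSet(path)
  ref_chars <- ref_as_chars(reference)
  L <- length(ref_chars)
  bad <- which(Biostrings::width(seqs) != L)
  if (length(bad)) {
    stop("sequence length differs from reference (", L, " bp): ",
         paste(names(seqs)[utils::head(bad, 3)], collapse = ", "))
  }
  m <- as.matrix(seqs)  # samples x positions, characters
  haplotype_matrix_from_chars(m, ref_chars)
}

# Build the site table from a character matrix (samples x positions).
haplotype_matrix_from_chars <- function(m, ref_chars) {
  n <- nrow(m)
  stopifnot(n >= 2L)
  missing_code <- !(m %in% c("A", "C", "G", "T"))
  dim(missing_code) <- dim(m)
  diff_any <- vapply(seq_len(ncol(m)), function(j) {
    any(m[, j] != ref_chars[j] & !missing_code[, j])
  }, logical(1))
  sites <- list(); alleles <- list()
  for (j in which(diff_any)) {
    col <- m[, j]
    col[missing_code[, j]] <- NA
    alts <- setdiff(unique(col[!is.na(col)]), ref_chars[j])
    for (a in alts) {
      v <- ifelse(is.na(col), NA_integer_,
                  ifelse(col == a, 1L, ifelse(col == ref_chars[j], 0L,
                                              NA_integer_)))
      sites[[length(sites) + 1L]] <-
        data.frame(position = j - 1L, ref = ref_chars[j], alt = a,
                   stringsAsFactors = FALSE)
      alleles[[length(alleles) + 1L]] <- v
    }
  }
  if (length(sites) == 0) {
    sites_df <- data.frame(position = integer(0), ref = character(0),
                           alt = character(0), stringsAsFactors = FALSE)
    am <- matrix(integer(0), nrow = n, ncol = 0)
  } else {
    sites_df <- do.call(rbind, sites)
    am <- do.call(cbind, alleles)
    o <- order(sites_df$position, sites_df$alt)
    sites_df <- sites_df[o, , drop = FALSE]
    rownames(sites_df) <- NULL
    am <- am[, o, drop = FALSE]
  }
  structure(list(alleles = am, sites = sites_df, n_samples = n),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix: ", x$n_samples, " samples x ", nrow(x$sites),
      " biallelic site(s)\n", sep = "")
  invisible(x)
}

#' Build a pairwise LD r-squared table over mitochondrial sites
#'
#' Computes r² for every pair of sites passing a minor-allele-frequency
#' filter (and an optional pairwise distance cap), producing the lookup used
#' by the LD co-occurrence read feature. Pairs for which r² is undefined
#' (monomorphic after missing-data removal) are excluded rather than stored
#' as zero. mtDNA LD is genome-wide, so no distance cap is applied by
#' default.
#'
#' @param h A `haplotype_matrix` (see [read_haplotype_fasta()]).
#' @param min_maf Minimum minor allele frequency for a site to enter the
#'   table (computed over non-missing samples). Default 0.01.
#' @param max_pair_distance Optional cap on |position_i − position_j|.
#' @return An object of class `ld_table`: list with `pairs` (data.table
#'   `pos_i`, `alt_i`, `pos_j`, `alt_j`, `r2`, canonical order i < j),
#'   `lookup` (environment keyed `"pos:alt|pos:alt"`), `min_maf`,
#'   `n_samples` and `sites`.
#' @export
build_ld_table <- function(h, min_maf = 0.01, max_pair_distance = NULL) {
  stopifnot(inherits(h, "haplotype_matrix"))
  am <- h$alleles
  maf <- apply(am, 2, function(v) {
    p <- mean(v, na.rm = TRUE); min(p, 1 - p)
  })
  keep <- which(!is.na(maf) & maf >= min_maf)
  if (length(keep) == 0) {
    warning("no sites pass min_maf = ", min_maf, "; LD table is empty")
  }
  sites <- h$sites[keep, , drop = FALSE]
  am <- am[, keep, drop = FALSE]
  rows <- list()
  if (length(keep) >= 2) {
    idx <- utils::combn(seq_along(keep), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      if (!is.null(max_pair_distance) &&
          abs(sites$position[i] - sites$position[j]) > max_pair_distance) next
      val <- r2(am[, i], am[, j])
      if (is.na(val)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pos_i = sites$position[i], alt_i = sites$alt[i],
        pos_j = sites$position[j], alt_j = sites$alt[j],
        r2 = val, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(pos_i = integer(0), alt_i = character(0),
                           pos_j = integer(0), alt_j = character(0),
                           r2 = numeric(0))
  lookup <- new.env(parent = emptyenv(), size = max(2L * nrow(pairs), 29L))
  if (nrow(pairs)) {
    k1 <- paste0(pairs$pos_i, ":", pairs$alt_i, "|", pairs$pos_j, ":",
                 pairs$alt_j)
    k2 <- paste0(pairs$pos_j, ":", pairs$alt_j, "|", pairs$pos_i, ":",
                 pairs$alt_i)
    for (i in seq_len(nrow(pairs))) {
      assign(k1[i], pairs$r2[i], envir = lookup)
      assign(k2[i], pairs$r2[i], envir = lookup)
    }
  }
  structure(list(pairs = pairs, lookup = lookup, min_maf = min_maf,
                 n_samples = h$n_samples, sites = sites),
            class = "ld_table")
}

#' Look up the r-squared of a site pair in an LD table
#'
#' Symmetric in the two sites. Returns `default` (typically the configured
#' unseen-pair score) when the pair is absent.
#'
#' @param ld An `ld_table`.
#' @param pos_i,alt_i,pos_j,alt_j Site coordinates (0-based) and alternate
#'   alleles.
#' @param default Value for pairs not in the table.
#' @export
ld_lookup <- function(ld, pos_i, alt_i, pos_j, alt_j, default = NA_real_) {
  key <- paste0(pos_i, ":", alt_i, "|", pos_j, ":", alt_j)
  val <- mget(key, envir = ld$lookup, ifnotfound = default)
  unname(unlist(val))
}

#' @export
print.ld_table <- function(x, ...) {
  cat("ld_table: ", nrow(x$pairs), " site pair(s) over ", nrow(x$sites),
      " site(s); built from ", x$n_samples, " haplotypes (min MAF ",
      x$min_maf, ")\n", sep = "")
  invisible(x)
}

#' Serialise / restore an LD table as tab-separated text
#'
#' The on-disk form is a TSV of `pos_i`, `alt_i`, `pos_j`, `alt_j`, `r2`
#' preceded by header comments recording the source sample count and MAF
#' filter — stable and diffable.
#'
#' @param ld An `ld_table`.
#' @param path Output path.
#' @return `path` invisibly (`write_ld_table`); an `ld_table`
#'   (`read_ld_table`).
#' @export
write_ld_table <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#n_samples=%d", ld$n_samples),
               sprintf("#min_maf=%g", ld$min_maf),
               "pos_i\talt_i\tpos_j\talt_j\tr2"), con)
  if (nrow(ld$pairs)) {
    utils::write.table(ld$pairs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ld_table
#' @export
read_ld_table <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    m <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^#", key, "="), "", m[1])) else default
  }
  pairs <- data.table::fread(path, skip = length(meta), header = TRUE,
                             colClasses = list(character = c("alt_i", "alt_j")))
  lookup <- new.env(parent = emptyenv(), size = max(2L * nrow(pairs), 29L))
  if (nrow(pairs)) {
    k1 <- paste0(pairs$pos_i, ":", pairs$alt_i, "|", pairs$pos_j, ":",
                 pairs$alt_j)
    k2 <- paste0(pairs$pos_j, ":", pairs$alt_j, "|", pairs$pos_i, ":",
                 pairs$alt_i)
    for (i in seq_len(nrow(pairs))) {
      assign(k1[i], pairs$r2[i], envir = lookup)
      assign(k2[i], pairs$r2[i], envir = lookup)
    }
  }
  sites <- unique(data.frame(
    position = c(pairs$pos_i, pairs$pos_j),
    alt = c(pairs$alt_i, pairs$alt_j), stringsAsFactors = FALSE))
  structure(list(pairs = pairs, lookup = lookup,
                 min_maf = get_meta("min_maf", NA_real_),
                 n_samples = as.integer(get_meta("n_samples", NA)),
                 sites = sites),
            class = "ld_table")
}
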