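#' Simulation configuration
#'
#' Bundles the parameters of the labelled read simulator that stands in for
#' the wet-lab training and benchmark libraries: an mtDNA-enriched library
#' (pure mtDNA fragments), a rho-zero library (NUMT fragments only — cells
#' depleted of mtDNA), and WGS-like mixtures of the two. NUMT specifications
#' follow the biology of human NUMTs: 64-100% sequence identity to mtDNA
#' and lengths from 40 bp up to nearly the whole mitochondrial genome.
#'
#' @param seed Integer seed; all outputs are deterministic per seed.
#' @param mt_reference Mitochondrial reference ([mt_reference()] default).
#' @param haplotype_variants data.frame (`position` 0-based, `alt`): the
#'   sample's fixed haplotype relative to the reference, carried by every
#'   mtDNA fragment.
#' @param heteroplasmies data.frame (`position`, `alt`, `fraction`):
#'   heteroplasmic variants planted per fragment with probability
#'   `fraction`.
#' @param numt_spec data.frame (`start`, `end` 0-based half-open mtDNA
#'   interval, `identity` in \[0.64, 1\]): the NUMTs present in the nuclear
#'   genome. Lengths must be at least 40 bp.
#' @param read_length Read length in bp (default 150, the common paired-end
#'   configuration).
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param depth Target mean coverage.
#' @param error_rate Per-base substitution sequencing error rate (default
#'   0.002, Illumina-like). Errors are substitution-only.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, mt_reference = numtsieve::mt_reference(),
                       haplotype_variants = NULL, heteroplasmies = NULL,
                       numt_spec = NULL, read_length = 150,
                       fragment_mean = 350, fragment_sd = 35, depth = 200,
                       error_rate = 0.002) {
  L <- Biostrings::width(mt_reference)[1]
  chk_vars <- function(df, need) {
    if (is.null(df)) return(invisible())
    stopifnot(all(need %in% names(df)), all(df$position >= 0),
              all(df$position < L))
    if ("fraction" %in% need) {
      stopifnot(all(df$fraction >= 0 & df$fraction <= 1))
    }
  }
  chk_vars(haplotype_variants, c("position", "alt"))
  chk_vars(heteroplasmies, c("position", "alt", "fraction"))
  if (!is.null(numt_spec)) {
    stopifnot(all(c("start", "end", "identity") %in% names(numt_spec)))
    if (any(numt_spec$start < 0 | numt_spec$end > L)) {
      stop("NUMT interval outside the mitochondrial reference")
    }
    len <- numt_spec$end - numt_spec$start
    if (any(len < 40)) stop("NUMT length below 40 bp: human NUMTs are >= 40 bp")
    if (any(numt_spec$identity < 0.64 | numt_spec$identity > 1)) {
      stop("NUMT identity must be within [0.64, 1]")
    }
  }
  structure(list(seed = as.integer(seed), mt_reference = mt_reference,
                 haplotype_variants = haplotype_variants,
                 heteroplasmies = heteroplasmies, numt_spec = numt_spec,
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth, error_rate = error_rate,
                 ref_length = L),
            class = "sim_config")
}

#' Simulate NUMT-bearing nuclear sequences
#'
#' Realises each NUMT of `cfg$numt_spec` as a diverged copy of its source
#' mitochondrial interval embedded in a random nuclear flank (one synthetic
#' nuclear contig per NUMT). Divergence is applied as random substitutions:
#' `round((1 - identity) * length)` positions are mutated, so the realised
#' identity is within a percentage point of the target (length permitting).
#'
#' @param cfg A [sim_config()] with a non-empty `numt_spec`.
#' @param flank Nuclear flank length on each side (bp).
#' @return List of class `sim_numts`: `sequences` (nuclear
#'   [Biostrings::DNAStringSet]), `truth` (data.frame `chrom`, `nuc_start`,
#'   `nuc_end`, `mt_start`, `mt_end`, `identity_target`,
#'   `identity_realized`, `name`), `numt_chars` (list of character vectors
#'   of each NUMT's diverged sequence), `flank`.
#' @export
simulate_numt_sequences <- function(cfg, flank = 500L) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- cfg$numt_spec
  if (is.null(spec) || nrow(spec) == 0) stop("cfg$numt_spec is empty")
  ref_chars <- ref_as_chars(cfg$mt_reference)
  bases <- c("A", "C", "G", "T")
  with_local_seed(cfg$seed + 101L, {
    seqs <- character(nrow(spec))
    chars <- vector("list", nrow(spec))
    subs <- vector("list", nrow(spec))
    realized <- numeric(nrow(spec))
    nm <- if ("name" %in% names(spec)) spec$name else
      paste0("numt", seq_len(nrow(spec)))
    for (k in seq_len(nrow(spec))) {
      src <- ref_chars[(spec$start[k] + 1L):spec$end[k]]
      len <- length(src)
      n_sub <- round((1 - spec$identity[k]) * len)
      pos <- if (n_sub > 0) sort(sample.int(len, n_sub)) else integer(0)
      numt <- src
      for (p in pos) numt[p] <- sample(setdiff(bases, numt[p]), 1)
      realized[k] <- mean(numt == src)
      chars[[k]] <- numt
      subs[[k]] <- data.frame(
        mt_position = spec$start[k] + pos - 1L,
        base = numt[pos], stringsAsFactors = FALSE)
      left <- paste(sample(bases, flank, replace = TRUE), collapse = "")
      right <- paste(sample(bases, flank, replace = TRUE), collapse = "")
      seqs[k] <- paste0(left, paste(numt, collapse = ""), right)
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- paste0("chrN_", nm)
    truth <- data.frame(chrom = names(dss),
                        nuc_start = flank,
                        nuc_end = flank + (spec$end - spec$start),
                        mt_start = spec$start, mt_end = spec$end,
                        identity_target = spec$identity,
                        identity_realized = realized,
                        name = nm, stringsAsFactors = FALSE)
    structure(list(sequences = dss, truth = truth, numt_chars = chars,
                   substitutions = subs, flank = as.integer(flank)),
              class = "sim_numts")
  })
}

#' Write the NUMT truth intervals as a BED file
#'
#' Emits the mitochondrial intervals each NUMT mirrors — the coordinate
#' system in which fragment overlap is computed — with the nuclear locus in
#' a fifth column.
#'
#' @param numts A `sim_numts` object.
#' @param path Output BED path.
#' @param chrom Mitochondrial contig name.
#' @export
write_numt_bed <- function(numts, path, chrom = "chrM") {
  tr <- numts$truth
  df <- data.frame(chrom = chrom, start = tr$mt_start, end = tr$mt_end,
                   name = tr$name,
                   nuclear_locus = sprintf("%s:%d-%d", tr$chrom,
                                           tr$nuc_start, tr$nuc_end))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a labelled paired-end sequencing library
#'
#' Generates aligned read pairs with complete truth labels, emulating the
#' libraries the classifier is trained and tested on:
#' \describe{
#'   \item{`"mtDNA"`}{a pure mtDNA-enriched library: fragments sampled
#'     uniformly around the circular mitochondrial genome, carrying the
#'     sample haplotype and, per fragment with probability `fraction`, the
#'     configured heteroplasmic variants;}
#'   \item{`"rho_zero"` / `"numt"`}{a library of NUMT-derived fragments
#'     only (what an mtDNA-depleted cell line yields after alignment to the
#'     mitochondrial reference);}
#'   \item{`"mixture"`}{a WGS-like mixture of the two at the given NUMT
#'     fraction.}
#' }
#' Each fragment yields mitochondrial alignment records (position, CIGAR,
#' `NM`/`MD`/`NH`/`XQ` tags computed against the mitochondrial reference)
#' and, where a nuclear alignment exists — always for NUMT fragments, and
#' for mtDNA fragments whose mates fall inside a NUMT-mirrored interval —
#' nuclear alignment records against the synthetic NUMT-bearing contigs.
#' This bypasses any external aligner while matching the pipeline's input
#' contract; `emit_fastq = TRUE` additionally writes the raw reads for use
#' with a real aligner.
#'
#' Fragments whose individual mates would cross the circular origin are
#' resampled (pairs *straddling* the origin, one mate on each side, are
#' kept), and sequencing errors are substitution-only, matching the
#' SNV-only variant caller.
#'
#' @param cfg A [sim_config()].
#' @param source One of `"mixture"`, `"mtDNA"`, `"numt"`, `"rho_zero"`.
#' @param numt_fraction Fraction of NUMT fragments in a mixture.
#' @param out_dir Directory for the SAM/FASTQ outputs.
#' @param prefix File name prefix (defaults to `source`).
#' @param emit_fastq Also write FASTQ mate files.
#' @return List of class `sim_reads`: `truth` (fragment table: `read_id`,
#'   `label`, `source`, `frag_start`, `frag_end`, `has_nuclear`),
#'   `het_truth` (planted heteroplasmic alleles per fragment), `mt_sam`,
#'   `nuc_sam` (`NA` if no nuclear records), FASTQ paths when requested,
#'   and `cfg`.
#' @export
simulate_reads <- function(cfg, source = c("mixture", "mtDNA", "numt",
                                           "rho_zero"),
                           numt_fraction = 0.2, out_dir = tempfile("sim"),
                           prefix = NULL, emit_fastq = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  source <- match.arg(source)
  if (is.null(prefix)) prefix <- source
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_str <- as.character(cfg$mt_reference[[1]])
  ref_chars <- ref_as_chars(cfg$mt_reference)
  L <- cfg$ref_length
  rl <- cfg$read_length
  chrom <- ref_name(cfg$mt_reference)
  bases <- c("A", "C", "G", "T")

  numts <- NULL
  if (source != "mtDNA") {
    if (is.null(cfg$numt_spec)) stop("source '", source,
                                     "' requires cfg$numt_spec")
    numts <- simulate_numt_sequences(cfg)
  } else if (!is.null(cfg$numt_spec)) {
    numts <- simulate_numt_sequences(cfg)
  }

  seed_off <- c(mixture = 11L, mtDNA = 12L, numt = 13L, rho_zero = 14L)
  with_local_seed(cfg$seed + seed_off[[source]], {
    # ---- fragment layout -------------------------------------------------
    # `depth` is the coverage of the sequenced material: the mitochondrial
    # genome for mtDNA-bearing libraries, the NUMT complement for a
    # NUMT-only (rho-zero) library
    if (source %in% c("numt", "rho_zero")) {
      numt_len_total <- sum(numts$truth$mt_end - numts$truth$mt_start)
      n_total <- max(1L, round(numt_len_total * cfg$depth / (2 * rl)))
      n_numt <- n_total
      n_mt <- 0L
    } else {
      n_total <- max(1L, round(L * cfg$depth / (2 * rl)))
      n_numt <- if (source == "mixture") round(n_total * numt_fraction)
                else 0L
      n_mt <- n_total - n_numt
    }

    frag <- list()
    if (n_mt > 0) {
      fl <- pmin(pmax(round(stats::rnorm(n_mt, cfg$fragment_mean,
                                         cfg$fragment_sd)), rl), L - 1L)
      s <- sample.int(L, n_mt, replace = TRUE) - 1L
      # resample starts whose mates individually cross the origin
      repeat {
        s2 <- (s + fl - rl) %% L
        bad <- (s + rl > L) | (s2 + rl > L)
        if (!any(bad)) break
        s[bad] <- sample.int(L, sum(bad), replace = TRUE) - 1L
      }
      frag$mt <- data.table::data.table(
        label = "mtDNA", src = 0L, fstart = s, flen = fl,
        m1s = s, m2s = (s + fl - rl) %% L, m1l = rl, m2l = rl)
    }
    if (n_numt > 0) {
      tr <- numts$truth
      numt_len <- tr$mt_end - tr$mt_start
      pick <- sample.int(nrow(tr), n_numt, replace = TRUE,
                         prob = numt_len / sum(numt_len))
      fl <- pmin(pmax(round(stats::rnorm(n_numt, cfg$fragment_mean,
                                         cfg$fragment_sd)), 40L),
                 numt_len[pick])
      mrl <- pmin(rl, fl)
      s_local <- floor(stats::runif(n_numt) * (numt_len[pick] - fl + 1))
      s <- tr$mt_start[pick] + s_local
      frag$numt <- data.table::data.table(
        label = "NUMT", src = pick, fstart = s, flen = fl,
        m1s = s, m2s = s + fl - mrl, m1l = mrl, m2l = mrl)
    }
    frags <- data.table::rbindlist(frag)
    n_frag <- nrow(frags)
    frags$read_id <- sprintf("%s_f%06d", prefix, seq_len(n_frag))

    # planted heteroplasmic alleles, per fragment
    het_truth <- data.table::data.table(read_id = character(0),
                                        position = integer(0),
                                        alt = character(0))
    if (!is.null(cfg$heteroplasmies) && n_mt > 0) {
      hets <- cfg$heteroplasmies
      rows <- list()
      is_mt <- frags$label == "mtDNA"
      for (v in seq_len(nrow(hets))) {
        carrier <- is_mt & stats::rbinom(n_frag, 1L, hets$fraction[v]) == 1L
        if (any(carrier)) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            read_id = frags$read_id[carrier],
            position = hets$position[v], alt = hets$alt[v])
        }
      }
      if (length(rows)) het_truth <- data.table::rbindlist(rows)
    }

    # ---- per-mate read table --------------------------------------------
    reads <- data.table::rbindlist(list(
      data.table::data.table(read_id = frags$read_id, mate = 1L,
                             label = frags$label, src = frags$src,
                             start = frags$m1s, len = frags$m1l),
      data.table::data.table(read_id = frags$read_id, mate = 2L,
                             label = frags$label, src = frags$src,
                             start = frags$m2s, len = frags$m2l)))
    reads$end <- reads$start + reads$len
    nr <- nrow(reads)
    reads$idx <- seq_len(nr)
    seqs <- substring(ref_str, reads$start + 1L, reads$end)

    # ---- edits: NUMT divergence, haplotype, heteroplasmy ----------------
    edits <- list()
    if (!is.null(numts)) {
      for (k in seq_along(numts$numt_chars)) {
        rows <- which(reads$src == k)
        if (!length(rows)) next
        sub <- numts$substitutions[[k]]
        if (nrow(sub) == 0) next
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(sub$mt_position + 1L, sub$mt_position + 1L),
          IRanges::IRanges(reads$start[rows] + 1L, reads$end[rows]))
        if (!length(ov)) next
        qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        edits[[length(edits) + 1L]] <- data.table::data.table(
          idx = reads$idx[rows[si]],
          off = sub$mt_position[qi] - reads$start[rows[si]] + 1L,
          base = sub$base[qi])
      }
    }
    plant_var <- function(var_df, id_filter = NULL) {
      out <- list()
      for (v in seq_len(nrow(var_df))) {
        p <- var_df$position[v]
        rows <- which(reads$label == "mtDNA" & reads$start <= p &
                      reads$end > p)
        if (!is.null(id_filter)) {
          rows <- rows[reads$read_id[rows] %in% id_filter[[v]]]
        }
        if (length(rows)) {
          out[[length(out) + 1L]] <- data.table::data.table(
            idx = reads$idx[rows], off = p - reads$start[rows] + 1L,
            base = var_df$alt[v])
        }
      }
      out
    }
    if (!is.null(cfg$haplotype_variants) && n_mt > 0) {
      edits <- c(edits, plant_var(cfg$haplotype_variants))
    }
    if (nrow(het_truth) > 0) {
      hv <- unique(het_truth[, list(position, alt)])
      carriers <- lapply(seq_len(nrow(hv)), function(v) {
        het_truth$read_id[het_truth$position == hv$position[v] &
                          het_truth$alt == hv$alt[v]]
      })
      edits <- c(edits, plant_var(hv, carriers))
    }
    edits <- if (length(edits)) data.table::rbindlist(edits) else
      data.table::data.table(idx = integer(0), off = integer(0),
                             base = character(0))

    # sequencing errors (substitution-only)
    n_err <- stats::rbinom(nr, reads$len, cfg$error_rate)
    err_rows <- which(n_err > 0)
    err <- list()
    for (i in err_rows) {
      off <- sample.int(reads$len[i], n_err[i])
      err[[length(err) + 1L]] <- data.table::data.table(
        idx = i, off = off, base = NA_character_)  # base drawn at apply time
    }
    err <- if (length(err)) data.table::rbindlist(err) else
      data.table::data.table(idx = integer(0), off = integer(0),
                             base = character(0))

    # apply edits then errors
    all_ed <- data.table::rbindlist(list(edits, err))
    touched <- integer(0)
    if (nrow(all_ed)) {
      data.table::setorder(all_ed, idx, off)
      by_read <- split(all_ed, by = "idx")
      touched <- as.integer(names(by_read))
      for (nm_i in seq_along(by_read)) {
        i <- touched[nm_i]
        e <- by_read[[nm_i]]
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        for (r in seq_len(nrow(e))) {
          b <- e$base[r]
          if (is.na(b)) b <- sample(setdiff(bases, ch[e$off[r]]), 1)
          ch[e$off[r]] <- b
        }
        seqs[i] <- paste(ch, collapse = "")
      }
    }

    # ---- mitochondrial MD/NM from candidate offsets ---------------------
    md <- paste0(reads$len)
    nm_tag <- integer(nr)
    if (length(touched)) {
      cand <- all_ed[, list(offs = list(sort(unique(off)))), by = "idx"]
      for (r in seq_len(nrow(cand))) {
        i <- cand$idx[r]
        offs <- cand$offs[[r]]
        rc <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        refc <- ref_chars[reads$start[i] + offs]
        mm <- offs[rc[offs] != refc]
        nm_tag[i] <- length(mm)
        if (length(mm)) md[i] <- md_string(mm, ref_chars[reads$start[i] + mm],
                                           reads$len[i])
      }
    }

    # ---- mitochondrial SAM ----------------------------------------------
    qual <- strrep("I", reads$len)
    mt_rec <- data.frame(
      read_id = reads$read_id,
      flag = ifelse(reads$mate == 1L, 99L, 147L),
      rname = chrom, start = reads$start,
      mapq = 60L, cigar = paste0(reads$len, "M"),
      seq = seqs, qual = qual,
      nm = nm_tag, md = md, nh = 1L,
      xq = pmax(0L, 60L - 2L * nm_tag),
      stringsAsFactors = FALSE)
    mt_sam <- file.path(out_dir, paste0(prefix, "_mt.sam"))
    write_sam(mt_rec, stats::setNames(L, chrom), mt_sam)

    # ---- nuclear alignments ---------------------------------------------
    nuc_sam <- NA_character_
    if (!is.null(numts)) {
      tr <- numts$truth
      nuc_list <- list()
      for (k in seq_len(nrow(tr))) {
        nch <- numts$numt_chars[[k]]
        # reads sourced from this NUMT, plus mtDNA mates fully inside it
        from_numt <- which(reads$src == k)
        inside <- which(reads$label == "mtDNA" &
                        reads$start >= tr$mt_start[k] &
                        reads$end <= tr$mt_end[k])
        rows <- c(from_numt, inside)
        if (!length(rows)) next
        local_start <- reads$start[rows] - tr$mt_start[k]
        nmv <- integer(length(rows)); mdv <- paste0(reads$len[rows])
        for (j in seq_along(rows)) {
          i <- rows[j]
          rc <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          src_c <- nch[(local_start[j] + 1L):(local_start[j] + reads$len[i])]
          mm <- which(rc != src_c)
          nmv[j] <- length(mm)
          if (length(mm)) mdv[j] <- md_string(mm, src_c[mm], reads$len[i])
        }
        nuc_list[[length(nuc_list) + 1L]] <- data.frame(
          read_id = reads$read_id[rows],
          flag = ifelse(reads$mate[rows] == 1L, 99L, 147L),
          rname = tr$chrom[k],
          start = numts$flank + local_start,
          mapq = 60L, cigar = paste0(reads$len[rows], "M"),
          seq = seqs[rows], qual = qual[rows],
          nm = nmv, md = mdv, nh = 1L,
          xq = pmax(0L, 60L - 2L * nmv),
          stringsAsFactors = FALSE)
      }
      if (length(nuc_list)) {
        nuc_rec <- do.call(rbind, nuc_list)
        nuc_sam <- file.path(out_dir, paste0(prefix, "_nuc.sam"))
        write_sam(nuc_rec,
                  stats::setNames(Biostrings::width(numts$sequences),
                                  names(numts$sequences)), nuc_sam)
      }
    }

    fq <- list()
    if (emit_fastq) {
      for (m in 1:2) {
        sel <- reads$mate == m
        ss <- Biostrings::DNAStringSet(seqs[sel])
        names(ss) <- reads$read_id[sel]
        p <- file.path(out_dir, sprintf("%s_R%d.fastq", prefix, m))
        Biostrings::writeXStringSet(
          ss, p, format = "fastq",
          qualities = Biostrings::BStringSet(qual[sel]))
        fq[[paste0("fastq_", m)]] <- p
      }
    }

    has_nuc <- if (!is.null(numts)) {
      nuc_ids <- character(0)
      if (!is.na(nuc_sam)) {
        nuc_ids <- unique(do.call(rbind, nuc_list)$read_id)
      }
      frags$read_id %in% nuc_ids
    } else rep(FALSE, n_frag)
    truth <- data.frame(
      read_id = frags$read_id, label = frags$label,
      source = ifelse(frags$src == 0L, "mt",
                      if (!is.null(numts)) numts$truth$name[
                        pmax(frags$src, 1L)] else "mt"),
      frag_start = frags$fstart,
      frag_end = frags$fstart + frags$flen,
      has_nuclear = has_nuc,
      stringsAsFactors = FALSE)
    truth$source[frags$src == 0L] <- "mt"

    structure(c(list(truth = truth,
                     het_truth = as.data.frame(het_truth),
                     mt_sam = mt_sam, nuc_sam = nuc_sam,
                     numts = numts, source = source, cfg = cfg), fq),
              class = "sim_reads")
  })
}

# MD tag string from sorted 1-based mismatch offsets and their reference
# bases, for a gapless alignment of length `len`.
md_string <- function(offs, ref_bases, len) {
  gaps <- diff(c(0L, offs)) - 1L
  paste0(paste0(gaps, ref_bases, collapse = ""), len - offs[length(offs)])
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads ('", x$source, "'): ", nrow(x$truth), " fragment(s); ",
      sum(x$truth$label == "mtDNA"), " mtDNA, ",
      sum(x$truth$label == "NUMT"), " NUMT; ",
      sum(x$truth$has_nuclear), " with nuclear alignment\n", sep = "")
  invisible(x)
}

#' Simulate an aligned haplotype panel for LD table construction
#'
#' Stands in for the curated full-length mitochondrial sequence panels from
#' which LD r² tables are built. Samples are partitioned into clades
#' (haplogroup-like lineages); each clade carries its own set of marker
#' variants in perfect within-clade co-segregation, low-frequency private
#' singleton variants are sprinkled on individual samples, and optional
#' extra alleles (e.g. known heteroplasmic variants) can be planted within
#' a clade at a chosen carrier frequency.
#'
#' @param cfg A [sim_config()] (provides the reference and seed).
#' @param n_samples Number of panel sequences (>= 4).
#' @param n_clades Number of clades.
#' @param markers_per_clade Clade-defining marker variants per clade.
#' @param n_private Number of private singleton variants.
#' @param extra_alleles Optional data.frame (`position`, `alt`, `clade`,
#'   `freq`): alleles planted on clade members with probability `freq`
#'   (e.g. known heteroplasmic alleles segregating within a lineage).
#' @param fixed_markers Optional data.frame (`position`, `alt`, `clade`):
#'   clade-defining markers at chosen sites — typically the simulated
#'   sample's own haplotype, so that the sample's variant pairs are in
#'   perfect LD in the panel — used in addition to the random markers.
#' @param path Optional output FASTA path; written when non-`NULL`.
#' @return List of class `sim_haplotypes`: `sequences`
#'   ([Biostrings::DNAStringSet]), `clades` (per-sample assignment),
#'   `markers` (data.frame `position`, `alt`, `clade`), `path`.
#' @export
simulate_haplotype_fasta <- function(cfg, n_samples = 50, n_clades = 2,
                                     markers_per_clade = 3, n_private = 5,
                                     extra_alleles = NULL,
                                     fixed_markers = NULL, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_samples >= 4)
  ref_chars <- ref_as_chars(cfg$mt_reference)
  L <- cfg$ref_length
  bases <- c("A", "C", "G", "T")
  with_local_seed(cfg$seed + 202L, {
    clades <- rep_len(seq_len(n_clades), n_samples)
    m <- matrix(rep(ref_chars, each = n_samples), nrow = n_samples)
    n_mark <- n_clades * markers_per_clade
    reserved <- c(if (!is.null(extra_alleles)) extra_alleles$position,
                  if (!is.null(fixed_markers)) fixed_markers$position)
    pos_pool <- setdiff(seq_len(L) - 1L, reserved)
    mark_pos <- sort(sample(pos_pool, n_mark))
    markers <- data.frame(position = mark_pos,
                          alt = vapply(mark_pos, function(p) {
                            sample(setdiff(bases, ref_chars[p + 1L]), 1)
                          }, character(1)),
                          clade = rep_len(seq_len(n_clades), n_mark),
                          stringsAsFactors = FALSE)
    if (!is.null(fixed_markers)) {
      markers <- rbind(markers,
                       fixed_markers[, c("position", "alt", "clade")])
    }
    for (v in seq_len(nrow(markers))) {
      rows <- which(clades == markers$clade[v])
      m[rows, markers$position[v] + 1L] <- markers$alt[v]
    }
    if (!is.null(extra_alleles)) {
      for (v in seq_len(nrow(extra_alleles))) {
        rows <- which(clades == extra_alleles$clade[v])
        carry <- rows[stats::runif(length(rows)) < extra_alleles$freq[v]]
        if (length(carry)) {
          m[carry, extra_alleles$position[v] + 1L] <- extra_alleles$alt[v]
        }
      }
    }
    if (n_private > 0) {
      ppos <- sample(setdiff(pos_pool, mark_pos), n_private)
      for (p in ppos) {
        s <- sample.int(n_samples, 1)
        m[s, p + 1L] <- sample(setdiff(bases, ref_chars[p + 1L]), 1)
      }
    }
    seqs <- Biostrings::DNAStringSet(apply(m, 1, paste, collapse = ""))
    names(seqs) <- sprintf("sample%03d_clade%d", seq_len(n_samples), clades)
    if (!is.null(path)) Biostrings::writeXStringSet(seqs, path)
    structure(list(sequences = seqs, clades = clades, markers = markers,
                   path = path),
              class = "sim_haplotypes")
  })
}

#' Write the canonical small fixture suite
#'
#' Produces, deterministically per seed, the small test fixtures the rest
#' of the package exercises: a pure mtDNA library, a rho-zero library, a
#' mixture library (SAM + BAM), the LD haplotype panel FASTA, the NUMT BED,
#' fragment truth tables (TSV) and a JSON manifest of counts. Two calls
#' with the same seed produce byte-identical manifests.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param cfg Optional [sim_config()]; a small default is built from `seed`
#'   otherwise.
#' @return The manifest, invisibly (list; also written as `manifest.json`).
#' @export
make_fixture_suite <- function(seed, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg)) {
    ref <- mt_reference(4000L)
    cfg <- sim_config(
      seed = seed, mt_reference = ref,
      haplotype_variants = data.frame(position = c(500L, 2500L),
                                      alt = c("A", "G")),
      heteroplasmies = data.frame(position = 1200L, alt = "T",
                                  fraction = 0.3),
      numt_spec = data.frame(start = c(800L, 3000L), end = c(1800L, 3600L),
                             identity = c(0.9, 0.95)),
      depth = 30)
  }
  hap <- simulate_haplotype_fasta(cfg, n_samples = 30,
                                  path = file.path(dir, "ld_panel.fasta"))
  libs <- list(pure_mt = simulate_reads(cfg, "mtDNA", out_dir = dir,
                                        prefix = "pure_mt"),
               rho_zero = simulate_reads(cfg, "rho_zero", out_dir = dir,
                                         prefix = "rho_zero"),
               mixture = simulate_reads(cfg, "mixture", out_dir = dir,
                                        prefix = "mixture"))
  files <- c(ld_panel = "ld_panel.fasta")
  counts <- list()
  for (nm in names(libs)) {
    sim <- libs[[nm]]
    utils::write.table(sim$truth, file.path(dir, paste0(nm, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sam_to_bam(sim$mt_sam)
    if (!is.na(sim$nuc_sam)) sam_to_bam(sim$nuc_sam)
    counts[[nm]] <- list(n_fragments = nrow(sim$truth),
                         n_mtDNA = sum(sim$truth$label == "mtDNA"),
                         n_NUMT = sum(sim$truth$label == "NUMT"),
                         n_with_nuclear = sum(sim$truth$has_nuclear))
    files[[paste0(nm, "_mt_sam")]] <- basename(sim$mt_sam)
    if (!is.na(sim$nuc_sam)) {
      files[[paste0(nm, "_nuc_sam")]] <- basename(sim$nuc_sam)
    }
    files[[paste0(nm, "_truth")]] <- paste0(nm, "_truth.tsv")
  }
  numts <- simulate_numt_sequences(cfg)
  write_numt_bed(numts, file.path(dir, "numts.bed"),
                 chrom = ref_name(cfg$mt_reference))
  files[["numt_bed"]] <- "numts.bed"
  manifest <- list(seed = as.integer(seed),
                   ref_length = cfg$ref_length,
                   n_ld_samples = length(hap$sequences),
                   counts = counts,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
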