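# Shared simulated fixtures, built once per test run (lazily) and reused
# across test files. Everything is generated in code under fixed seeds.

.fixture_env <- new.env()

# first base differing from the reference at a 0-based position
pick_alt <- function(ref, pos) {
  rc <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  setdiff(c("A", "C", "G", "T"), rc[pos + 1L])[1]
}

shared_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  ref <- mt_reference(3000L)
  hap_pos <- c(400L, 2200L)
  hap_alt <- vapply(hap_pos, function(p) pick_alt(ref, p), character(1))
  het_pos <- 1500L
  het_alt <- pick_alt(ref, het_pos)
  cfg <- sim_config(
    seed = 42, mt_reference = ref,
    haplotype_variants = data.frame(position = hap_pos, alt = hap_alt),
    heteroplasmies = data.frame(position = het_pos, alt = het_alt,
                                fraction = 0.3),
    numt_spec = data.frame(start = c(600L, 2400L), end = c(1600L, 2900L),
                           identity = c(0.90, 0.97)),
    depth = 40)
  hap <- simulate_haplotype_fasta(
    cfg, n_samples = 40, n_clades = 3,
    fixed_markers = data.frame(position = hap_pos, alt = hap_alt,
                               clade = 1L),
    extra_alleles = data.frame(position = het_pos, alt = het_alt,
                               clade = 1L, freq = 0.3),
    path = tempfile(fileext = ".fasta"))
  ld <- build_ld_table(read_haplotype_fasta(hap$path, ref), min_maf = 0.02)
  numts <- simulate_numt_sequences(cfg)
  bed <- tempfile(fileext = ".bed")
  write_numt_bed(numts, bed, chrom = "chrM")
  .fixture_env$fx <- list(
    ref = ref, cfg = cfg, hap = hap, ld = ld,
    numts = numts, numt_bed = read_numt_bed(bed),
    mix = simulate_reads(cfg, "mixture", numt_fraction = 0.2),
    pure = simulate_reads(cfg, "mtDNA"),
    rho = simulate_reads(cfg, "rho_zero"))
  .fixture_env$fx
}

# model trained on the shared positive/negative libraries (memoised)
shared_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  fx <- shared_fixture()
  pos <- build_positive_training_set(fx$pure$mt_sam, fx$ld, fx$numt_bed)
  neg <- build_negative_training_set(fx$rho$mt_sam, fx$rho$nuc_sam, fx$ld,
                                     fx$numt_bed)
  .fixture_env$model <- numt_rf(rbind(pos, neg), seed = 11)
  .fixture_env$model
}

# hand-built LD table for unit tests of the fragment score
make_ld <- function(df) {
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df))) {
    k1 <- paste0(df$pos_i[i], ":", df$alt_i[i], "|", df$pos_j[i], ":",
                 df$alt_j[i])
    k2 <- paste0(df$pos_j[i], ":", df$alt_j[i], "|", df$pos_i[i], ":",
                 df$alt_i[i])
    assign(k1, df$r2[i], envir = lookup)
    assign(k2, df$r2[i], envir = lookup)
  }
  structure(list(pairs = df, lookup = lookup, min_maf = 0, n_samples = 0L,
                 sites = NULL),
            class = "ld_table")
}

# minimal alignment record data.frame for crafting SAM fixtures
sam_record <- function(read_id, start, seq, cigar = paste0(nchar(seq), "M"),
                       md = paste0(nchar(seq)), nm = 0L, flag = 0L,
                       rname = "chrM", mapq = 60L, nh = 1L, xq = NULL) {
  data.frame(read_id = read_id, flag = flag, rname = rname, start = start,
             mapq = mapq, cigar = cigar, seq = seq,
             qual = strrep("I", nchar(seq)), nm = nm, md = md, nh = nh,
             xq = if (is.null(xq)) mapq else xq, stringsAsFactors = FALSE)
}

write_sam_bam <- function(records, ref_lengths, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "records.sam")
  write_sam(records, ref_lengths, sam)
  sam
}

# random gapped-alignment generator for the MD-caller oracle test: builds
# read/CIGAR/MD by explicit construction and records the planted mismatches
# independently of the parser under test.
random_alignment <- function() {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 400, replace = TRUE)
  start <- sample(0:100, 1)
  lead_s <- sample(0:5, 1)
  tail_s <- sample(0:5, 1)
  n_seg <- sample(1:3, 1)
  m_lens <- sample(15:50, n_seg, replace = TRUE)
  gap_ops <- if (n_seg > 1) {
    sample(c("D", "I"), n_seg - 1, replace = TRUE)
  } else character(0)
  gap_lens <- if (n_seg > 1) sample(1:3, n_seg - 1, replace = TRUE) else
    integer(0)

  read <- character(0)
  cigar <- if (lead_s > 0) paste0(lead_s, "S") else ""
  read <- c(read, sample(bases, lead_s, replace = TRUE))
  md_parts <- character(0)
  run <- 0L
  rp <- start  # 0-based ref cursor
  expected <- data.frame(position = integer(0), ref = character(0),
                         alt = character(0), stringsAsFactors = FALSE)
  for (s in seq_len(n_seg)) {
    for (b in seq_len(m_lens[s])) {
      rb <- ref[rp + 1L]
      if (stats::runif(1) < 0.07) {
        ab <- sample(setdiff(bases, rb), 1)
        expected <- rbind(expected, data.frame(position = rp, ref = rb,
                                               alt = ab))
        md_parts <- c(md_parts, paste0(run, rb))
        run <- 0L
        read <- c(read, ab)
      } else {
        run <- run + 1L
        read <- c(read, rb)
      }
      rp <- rp + 1L
    }
    cigar <- paste0(cigar, m_lens[s], "M")
    if (s < n_seg) {
      if (gap_ops[s] == "D") {
        md_parts <- c(md_parts, paste0(run, "^",
                                       paste(ref[rp + seq_len(gap_lens[s])],
                                             collapse = "")))
        run <- 0L
        rp <- rp + gap_lens[s]
        cigar <- paste0(cigar, gap_lens[s], "D")
      } else {
        read <- c(read, sample(bases, gap_lens[s], replace = TRUE))
        cigar <- paste0(cigar, gap_lens[s], "I")
      }
    }
  }
  md <- paste0(paste(md_parts, collapse = ""), run)
  read <- c(read, sample(bases, tail_s, replace = TRUE))
  if (tail_s > 0) cigar <- paste0(cigar, tail_s, "S")
  list(md = md, cigar = cigar, seq = paste(read, collapse = ""),
       start = start, expected = expected,
       ref = ref)
}
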