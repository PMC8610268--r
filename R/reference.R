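#' Bundled circular mitochondrial reference stand-in
#'
#' Returns a deterministic pseudo-random DNA sequence of the length of the
#' human mitochondrial genome (16,569 bp by default), used as a circular
#' mitochondrial reference for simulation and testing. A homopolymer C tract
#' is planted around position 300 (0-based) to emulate the low-complexity
#' region near m.303 that makes real mitochondrial variant calling difficult
#' there. The sequence is *not* the rCRS (which is not redistributed); it is a
#' synthetic stand-in with the same length and circular topology.
#'
#' The sequence is a pure function of `length`: repeated calls, in any
#' session, return the same sequence.
#'
#' @param length Reference length in bp. Default 16569, the length of the
#'   human mitochondrial genome.
#' @param name Sequence name used as the SAM/FASTA contig name.
#' @return A named [Biostrings::DNAStringSet] of length 1.
#' @examples
#' ref <- mt_reference()
#' width(ref)  # 16569
#' @export
mt_reference <- function(length = 16569L, name = "chrM") {
  length <- as.integer(length)
  stopifnot(length >= 400L)
  bases <- with_local_seed(16569L, {
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c(0.31, 0.31, 0.13, 0.25))
    # poly-C tract with a single interrupting T, as in the m.303 region
    b[291:302] <- "C"
    b[303] <- "T"
    b[304:310] <- "C"
    b
  })
  seq <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(seq) <- name
  seq
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Single-sequence character access helpers used throughout the simulator.
ref_as_chars <- function(ref) {
  strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
}

ref_name <- function(ref) {
  nm <- names(ref)
  if (is.null(nm) || !nzchar(nm[1])) "chrM" else nm[1]
}
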