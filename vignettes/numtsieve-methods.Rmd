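---
title: "Separating mitochondrial reads from NUMTs: model and methods"
author: "numtsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating mitochondrial reads from NUMTs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human nuclear genomes contain several hundred nuclear-encoded mitochondrial
segments (NUMTs): fragments of mitochondrial DNA that were transferred into
the nucleus over evolutionary time. They range from roughly 40 bp to nearly
the full 16,569 bp mitochondrial genome, at 64–100% sequence identity to
mtDNA. Short sequencing reads derived from a NUMT can align perfectly well
to the mitochondrial reference, and genuine mitochondrial reads can align
to NUMT loci. Both failure modes corrupt *heteroplasmy* estimates — the
fraction of a sample's mtDNA copies carrying a variant allele — which is
the quantity of clinical interest in mitochondrial genetics: NUMT reads
carrying the nuclear allele inflate apparent low-level heteroplasmy
(false positives), while mtDNA reads lost to nuclear loci depress it
(false negatives).

numtsieve treats the problem as supervised read classification rather than
hard filtering. Every read pair that aligns to the mitochondrial reference
receives a probability of being genuine mtDNA, so downstream analyses can
choose their own operating point instead of silently losing reads.

## The classifier

The core model, `numt_rf()`, is a random forest with 128 trees over four
per-fragment features (`final_model_features()`); the remaining alignment
features are computed and kept available for model-selection experiments
but are not in the default set.

* **mt_edit_distance** — sum over the two mates of the `NM` edit distance
  of the mitochondrial alignment. Genuine mtDNA reads differ from the
  reference only by the sample's variants and sequencing error; NUMT reads
  additionally carry the NUMT's accumulated divergence.
* **nuc_edit_distance** — the best nuclear explanation of the fragment:
  per mate, the minimum `NM` over its nuclear re-alignments, summed over
  mates. A mate with no nuclear alignment contributes its read length — a
  sentinel meaning "no plausible nuclear origin", the most mtDNA-like
  value. Taking the *minimum* over multiple nuclear hits is deliberately
  conservative toward calling a read a NUMT.
* **mt_ld** — a linkage-disequilibrium co-occurrence score. Mitochondrial
  variants segregate as haplotypes, so pairs of genuine variants observed
  on the same fragment should co-occur on known mitochondrial lineages. The
  fragment's variants are called from the `MD` tags of both mates
  (deduplicated on position and alternate allele); with fewer than two
  variants the score is the neutral 1, otherwise it is the **minimum**
  pairwise r² over all variant pairs, with pairs absent from the LD table
  contributing an *unseen-pair score*, default 0. The minimum is the most
  conservative single-number summary of "could this combination exist on
  one mitochondrial haplotype"; a NUMT read typically carries several
  divergence-derived alleles that never co-occur in any haplotype panel
  and scores 0.
* **numt_overlap** — the fraction of the fragment's span that lies inside
  known NUMT-mirrored intervals of the mitochondrial reference, computed by
  interval intersection (origin-spanning fragments contribute both
  sub-intervals).

Training data come from two library types with known labels: an
mtDNA-enriched library (long-range PCR amplification of the mitochondrial
genome; every aligned fragment is genuine mtDNA) and a rho-zero library
(cells experimentally depleted of mtDNA; any read that aligns to the
mitochondrial reference *and* re-aligns to the nuclear genome must be a
NUMT). `build_positive_training_set()` and `build_negative_training_set()`
encode exactly those rules.

Forest hyper-parameters beyond the tree count follow common defaults —
unlimited depth, `floor(sqrt(p))` features per split, no class weighting —
and are exposed as arguments. Fits are deterministic given `seed`.
Validation uses stratified k-fold cross-validation (`cross_validate()`);
an 80%/20% split corresponds to k = 5. Stratification is added so that
small fixtures cannot produce single-class folds. F1 is the standard
harmonic mean 2PR/(P + R), defined as 0 at P = R = 0. The pooled F1 is
computed from pooled confusion counts rather than averaged per-fold.

At classification time (`classify_run()`), a fragment with probability
`>= threshold` (default 0.5) is retained; the tie is inclusive, favouring
retention. Rejected reads are written to their own output, never dropped,
so the filtering is auditable. An optional fast path can auto-accept
fragments with no nuclear alignment at all; by default every fragment is
scored, since the sentinel already encodes that situation.

## The LD table

`build_ld_table()` computes haploid r² = D²/(p₁q₁p₂q₂), D = p₁₂ − p₁p₂,
between all pairs of biallelic sites called from an aligned panel of
full-length mitochondrial sequences (`read_haplotype_fasta()`). Haploid
(allele-level) r² is the right statistic because mtDNA is effectively
haploid; for 0/1 vectors it equals the squared Pearson correlation, which
the tests use as an independent oracle. Choices that matter:

* sites are called against the reference; multi-allelic columns are split
  into one biallelic site per alternate allele, with samples carrying a
  different alternate coded missing; gaps and `N` are missing;
* r² is computed pairwise-complete; a pair whose sites become monomorphic
  after missing-data removal has no defined r² and is *excluded* from the
  table, not stored as 0;
* default `min_maf = 0.01` and no distance cap — mitochondrial LD is
  genome-wide and fragments are short anyway; both are configurable;
* serialisation is plain TSV with header comments (sample count, MAF
  filter), stable and diffable.

The unseen-pair score deserves a note: a variant pair can be absent from
the table either because the two alleles genuinely never co-occur or
because one allele (for example, a sequencing error) is unknown to the
panel. Both receive the unseen-pair score, and the default 0 treats
absence as suspicion. This makes the LD feature noisy for genuine reads
that carry one real variant plus one sequencing error — which is why the
score is one input to a trained forest rather than a filter, and why the
no-evidence cases (0 or 1 variants) score a neutral 1.

## The MD-tag mismatch caller

`call_md_variants()` reconstructs reference mismatches from the SAM `MD`
tag, taking the reference base from the tag and the alternate base from
the read at the CIGAR-mapped offset. It is substitution-only by design:
insertions cannot be encoded in `MD`, and deleted reference bases (`^`
syntax) are consumed without producing a call, because the LD table is
keyed on SNVs. Any disagreement between the `MD` tag, the CIGAR and the
read length is a hard error naming the offending tag rather than a silent
skip. The tests check the parser against an independent
construction-based oracle over randomized gapped alignments (soft clips,
insertions, deletions, leading-zero `MD` dialects).

## Pileup heteroplasmy and copy number

`pileup_heteroplasmy()` is intentionally minimal plumbing so the pipeline
is testable end to end: per-site depth is read coverage, alternate counts
come from the MD-called mismatches, heteroplasmy is `alt_count / depth`,
and a call requires depth ≥ `min_depth` (default 10). There is no
strand-bias, base-quality or indel handling — in production use a
dedicated somatic caller runs downstream of classification.

`mtdna_copy_number()` is the ratio of mtDNA-classified reads to autosomal
(chromosomes 1–22) reads; both `"1"` and `"chr1"` naming dialects are
matched. The raw ratio is the default; an optional mode normalises by
reference lengths and ploidy to express copies per diploid genome.

## Evaluation statistics

`compare_variant_sets()` implements the benchmark-comparison rules used to
score a tool's heteroplasmy calls against a gold standard:

* heteroplasmy error = benchmark − tool, with a variant absent from one
  set entered as 0 on that side;
* a call is a **false negative** when the tool value is more than `tol`
  (default 0.2) *below* the benchmark value, a **false positive** when
  more than `tol` above, otherwise a **match** — so a benchmark variant at
  0.5 needs a tool value above 0.3 to match. The boundary itself is
  counted as a match;
* a *homoplasmic* variant error is a misclassification whose governing
  heteroplasmy exceeds 0.5 — benchmark-side for false negatives,
  tool-side for false positives (the side on which the homoplasmic claim
  was made);
* variant identity is `(position, alt)`: a tool calling a different
  alternate at a benchmark position produces one false negative plus one
  false positive;
* the scaled error divides by p(1 − p) of the benchmark value to
  normalise the binomial sampling variance; it is undefined at p ∈ {0, 1}
  and those rows are flagged and excluded from scaled summaries.

`detection_curve()` reports, per heteroplasmy threshold, the fraction of
benchmark variants at or above the threshold that the tool recovers;
"recovers" defaults to "is not a false negative under the tolerance rule",
with a strict key-presence mode available. `maf()` folds heteroplasmy at
one half.

## What the simulator emulates — and what it does not

`simulate_reads()` generates labelled paired-end libraries with the
statistical structure the method relies on:

* fragments sampled uniformly on the *circular* mitochondrial genome
  (pairs may straddle the origin; a mate that would individually cross the
  origin is resampled);
* a fixed sample haplotype on every mtDNA fragment, plus heteroplasmic
  alleles planted per fragment with their configured fractions — both
  mates of a carrier fragment agree;
* NUMTs realised as diverged copies of mitochondrial intervals
  (`simulate_numt_sequences()`), with identity in the biological 64–100%
  range and length ≥ 40 bp, embedded in random nuclear flanks; the
  realised identity is within a percentage point of target;
* substitution-only sequencing errors at `error_rate` (default 0.002 per
  base, an Illumina-like figure) — substitution-only matches the SNV-only
  MD caller; an indel mode is deliberately absent;
* library presets: `mtDNA` (enriched), `rho_zero` (NUMT-only — the
  defining property of mtDNA-depleted cells), `mixture` (WGS-like).
  `depth` always means coverage of the *sequenced material*: the
  mitochondrial genome for mtDNA-bearing libraries, the NUMT complement
  for a NUMT-only library — a rho-zero library yields few
  mitochondrially-aligned fragments, all NUMT-derived, exactly as the
  biology dictates.

The simulator emits already-aligned SAM records directly from truth
coordinates (with `NM`/`MD`/`NH`/`XQ` computed against the references),
bypassing an external aligner; this keeps tests deterministic and
download-free while matching the pipeline's input contract. A FASTQ mode
exists for users who want to run a real aligner. The bundled reference
(`mt_reference()`) is a deterministic pseudo-random 16,569 bp sequence
with a planted homopolymer C tract emulating the well-known difficult
region around position 300; the real human reference is not
redistributed.

Known departures from real data, and hence limits on what passing tests
show: no quality-score structure (uniform qualities), no indel errors, no
PCR duplicates or GC bias, no realistic aligner behaviour at high
divergence (every read of a NUMT-mirrored interval receives a nuclear
alignment regardless of mismatch load, where a real aligner would stop
reporting at some divergence), and the haplotype panel is tiny compared
with curated collections of tens of thousands of sequences. Results on
simulations therefore demonstrate internal correctness and sensible
statistical behaviour, not field performance on clinical libraries.

## Numerical and design choices

* Coordinates are 0-based half-open internally; SAM's 1-based convention
  is converted exactly once at the I/O boundary, so interval arithmetic
  with BED input needs no further adjustment.
* A fragment's span is the minimal interval covering both mates; on a
  circular reference the wrap-around interpretation (two sub-intervals) is
  chosen whenever it implies the shorter fragment.
* Per-fragment edit distances are *sums* over mates (not means or maxima):
  the fragment is the classification unit and both mates carry evidence.
* Missing aligner tags degrade gracefully: `NM` is recomputed from
  `MD` + CIGAR (error if neither is present), `NH` falls back to counting
  records per read and mate, `XQ` to the mapping quality.
* Duplicate-marked and QC-fail reads are excluded by default (flags to
  include them exist); single-mate fragments are retained, flagged, and
  featurised from the available mate, with the LD feature then usually
  neutral — dropping them would bias coverage.
* The LD feature uses r² directly, untransformed; the forest can learn any
  monotone transformation it needs.
* NUMT regions are supplied as the mitochondrial intervals each NUMT
  mirrors (BED, 0-based), because fragment overlap is only computable in
  mitochondrial coordinates; an optional fifth column records the nuclear
  locus for reporting.
* `benchmark_filter()` counts reference-consuming aligned bases
  (CIGAR `M`/`=`/`X`) against its threshold, default 270 bp.

## Validation problem sizes

The test suite validates the full loop at study scale on the bundled
16,569 bp reference: a 500× WGS-like mixture with 20% NUMT fragments at
8–12% divergence, training libraries at 100× (≈5,500 positive and ≈2,100
negative fragments), and planted heteroplasmies {0.01, 0.05, 0.2, 0.5,
0.9} — two of them deliberately inside NUMT-mirrored intervals so that
recovery genuinely depends on classification, not just alignment
geometry. Acceptance checks require every post-classification pileup
estimate within three binomial standard deviations of truth,
cross-validated F1 ≥ 0.9 at ≥10% divergence, chance-level F1 under label
permutation on balanced classes, and exact agreement of the tolerance-rule
boundaries and of the MD caller, r² and interval-overlap implementations
with independent oracles. Smaller 2–4 kb references with proportional
settings drive the per-module tests.

## Known limitations

* Fragments carrying one real variant plus one sequencing error inside a
  NUMT-overlap region sit in the least favourable feature cell (LD 0,
  overlap 1) and are the first to be lost as the threshold rises; with a
  representative positive training library the forest resolves them
  through the nuclear edit distance, but heavily skewed training sets can
  bias low-level heteroplasmy in NUMT-mirrored regions downward.
* The pileup estimator is deliberately naive (no strand or quality
  modelling); its role is pipeline plumbing and validation, not clinical
  calling.
* Homopolymer-region artefacts (the planted C tract emulates one) are
  simulated only as ordinary sequence content; real signal dropout there
  is not modelled.
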