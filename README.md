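# numtsieve

Machine-learning separation of genuine mitochondrial DNA (mtDNA) reads
from nuclear-encoded mitochondrial segments (NUMTs) in paired-end
sequencing data, with heteroplasmy estimation and benchmark-comparison
statistics.

## The problem

The human nuclear genome carries hundreds of NUMTs — ancient insertions of
mitochondrial sequence, 64–100% identical to mtDNA and from ~40 bp up to
nearly the whole 16,569 bp mitochondrial genome. Short reads from NUMTs
align to the mitochondrial reference and genuine mtDNA reads align to NUMT
loci, so both heteroplasmy (the fraction of mtDNA copies carrying a
variant, the clinically decisive quantity in mitochondrial genetics) and
mtDNA copy number are systematically distorted. Hard filters — keeping
only uniquely-aligning reads, or masking variants near known NUMTs —
discard real signal invisibly.

numtsieve instead scores every mitochondrially-aligned read pair with a
probability of being genuine mtDNA, using a random forest (128 trees) over
four alignment-derived features:

| feature | meaning |
|---|---|
| `mt_edit_distance` | summed `NM` of the pair against the mitochondrial reference |
| `nuc_edit_distance` | best nuclear explanation: minimum `NM` over nuclear re-alignments, summed over mates; read-pair length when no nuclear hit exists |
| `mt_ld` | minimum pairwise LD r² over the variants carried by the pair (called from `MD` tags); variant combinations unseen on known mitochondrial haplotypes score 0 |
| `numt_overlap` | fraction of the fragment inside known NUMT-mirrored intervals |

The positive training class comes from mtDNA-enriched (long-range PCR)
libraries; the negative class from rho-zero libraries — cells depleted of
mtDNA, whose mitochondrially-aligned, nuclear-realigning reads are NUMTs
by construction. The package also ships the LD r² table builder (haploid
r² = D²/(p₁q₁p₂q₂) from an aligned haplotype panel), an `MD`-tag mismatch
caller, a pileup heteroplasmy estimator, copy-number estimation,
tolerance-rule evaluation statistics for comparing call sets against a
benchmark, and a fully labelled read simulator (mtDNA / rho-zero /
mixture libraries) so everything is testable without external data.

## Worked example

A complete round trip on simulated data — an 8 kb reference stand-in, two
NUMTs (90% and 95% identity), one heteroplasmy planted at fraction 0.2,
150× coverage:

```r
library(numtsieve)

ref <- mt_reference(8000L)
alt_at <- function(p) setdiff(c("A","C","G","T"),
                              substring(as.character(ref[[1]]), p + 1, p + 1))[1]
cfg <- sim_config(
  seed = 1, mt_reference = ref,
  haplotype_variants = data.frame(position = c(1200L, 5200L),
                                  alt = c(alt_at(1200L), alt_at(5200L))),
  heteroplasmies = data.frame(position = 3500L, alt = alt_at(3500L),
                              fraction = 0.2),
  numt_spec = data.frame(start = c(2000L, 6000L), end = c(3200L, 6900L),
                         identity = c(0.90, 0.95)),
  depth = 150)

panel <- simulate_haplotype_fasta(cfg, n_samples = 60, n_clades = 3,
                                  path = tempfile(fileext = ".fasta"))
ld <- build_ld_table(read_haplotype_fasta(panel$path, ref), min_maf = 0.01)

numts <- simulate_numt_sequences(cfg)
bed <- tempfile(fileext = ".bed")
write_numt_bed(numts, bed)
numt_regions <- read_numt_bed(bed)

pos_lib <- simulate_reads(cfg, "mtDNA",    prefix = "enriched")
neg_lib <- simulate_reads(cfg, "rho_zero", prefix = "rho0")
train <- rbind(
  build_positive_training_set(pos_lib$mt_sam, ld, numt_regions),
  build_negative_training_set(neg_lib$mt_sam, neg_lib$nuc_sam, ld, numt_regions))

model <- numt_rf(train, seed = 7)
model
#> numt_rf: random-forest mtDNA/NUMT read classifier
#>   trees: 128, mtry: 2, seed: 7
#>   features: mt_edit_distance, nuc_edit_distance, mt_ld, numt_overlap
#>   training fragments: NUMT=1050, mtDNA=4000

cross_validate(train, k = 5, seed = 7)
#> cv_report: 5-fold stratified cross-validation
#>  fold precision recall f1
#>     1         1      1  1
#>     ...
#> pooled: precision 1.000, recall 1.000, F1 1.000

wgs <- simulate_reads(cfg, "mixture", numt_fraction = 0.2)
res <- classify_run(wgs$mt_sam, wgs$nuc_sam, model, ld, numt_regions,
                    threshold = 0.5, out_dir = tempfile())
res
#> classify_result: 4000 fragment(s); 3200 retained, 800 rejected at threshold 0.50

calls <- pileup_heteroplasmy(res$paths$retained, ref, min_depth = 10)
subset(calls, alt_count >= 5)
#>      position ref alt depth alt_count heteroplasmy
#> 247      1200   A   C   129       128    0.9922481
#> 785      3500   A   C   114        25    0.2192982
#> 1212     5200   T   A   127       126    0.9921260

mtdna_copy_number(42000, 1500000)
#> [1] 0.028
```

Reading the output: cross-validated F1 is 1.0 on this cleanly separated
mixture (10% NUMT divergence far exceeds the 0.2% error rate); the
classifier retains exactly the 3,200 mtDNA fragments of the 4,000-fragment
mixture; the two haplotype variants are recovered as homoplasmic (~0.99)
and the planted 0.2 heteroplasmy is estimated at 0.219 from 114×
(within binomial sampling error, 3·√(p(1−p)/114) ≈ 0.11); the copy-number
example is simply the read-count ratio.

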