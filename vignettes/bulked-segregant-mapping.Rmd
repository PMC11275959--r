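---
title: "Methods: bulked-segregant mapping with bulkmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant mapping with bulkmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmapr)
```

## The experimental design being modeled

Two inbred parents differing at dense biallelic SNPs are crossed; the F1 is
selfed to produce an F2 population in which a recessive phenotype (the
motivating case is a temperature-sensitive albino seedling phenotype)
segregates. From each phenotypic tail, `bulk_size` individuals (default 50)
are pooled and whole-genome sequenced to a mean pooled depth of 78×. The
same cross is made in both parental orientations, giving two reciprocal F2
populations that are analysed independently and then combined by interval
intersection.

At an unlinked marker, both bulks are random samples of the 1:2:1 F2
genotype distribution, so their pooled allele frequencies both estimate
1/2. At a marker fully linked to the recessive causal locus, the albino
bulk is fixed for the albino-parent allele (frequency 1) while the normal
bulk — a 1:2 mixture of homozygous-dominant and heterozygous genotypes —
sits at 2/3 dominant-parent / 1/3 albino-parent allele.

## The synthetic-data generator

`sim_config()` + `simulate_experiment()` generate complete experiments
with known truth. Design choices, with defaults chosen to match the study
conditions the package targets:

* **Markers**: uniform random positions at `snp_density` (default one SNP
  per 10 kb); causal positions are always included as markers so truth
  coincides with an observable site.
* **Meiosis**: each F2 individual is the sum of two independent gametes.
  Per chromosome, a gamete receives a Poisson number of crossovers with
  mean equal to the genetic length in Morgans (physical length ×
  `morgans_per_bp`, default 1 Morgan per 25 Mb — a rice-scale heuristic),
  placed uniformly in genetic distance, with a fair-coin starting
  haplotype. This is the interference-free Haldane model. The `kosambi`
  option rescales every inter-marker genetic gap `d` to the Haldane
  distance with the same Kosambi recombination fraction
  (`d' = haldane⁻¹(kosambi(d))`), so adjacent-marker recombination
  follows Kosambi's map while the crossover process stays Poisson;
  interference itself is not simulated.
* **Phenotype architectures**: `single_recessive` (albino iff homozygous
  for the albino-parent allele; 3:1), `single_recessive_penetrance`
  (albino with probability π given that genotype; π = 0.5 gives 7:1),
  `duplicate_recessive_two_locus` (albino iff homozygous at both loci;
  15:1), and `none` (phenotype independent of genotype, for null
  controls). The penetrance and two-locus options span the
  normal:albino ratios between 3:1 and 15:1 that motivated them; the
  package does not assert which architecture underlies any particular
  observed ratio. Maternal/cytoplasmic effects — one candidate
  explanation for reciprocal-cross ratio differences — are not modeled;
  a reciprocal population is simulated as an independent replicate with
  a new seed.
* **Bulks**: uniformly random subsets of exactly `bulk_size` per class;
  an informative error names the deficient class. Note that
  `pop_size` must comfortably exceed `bulk_size`/expected-class-fraction
  (500 F2 with bulks of 50 at a 1/4 albino rate is comfortable; 200 is
  not).
* **Depths**: per SNP per bulk, total depth ~ negative binomial with mean
  `mean_depth` (78) and size `depth_dispersion` (default 10; `Inf` gives
  the Poisson limit) — short-read depth is overdispersed in practice.
  The albino-parent-allele read count is Binomial(total, f) with f the
  bulk's mean allele dosage/2. There is no read-level error model, no
  mapping bias, and no alignment artifacts: allele depths are sampled
  directly. Passing tests therefore demonstrate correctness of the
  statistics and calling machinery, not robustness to alignment or
  calling artifacts in real data.
* **Site annotations** default to passing values (QUAL 60, QD 25, MQ 60,
  FS 1); `fail_fraction` injects failing sites to exercise the hard
  filters.
* **`unlinked = TRUE`** draws genotypes i.i.d. 1:2:1 at every marker.
  This mode exists because the confidence-band model (below) describes
  independent sites: on a linked genome, bulk-composition drift is shared
  along a chromosome, so the fraction of sites outside a band has very
  high variance across replicates even when the band is perfectly
  calibrated. Calibration checks use the unlinked mode; mapping runs use
  the linked default.

## Filtering

Stage one (`apply_hard_filters()`) applies GATK-style site filters in a
fixed order, attributing each removal to the first failing rule: QUAL
< 30, QD < 2.0, MQ < 40, FS > 60, within 5 bp of an InDel (a precomputed
flag; the package does not call InDels), and SNP clusters. Comparators
are strict, so boundary values (QUAL = 30, QD = 2.0, MQ = 40, FS = 60)
are retained. The cluster rule removes every SNP lying in any 5 bp window
that holds more than 2 SNPs; this is implemented as an exact scan over
consecutive triples (any offending window necessarily contains a
consecutive triple spanning ≤ 4 bp) and is verified against a brute-force
window scan in the tests. Missing annotations fail their rule in strict
mode (the default, for reproducibility) and are skipped per record in
lenient mode.

Stage two (`filter_high_quality()`) keeps biallelic records with per-bulk
depth ≥ 4 that are informative: records are dropped when both bulks are
effectively homozygous for the same allele, when both parents share a
homozygous genotype, or when a bulk's majority allele contradicts its
expected parental origin. Pool "homozygosity" is operationalized as an
allele fraction ≤ ε or ≥ 1 − ε with ε = 0.01, since pools are mixtures
and have no called genotype. The origin filter uses the majority allele
(fraction above/below 0.5); an exact 50/50 pool carries no evidence of
wrong origin and is retained. Each stage-two rule is a pure per-record
predicate, so the surviving set is order-independent — a property the
tests check by permuting the rule order.

## Association statistics

**ED**: for a biallelic site, `ED = √2·|f − g|` where f and g are the two
bulks' albino-parent allele fractions; the association value is `ED^5`
(exponent configurable). **ΔSNP-index**: each bulk's index is the
fraction of reads carrying the albino-parent allele, and Δ =
index(albino) − index(normal). This orientation is a package convention
(either sign convention is defensible); it makes peaks positive, with
Δ → 2/3 expected at a fully linked recessive locus. Zero-depth records
are flagged and excluded before track building.

**SNPNUM fitting**: windows hold exactly `window_snps` consecutive SNPs
(default 101 — odd, so the median position is a SNP position), advance by
`step_snps` (default 1), and the fitted value is the window *mean*
assigned to the median SNP position. The mean (rather than the median)
preserves the additive spike signal of the ED⁵ transform; window
parameters are configurable because the method's canonical parameters are
not standardized. Chromosomes with fewer SNPs than the window produce no
fitted values there, with a message rather than an error.

**ED threshold**: median + 3·SD (n−1 denominator) of all fitted values,
all chromosomes pooled. The threshold is a property of each dataset; the
degenerate all-equal case yields SD 0 and threshold = median.

**Δ confidence bands** (`simulate_delta_ci()`): for each depth d on a
grid (default 1–200) and each of (default) 10,000 replicates, each bulk's
true frequency is drawn as Binomial(2·`bulk_size`, 1/2)/(2·`bulk_size`)
— the exact distribution of the mean dosage of `bulk_size` F2 individuals
under no linkage — and its observed index as Binomial(d, freq)/d. Bands
are two-sided empirical quantiles of Δ at 90/95/99%. Band lookup at a SNP
uses the **harmonic mean of the two bulk depths** as the effective depth,
because Var(Δ) ∝ (1/d₁ + 1/d₂) = 2/harmonic-mean — matching the band
simulation's equal-depth variance exactly — with linear interpolation on
the grid and clamping outside it.

## Region calling and interval algebra

Maximal runs of evaluation points exceeding the threshold (scalar for ED;
depth-matched band for Δ, two-sided by default — the choice of one- vs
two-sided exceedance is exposed) become intervals spanning the first to
last exceeding SNP position. Run boundaries are SNP positions rather than
window edges, matching the bp-resolution endpoints such analyses report.
Runs separated by fewer than `gap_snps` non-exceeding points merge
(default 1: no merging); intervals shorter than `min_len` (default
10 kb) are discarded. Coordinates are 1-based inclusive throughout
(length = end − start + 1); BED files are converted to 0-based half-open
at the file boundary only.

Reciprocal combination (`run_reciprocal()`) selects each population's
intervals by a policy flag — the Δ regions (default, since the final
interval in the motivating analysis came from the Δ scan), the ED∪Δ
union, or the ED∩Δ intersection — and intersects the two populations'
selections pairwise, clipping to `[max(starts), min(ends)]`. Gene overlap
against a GFF3 annotation requires ≥ 1 bp of overlap, strand ignored, and
malformed annotation lines are skipped with a warning.

Segregation ratios are reported to 3 significant figures
(386/64 → 6.03, 628/62 → 10.1) with a Pearson chi-square (1 df) against
the expected ratio.

## Reproducibility and problem sizes

Every stochastic stage accepts a seed; a fixed seed reproduces the
simulated experiment, the bands, and every written artifact byte for
byte. The test-suite and acceptance simulations use 500 F2 individuals,
bulks of 50, 78× depth, and ~20,000 SNPs on two 100 Mb chromosomes (20
replicate seeds) — the bulk/depth design the package targets, at a genome
size that keeps a full 20-replicate study comfortably interactive.
Smaller toy genomes are used where only mechanics are exercised. One
caution from that choice: on very short chromosomes (tens of Mb at 1
Morgan/25 Mb) nearly all markers are linked to the causal locus, the
fitted ED⁵ background is inflated, and the median+3SD rule can exceed the
peak — the rule presumes the genome is mostly unlinked background.

## Known limitations

* No read-level simulation (FASTQ, alignment, base errors); depth is
  sampled directly.
* InDel proximity is consumed as a flag, never recomputed.
* The ED threshold value printed by any given study is a property of its
  data; only the median+3SD rule is reproducible.
* Window smoothing is SNP-count based only; bp-based or loess smoothing
  is out of scope.
* The maternal/cytoplasmic basis of reciprocal-cross ratio differences is
  not modeled.
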