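---
title: "Methods: composite selective-sweep scans in popsweep"
author: "popsweep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite selective-sweep scans in popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`popsweep` scans phased, ancestrally polarized SNP haplotypes from two
diverged populations for signatures of positive selection, combines
several per-SNP statistics into a single composite, aggregates it per
gene, and tests gene sets for enrichment. The central container is the
S4 class `HaplotypeSet`: an integer matrix of haplotypes (rows, two
consecutive rows per diploid sample) by sites (columns), with codes
0 = ancestral, 1 = derived, `NA` = missing call, per-site 1-based
coordinates, and per-haplotype population labels. Validity enforces
strictly increasing positions within a chromosome, pure 0/1/NA coding,
the 2-haplotypes-per-sample pairing, and at least two haplotypes per
population.

Gene annotation is held as a `GRanges` in its native 1-based closed
convention; every conversion happens exactly once at an I/O boundary
(VCF positions are 1-based and used as-is; BED intervals are 0-based
half-open and shifted on read). Centralising the conversions at the
boundaries is what removes off-by-one drift; the internal convention
itself is then free to follow the container's standard.

Polarization happens on read: the ancestral allele comes from the VCF
`AA` INFO key or from an explicit chromosome/position/allele table, and
genotype codes are flipped where the ancestral allele is the ALT base.
Sites whose ancestral state is missing, ambiguous, or matches neither
REF nor ALT are dropped and counted, as are multi-allelic and non-SNP
records (the statistics are biallelic-SNP statistics; records are never
split). Unphased genotypes are a hard error naming the sample and site,
because every haplotype statistic downstream assumes phase.

# Per-SNP statistics

**Derived allele frequency.** Per population, the derived count divided
by the non-missing haplotype count; missing calls leave the denominator.
ΔDAF = DAF(highland) − DAF(lowland).

**F_ST.** The Weir–Cockerham variance-components estimator θ̂ for two
populations. Because inputs are phased haplotypes, the default treats
haplotypes as haploid allele samples (the heterozygosity components drop
out); the full diploid a/b/c variant, with heterozygotes read off the
phased sample pairs, is available via `ploidy = "diploid"` since
published scans differ in which variant they use. Slightly negative
estimates are reported unclipped (they are informative about sampling
noise) but floored at zero when converted to selection probabilities, so
that ranking reflects "more differentiated, more selection-like". Sites
monomorphic in both populations are undefined (0/0) and reported `NA`.

**EHH and iHH.** The extended haplotype homozygosity of a group of
haplotypes at distance x from a core site is the probability that two
randomly drawn group members are identical over the interval from the
core to x. The implementation walks outward from the core keeping a
compact labelling of distinct extended haplotypes, so each step costs
O(group size). Two conventions deserve mention:

* EHH at distance 0 is 1 for every group, and haplotype identity spans
  the sites strictly beyond the core. For the allele-restricted groups
  used by iHS this is vacuous (carriers share the core allele); for the
  whole-population group used by XP-EHH it avoids penalising a
  population merely for being polymorphic at the core, which would
  otherwise systematically depress — and at partial sweeps sign-flip —
  the cross-population contrast.
* A haplotype that hits a missing call is removed from its identity
  class while the denominator stays C(n0, 2). Removal can only lower
  the numerator, so every EHH curve is monotone non-increasing by
  construction; treating missing as wildcard matches instead would
  break that invariant.

iHH is the trapezoidal integral of EHH over physical distance, summed
over the two directions. Each direction is truncated after the first
site whose EHH falls below the cutoff (default 0.05), including that
site's trapezoid; a direction that reaches the chromosome edge first is
flagged edge-truncated, and edge-truncated sites are dropped from the
scans rather than extrapolated (a truncated integral is biased low by an
unknown amount). A physical gap larger than `maxGap` (default 200 kb)
stops integration there and flags the site, which is kept. Integration
uses physical distance; no genetic maps are assumed (a uniform
per-bp rate is the implicit model), which matches the situation where
maps exist for none of the studied species.

**iHS.** ln(iHH_ancestral / iHH_derived) at each site passing the
minor-allele-frequency filter (default 0.05 within the scanned
population), z-scored within derived-allele-frequency bins (50
equal-width bins by default) because the neutral expectation of the raw
ratio depends strongly on DAF. Bins with fewer than `minBinSize`
(default 10) raw values are merged left-to-right with a warning; at
desk-scale site counts the merged bins are the common case, and the
default is deliberately lower than the hundreds-per-bin used on
chromosome-scale data.

**XP-EHH.** ln(iHH_popA / iHH_popB) over all haplotypes of each
population from the shared core, z-scored genome-wide. Positive values
mean longer haplotypes (more recent common ancestry) in popA. The raw
statistic is exactly antisymmetric under population swap, and the
z-score inherits that antisymmetry.

# The iFXD composite

Each chosen statistic is first mapped to a per-site probability of
positive selection. The composite is defined over such probabilities,
but how they are to be obtained is a genuinely open design point, so two
conversions are provided:

* `rank` (default): Ps = r/(N+1), the value's rank among the N
  non-missing sites (1 = least selection-like, average ranks on ties).
  This is assumption-free, strictly inside (0, 1) so no odds are
  infinite, and makes the composite a pure rank statistic.
* `normal`: the z-score's normal tail probability, clipped to
  [1/(N+1), N/(N+1)]. This rewards extremeness beyond rank but imports
  a distributional assumption.

Orientations: F_ST high, ΔDAF high, XP-EHH (highland over lowland)
high, iHS by absolute value (both unusually long derived and unusually
long ancestral haplotypes mark sweeps). The composite is

iFXD = ∏ Ps_i / (1 − Ps_i),

with log iFXD = Σ logit(Ps_i) also reported; sites missing any method
are skipped and counted. The default method set {F_ST, XP-EHH, ΔDAF}
matches a two-population mammal-style scan; {F_ST, XP-EHH, iHS} is the
human-style alternative. Gene scores are arithmetic means of member-SNP
iFXD (membership is position strictly inside the gene interval, no
flank by default; a flank parameter exists), ranked descending, with a
top-k report (k = 2 by default, the per-species reporting depth).
Because iFXD is a product of odds it is heavy-tailed; the arithmetic
mean is kept because it is what the composite's definition prescribes,
and the log-composite column is provided for inspection.

Sliding windows (size 50 kb, step 25 kb, anchored at position 0 of each
chromosome for determinism) average a chosen per-site statistic; the
empirical p of window w is #{windows with mean ≥ mean_w}/(N+1) — the +1
keeps −log10 p finite, and the count includes w itself so p ∈ (0, 1].

# Gene-set enrichment

Gene-level comparisons contrast a named set against all other scored
genes on a per-gene summary (maximum member F_ST, counts of SNPs with
|iHS| or XP-EHH above 2 — the conventional 2-SD cutoff, configurable —
or mean iFXD). SNP-level comparisons contrast SNPs inside set genes
against SNPs inside other genes; intergenic SNPs are excluded by default
(the stated contrast is genes versus other genes), with a switch to
include them, and SNPs in overlapping set and non-set genes count to the
set. Both use the Mann–Whitney U test, one-sided (set > other) by
default: exact when n1 + n2 ≤ 12 with no ties, otherwise the normal
approximation with tie and continuity corrections. The fully degenerate
all-values-tied case returns p = 1.

Permutation schemes that preserve linkage structure would give a better
null than SNP-level exchangeability; they are out of scope and the
SNP-level p-values should be read accordingly.

# Clinical contingency module

Positivity percentages are 100·a/n rounded half-up to one decimal
(272/487 = 55.85…% prints as 55.9, matching the conventional reporting
style; R's default banker's rounding would print 55.8 for exact halves).
2×2 association offers Yates-corrected chi-square (default — the
conventional choice when the source test is unnamed), plain chi-square,
and Fisher's exact test; the odds ratio is the plain cross-product
ad/bc, `NA` when a cell is zero (no Haldane correction, so the reported
ratio is never a shrunken artifact).

# The simulator and what it does (not) emulate

`simulateTwoPop()` is a forward Wright–Fisher simulator chosen over
coalescent machinery for transparency and exact sweep-trajectory truth.
One ancestral diploid population is initialised at a fixed site grid
with allele frequencies drawn from the neutral site-frequency spectrum
(P(i copies) ∝ 1/i) at linkage equilibrium for 85% of sites, evolves
neutrally for a burn-in during which drift and recombination build
linkage structure, then splits into highland and lowland populations
that drift independently. Mutation hits never-mutated grid sites (at
most one event per site, infinite-sites style; the pre-mutation state is
recorded as ancestral, so polarization of simulated data is perfect —
real-data mispolarization is deliberately out of scope). Recombination
is Poisson crossovers per transmitted chromosome at uniform positions.

Default study conditions: N = 1000 diploids per population, 1 Mb
chromosome with 400 grid sites, crossover 0.5 per transmission,
μ = 2×10⁻⁵ per site per generation, burn-in 80, post-split drift
T = 200 generations. T/2N = 0.1 puts the neutral background F_ST near
0.1 — the order observed between recently diverged highland/lowland
populations. These are desk-scale rescalings of a large outbred
population (small N, compressed time, correspondingly scaled-up
per-generation rates); runs take seconds, not hours.

The sweep, when enabled, is injected immediately after the split:
`initCopies` (default 10% of the 2N haplotypes, 200 at the default
population size) copies of one randomly chosen haplotype background
receive the derived allele at the sweep site, and the highland population then evolves under additive selection
with genotype fitnesses (1, 1+hs, 1+s), default h = 0.5, s = 0.05,
conditioned on non-loss by restarting the highland phase (restart count
reported in the truth object). The 10% standing frequency represents a
variant whose stochastic establishment phase is already past: with
s = 0.05 the deterministic trajectory then reaches a derived-allele
frequency near 0.95 within T = 200 generations, i.e. a completed or
nearly completed sweep — the regime the frequency-based statistics are
designed to detect. Injection from a single copy at these population
sizes would leave the final frequency anywhere between loss-conditioned
drift and fixation, which is a statement about trajectory stochasticity,
not about the scan.

Genes are tiled deterministically (20 kb genes, 5 kb gaps) and a
configurable fraction (default 25%) labeled as the "cancer" set, with an
option to force the sweep gene into or out of the set. All randomness
flows from the single config seed; identical configs give byte-identical
exports.

What the simulator does **not** emulate: deep coalescent linkage
disequilibrium (history is truncated at the burn-in), migration,
demographic size changes, background selection, variable recombination
and mutation rates, genotyping error and mispolarization. Passing tests
therefore demonstrate correctness of the statistics and the pipeline's
ranking behaviour under a clean two-population model, not robustness to
the confounders of real data.

# Numerical and testing choices

Problem sizes were chosen so the full suite runs comfortably on one
core: sweep-recovery checks use 20 replicates of the default
configuration; the EHH-statistic Monte-Carlo checks use 20 replicates of
a smaller, younger, stronger sweep (600 diploids, 500 kb, 600 sites,
sweep age 30 generations, s = 0.3) — the regime where haplotype-length
contrasts are sharpest, since EHH signals decay with sweep age while
frequency signals grow; null calibration uses 200 replicates (50 neutral
simulations × 4 independent random gene-set labelings — label
randomisation is exactly the null hypothesis of the enrichment test) of
a reduced neutral configuration.

One empirical limitation surfaced by these tests is worth recording: at
desk-scale site counts (50–100 scored sites), the DAF-bin z-scoring of
iHS caps how extreme the sweep site can look relative to the genome-wide
95th percentile of |iHS| — the sweep site is reliably the most negative
raw value but exceeds that percentile in only a minority of replicates,
across every regime tried. The tests therefore assert the directional
property (uniformly negative standardized iHS at the sweep site, mean
below −0.5), and the composite's power at chromosome scale should be
read from the XP-EHH and frequency statistics it actually combines.

Ties in gene ranking are broken by gene id for determinism. Empirical
probabilities use the +1 convention throughout so no log of zero ever
arises. Score tables serialize floats at 8 significant digits; round
trips through the TSV reader reproduce values to that precision.
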