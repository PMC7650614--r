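---
title: "Inversion karyotyping from SNPs and tag assays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion karyotyping from SNPs and tag assays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotag)
```

## The model

A paracentric inversion heterozygote suppresses recombination across the
rearranged segment, so the inverted and standard orientations accumulate
and maintain allele-frequency differences at sites inside the
breakpoints. Within that window, a cohort polymorphic for the inversion
behaves like a two-population mixture in Hardy–Weinberg proportions: the
two homokaryotype classes and their 1:1 "admixture", the heterokaryotype.
Principal component analysis of the within-inversion genotype matrix
therefore places specimens on three collinear, approximately equidistant
clusters ("stripes") along the leading component, ordered by inverted
chromosome dose. Anchoring those stripes with a handful of specimens of
known cytogenetic karyotype turns an unlabelled clustering into genotype
calls of 0 (standard homozygote), 1 (heterozygote), 2 (inverted
homozygote).

The same linkage argument motivates tag SNPs: a site whose alternate
allele rides the inverted orientation predicts inversion genotype by its
allele count alone. The association is strong but imperfect (double
crossovers, gene conversion), which is why tags are scored in aggregate:
the multilocus genotype is the mean alternate-allele dose over an
inversion's tags, binned back to 0/1/2.

## Pipeline parameters

All thresholds live in one object, `karyotag_thresholds()`:

* `min_mac = 4` (chromosomes): sites with a minor-allele count below 4
  carry too little information and inflate the matrix; counted over
  called chromosomes only, so missing genotypes contribute to neither
  allele class.
* `tag_concordance_min = 0.80`: a candidate tag must agree with the
  PCA-imputed genotype in at least 80 % of jointly genotyped specimens;
  the boundary value passes. Polarity is fixed — the reference assembly
  represents the un-inverted arrangement genome-wide, so a site whose
  *reference* allele tracks the inversion simply fails (a diagnostic
  column reports sites that would pass flipped, but they are never
  admitted).
* `min_n_compared = 20` specimens: a concordance estimated from fewer
  joint calls is too noisy to certify a tag; this guards against
  spurious 100 % tags from tiny denominators.
* `neighbor_window = 30` bp, inclusive: another segregating site within
  this distance disqualifies a candidate for probe/primer design.
* `min_total_reads = 10`, strict: a ratio genotype is attempted only
  when allele-1 + allele-2 counts exceed 10.
* Count-ratio cut-offs `ratio_hom1 = 10`, `ratio_hom2 = 0.1`,
  heterozygote band `[0.2, 5]`: inherited from the GT-seq genotyping
  pipeline (they are cited, not re-derived, by the assay literature);
  ratios in the ambiguous bands (0.1–0.2, 5–10) are uncalled. The
  defaults are symmetric under r → 1/r, which gives the genotype 0 ↔ 2
  swap symmetry the tests check.
* `call_rate_min = 0.80`, strict below: tag QC first, then specimen QC
  against the retained panel. The order matters and is fixed — dropping
  a failing tag can rescue a specimen — and specimen rates are computed
  over the whole multi-inversion panel, matching a single-plate
  workflow; per-inversion rates are reported as diagnostics only.
* `bin_edges = c(2/3, 4/3)`: the multilocus bins are exact thirds with
  upper edges closed (a mean of exactly 2/3 is genotype 0, exactly 4/3
  is genotype 1). The widely printed two-decimal rendering (0–0.67 /
  0.68–1.33 / 1.34–2) is available verbatim as
  `strict_printed_bins = TRUE` for audits; the two conventions differ
  only for means inside (0.6667, 0.67] and (1.3333, 1.34].

## Stripe finding and conformity

The stripe axis is PC1 alone; PC2 is kept for diagnostics and outlier
flagging but never drives assignment, because stripes separate along one
axis while geographic substructure tends to show up off-axis. Clustering
is deterministic 1-D k-means initialised at the minimum, median and
maximum of PC1. Model selection keeps the largest k ∈ {3, 2, 1} whose
adjacent centres are separated by more than twice the sum of the two
within-stripe standard deviations; a cohort fixed for one arrangement
spreads PC1 continuously and collapses to a single stripe rather than
being cut into artificial clusters. No random seed is involved anywhere
in the deterministic path.

Anchors label stripes by majority vote; a tied vote or a non-monotone
arrangement (labels must read 0,1,2 or 2,1,0 along PC1) is an error, and
minority anchors are reported as cytogenetic–PCA mismatches rather than
silently outvoted. When only one outer stripe carries anchors, the
remaining labels are inferred if exactly one monotone completion exists.

A specimen is non-conforming — flagged and left uncalled — when any of:

* its PC1 distance to its stripe centre exceeds `0.8 ×` half the minimum
  inter-centre gap;
* its stripe fails a shape diagnostic (middle centre more than 25 % of
  the outer gap away from the outer midpoint; within-stripe standard
  deviation above 30 % of the minimum gap);
* its PC2 deviation from the cohort median exceeds 6 × the robust PC2
  spread (MAD, floored at 1 % of the PC1 standard deviation) — the
  signature of specimens displaced by residual population structure
  rather than karyotype.

These three rules are explicit package constants, all overridable. Field
data exclude some specimens for "cryptic structure" without a stated
criterion; our rule is a declared stand-in, and its defaults were chosen
on geometric grounds, not calibrated to reproduce any particular
exclusion count.

## Missing-data conventions

PCA imputes missing genotypes by the per-site mean of called genotypes,
which keeps every specimen in the decomposition and is the standard
choice for genotype PCA; sites are centred but not variance-scaled
(no allele-frequency scaling term is assumed). Tag concordance and the
multilocus mean are computed over called values only, and an empty
denominator yields an undefined (missing) result, never zero. Uncalled
and half-called VCF genotypes both become missing; haploid or polyploid
records are an error, not a silent coercion. Multiallelic records are
dropped, not decomposed — ascertainment only ever saw biallelic sites.

## The simulator, and what it does not model

`simulate_inversion_cohort()` draws, per specimen, two orientation
chromosomes Bernoulli(q); per site, a base alternate-allele frequency
from a symmetric Beta(0.8, 0.8) rescaled into [d/2, 1 − d/2], with the
standard and inverted orientation frequencies at base ∓ d/2 so the
separation is exactly d; alleles are independent Bernoulli draws given
orientation. Defaults (n = 300, 1000 sites, q = 0.4, d = 0.8, 5 %
missingness, 20 % anchors) describe a well-powered cohort for an
inversion at intermediate frequency with strong orientation linkage —
the regime the method is designed for. Amplicon depth is
Poisson(100) per locus with a 0.5 % per-read probe-corruption rate.

Deliberately absent: background linkage disequilibrium, coalescent noise
around the per-site divergence, recombination/gene-flux inside the
inversion, demography, and geographic substructure (except for an
optional offset "second population" used to create non-conforming
specimens for tests). Passing tests on simulated cohorts therefore
demonstrates the estimator's correctness under its own assumptions —
stripe geometry, HWE, orientation-linked divergence — not robustness to
admixed or structured field samples, where the non-conforming flag is
expected to fire more often.

## Numerical and degenerate-input choices

The decomposition is an exact SVD (deterministic up to sign; calls are
anchor-labelled, so the PC1 sign is irrelevant and tested as such). A
matrix with zero variance or fewer than 3 specimens or 2 polymorphic
sites is an explicit error. k-means ties in point assignment break to
the lower-indexed centre; empty clusters reduce k. Genotype bins place
boundary means in the lower bin; the read-count rule is strictly
"greater than". Percentages print at one decimal using round-half-away-
from-zero (matching the field's reporting style); raw fractions and
counts are always carried alongside.

## Problem sizes in the checks

The acceptance-style tests run the defaults (300 × 1000) across ten
seeds for karyotype recovery, a five-point divergence grid at 150 × 200
for ascertainment behaviour, exhaustive enumeration of count pairs to
total 200 for the ratio genotyper, 10,000 random tag vectors against a
brute-force binning oracle, and 1,000 random 20 × 10 matrices against a
brute-force QC oracle — sizes chosen to exercise every rule and boundary
while keeping a full run in the tens of seconds.

## Known limitations

* Breakpoint spans are configuration values; no refinement is attempted,
  and sites just outside a mis-specified span are silently excluded.
* Anchored labelling requires at least one anchor in an outer stripe;
  cohorts anchored only at heterozygotes are rejected as unresolvable.
* The amplicon counter matches probes as exact forward-strand
  substrings, by design of the assay orientation; mismatch-tolerant or
  reverse-complement matching is intentionally not performed.
* Tag panels export every passing candidate; choosing a size-capped
  "best" subset (multiplex feasibility, pooling) is left to assay-design
  tooling.
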