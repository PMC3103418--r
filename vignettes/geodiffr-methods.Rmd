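---
title: "Methods: models, estimators and design choices in geodiffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in geodiffr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geodiffr)
```

`geodiffr` quantifies how the frequencies of disease risk alleles differ
among populations nested in geographic regions, and tests whether any SNP is
more differentiated than putatively neutral variation. This vignette is the
package's own account of the statistics it implements, the defaults it
ships, and the choices made where the design was genuinely open.

## Data model

A *panel* maps each sample to exactly one population and each population to
exactly one region; the seven continental areas of the HGDP system
(`default_regions()`) are the shipped vocabulary, but any region set can be
configured. Genotypes are biallelic calls stored as counts of allele A
(0/1/2, `NA` for missing). Missing genotypes are excluded from allele counts
(complete case per SNP per population): the simplest defensible contract,
since nothing downstream imputes.

Risk alleles from association catalogs frequently arrive on the opposite
strand from the genotyping platform. The reconciliation policy is the
standard merge hygiene: match by letter; if the risk allele matches neither
genotyped allele but matches the reverse complement of one, flip with a
warning; A/T and C/G SNPs — where a strand flip is indistinguishable from an
allele swap — are never auto-flipped and are dropped from frequency
computation with a warning. This policy is a package decision, not something
the underlying study methodology specifies.

## Risk-allele frequencies and the ΔF contrast

Per-population RAFs are allele-count ratios over non-missing calls. Region
summaries are **unweighted means over member populations** — populations,
not individuals, are the exchangeable units in the regional contrast — so a
large, densely sampled population cannot dominate its region.

For SNP *i* and region *r*,

$$\Delta F_{ir} = \bar F_{i,\mathrm{out}(r)} - \bar F_{i,\mathrm{in}(r)},$$

the difference between the mean RAF over populations outside and inside the
region. Negative values mean the risk allele is commoner inside. The null
distribution reassigns populations to regions uniformly at random while
preserving the observed region sizes — a pure relabeling, so the test asks
whether populations in the same region are more similar than an arbitrary
grouping of the same populations. Two open choices are resolved as follows:

* **Sidedness.** The test is two-sided on \(|\Delta F|\), matching the
  symmetric use of the ±0.3 threshold for "large" differences.
* **Correction.** p-values use the add-one rule
  \(p = (1 + \#\{|\Delta F^{perm}| \ge |\Delta F^{obs}|\})/(B + 1)\), which
  cannot return 0 and is valid for any number of permutations. A tie
  tolerance of \(10^{-12}\) keeps permutations whose statistic equals the
  observed one (up to floating-point rounding) in the tail; without it the
  p-value of symmetric configurations depends on rounding noise.
* **Missing data.** Populations with no data at a SNP are dropped from both
  the observed statistic and every permutation for that SNP.

The default 10,000 permutations give a p-value floor of about
\(10^{-4}\); the `|ΔF| > 0.3` flag uses a strict inequality.

## Weir–Cockerham F_ST

Population differentiation is estimated with the Weir–Cockerham (1984)
variance-component θ, computed from genotype data (allele frequencies,
observed heterozygosities and sample sizes per group): `a` is the
among-group component, `b` among individuals within groups, `c` within
individuals, and θ = a/(a+b+c). The exact formulas are in the
`weir_fst_components()` documentation; the test suite verifies them to
\(10^{-10}\) against an independently coded nested-ANOVA implementation on
thousands of random fixtures.

Numerical conventions:

* **Negative θ** estimates are reported as computed (a `truncate` flag
  clamps at 0). Truncation would bias averages of θ over SNPs upward.
* **Monomorphic SNPs** (a+b+c = 0 over the groups considered) are flagged
  `NA`, never coerced to 0 — "no variation" is not "no differentiation".
* Groups with zero non-missing calls at a SNP are dropped for that SNP; the
  estimator also requires mean group size above one individual.
* The **mean global F_ST** over a SNP set is the unweighted arithmetic mean
  of the defined per-SNP θ values (average-of-ratios). The alternative
  ratio-of-averages is larger in expectation; the average-of-ratios matches
  the "mean of the per-SNP global values" reading and is what the package
  reports, consistently, everywhere.

Three scales are computed from the same genotypes: global (all populations
as groups), region-pair (individuals of a region's populations pooled, i.e.
the two merged groups), and population-pair matrices.

## Empirical significance against a neutral panel

Model-based null distributions for θ are unreliable under real demography,
so significance is empirical: the observed SNP's global θ is ranked within
the θ of a large panel of putatively neutral SNPs genotyped on the same
individuals, with the add-one rule \(P = (1 + \#\{\theta_{null} \ge
\theta_{obs}\})/(N+1)\). Because θ's null distribution depends on allele
frequency, a corrected \(P_{cor}\) ranks only within the SNP's folded
minor-allele-frequency bin. Defaults: bin width 0.05 (ten bins over
(0, 0.5]); a bin must hold at least 20 neutral SNPs or \(P_{cor}\) is
reported unavailable rather than computed from a sliver. Both choices are
configurable; the bin width is a convention, not an estimate.

The frequency-matched mean-F_ST comparison draws, per resample, one neutral
SNP from each target SNP's MAF bin without replacement and compares the
target mean θ to the resampled means with the same add-one rule. With the
default 1,000 resamples the p-value floor is 1/1001.

Bonferroni and Benjamini–Hochberg adjustments are delegated to
`stats::p.adjust`.

## Geography

Distances are haversine great circles on a 6371-km sphere. Pairs of
populations in different regions are routed through obligatory waypoints in
the style of the classic land-migration distance literature (Cairo,
Istanbul, Phnom Penh, Anadyr, Prince Rupert); the shipped route table is a
**reconstruction from that literature, not a published supplement**, and is
fully overridable via a waypoint TSV. Same-region pairs and land-contiguous
Eurasian region pairs are direct. A region pair without a route falls back
to the direct distance with a warning.

Isolation by distance is ordinary least squares of pairwise θ on kilometres:
per SNP, and pooled by stacking all SNP × pair observations (the package
reports both; whether a combined analysis should stack observations or first
average θ per pair is an open convention — averaging removes per-SNP
sampling noise and yields a much higher R², so the two must not be
compared). Pairs with undefined θ are dropped pairwise; per-SNP fits with
fewer than three informative pairs return `NA` with a warning. Slope
significance is the standard t-test; no Mantel test or spatial
autocorrelation correction is attempted, so p-values on the pooled fit
ignore the dependence among pairs sharing a population and should be read
qualitatively.

## The synthetic-data generator

`simulate_dataset()` implements a two-level Balding–Nichols hierarchy:
ancestral frequency \(p \sim\) Uniform(0.05, 0.95) by default (a Beta
option exists); region frequency \(p_r \sim \mathrm{Beta}\big(p(1-F_R)/F_R,
(1-p)(1-F_R)/F_R\big)\) with \(F_R\) = `f_region`; population frequency
likewise around \(p_r\) with `f_pop`; genotypes Binomial(2, \(p_k\)) under
Hardy–Weinberg. The law of total variance gives the design differentiation
\(E[F_{ST}] = f_{region} + f_{pop} - f_{region} f_{pop}\), which is what
makes parameter-recovery tests possible.

Shipped defaults emulate the HGDP-style study system: 7 regions × 4
populations × 20 individuals (the real panel has 52 populations of very
uneven size; the simulator accepts per-region and per-population vectors),
`f_region = 0.10` — chosen so that region-level drift alone reproduces a
mean global θ near the ~0.10 observed for worldwide human samples —
`f_pop = 0.05` for within-region structure, and a 2,036-SNP neutral panel
matching the size of the intergenic marker set used as an empirical null in
the motivating study design. Outlier SNPs multiply `f_region` by
`outlier_boost` (artificially over-differentiated loci with known truth).
The `serial` regional model chains the regional drift along the
out-of-Africa expansion order instead of drawing regions independently;
only this regime carries an isolation-by-distance signal, and it is the one
used for IBD sign-recovery checks.

What the generator does **not** emulate: linkage disequilibrium (every SNP
is independent), haplotype structure (so no iHS-style statistics),
ascertainment bias of GWAS SNP discovery, non-equilibrium genotype error,
or admixed individuals. Passing tests therefore demonstrate correctness of
the estimators and calibration of the permutation/empirical nulls under the
model, not robustness to those real-data features.

## Test design and problem sizes

The suite builds all fixtures in code. Oracles are independent
implementations, not the code under test: a nested-ANOVA route for θ,
exhaustive enumeration for small permutation and resampling nulls, the
spherical law of cosines for distances, closed-form normal equations for
OLS. Calibration checks use 500 SNPs × 1,000 permutations
(Kolmogorov–Smirnov uniformity at α = 0.01), recovery checks 2,000 SNPs at
the 7 × 4 × 20 design, and outlier-recovery checks 125 planted SNPs against
a 2,036-SNP null — sizes chosen to keep Monte-Carlo noise well below the
asserted tolerances while the full suite runs in well under a minute.

## Known limitations

* **Outlier-detection power is bounded by the number of regions.** A
  fourfold boost of `f_region` is realized through only seven regional
  frequency draws, so the per-SNP θ of boosted SNPs is highly dispersed and
  overlaps the neutral null's upper tail; under the default study
  conditions the package's own tests measure recovery by \(P_{cor} <
  0.05\) at about 76–78%, and no estimator choice can remove that overlap.
  Detection of individual outliers on 7-region data should be read with
  this in mind.
* The empirical null assumes the neutral panel is genotyped on the same
  individuals as the tested SNPs; the package enforces a shared panel in
  simulation but cannot verify neutrality of a user-supplied panel.
* ΔF p-values across the SNP × region grid are reported without family-wise
  correction (by design, matching the contrast's exploratory use); the
  multiple-testing helpers apply to the empirical F_ST p-values.
* Waypoint routing is a coarse model of migration distance; populations
  near a route's junction (e.g. North Africa) can be assigned slightly
  longer paths than plausible.
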