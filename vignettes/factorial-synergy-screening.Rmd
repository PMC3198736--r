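---
title: "Detecting synergistic expression changes in a 2x2 factorial mutant design"
author: "synergyscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting synergistic expression changes in a 2x2 factorial mutant design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyscreen)
```

## The problem

When two regulators are individually dispensable but jointly essential --
as with the *SEUSS* (*SEU*) and *AINTEGUMENTA* (*ANT*) transcriptional
regulators of the Arabidopsis carpel margin meristem, whose double
mutant loses ovule initiation entirely -- the genes mediating that
redundancy are expected to respond *non-additively*: modestly reduced in
each single mutant, collapsed in the double mutant. `synergyscreen`
implements the statistical machinery for finding such genes from a
four-genotype expression experiment: wild type (WT), the two single
mutants (A, B), and the double mutant (AB), each profiled in a small
number of replicate arrays or libraries on the log2 scale.

## The model

Per gene the package fits the one-way fixed-effect ANOVA

$$y_{gj} = \mu_g + \varepsilon_{gj},\qquad
  \varepsilon_{gj} \sim N(0, \sigma^2),\quad g \in \{\mathrm{WT, A, B, AB}\}$$

by least squares ([genotype_anova()]); in a balanced design the LSmeans
$\hat\mu_g$ are the arithmetic genotype means and $\hat\sigma^2$ is the
pooled residual mean square on $\nu = \sum_g n_g - 4$ degrees of
freedom. Everything downstream is a linear contrast of the LSmeans with
standard error $\hat\sigma\sqrt{\sum_g w_g^2/n_g}$ and a two-sided t
test on $\nu$ df.

Under the additive null the single-mutant effects add on the log2
scale, so the expected double-mutant mean is
$\mu_A + \mu_B - \mu_{WT}$. The non-additivity deviation is the
interaction contrast

$$\delta = \mu_{AB} - \mu_A - \mu_B + \mu_{WT},$$

with weights $(+1, -1, -1, +1)$; $\delta = 0$ is the additive null and
$\delta < 0$ a synergistic loss of expression in the double mutant.
Additivity of *effects* is the only dimensionally consistent reading of
an "additive model using the data from each single mutant" on absolute
log2 means (literally adding two means near 9 would predict a value
near 18), and it is the interaction contrast a factorial estimate
builder encodes; under it every row of the curated candidate table
comes out synergistic-negative, which is what that screen claimed.

Two screens consume the fits:

* **Differential screen** (`approach1_screen()`): the target genotype is
  contrasted against wild type or against the grand mean
  (weights $1 - 1/G$ on the target, $-1/G$ elsewhere); Storey pFDR
  q-values are computed across genes, and membership requires
  `q <= alpha` (default 0.05), a strict `|log2 difference| > 0.35`
  (about 1.27-fold), and the matching sign. Both baselines are exposed
  because single-mutant comparisons are naturally wild-type-anchored
  while a double-mutant comparison against the overall mean is also in
  use; no silent default beyond `"wt"` is taken.
* **Synergy screen** (`synergy_screen()`): a gene passes when at least
  one single mutant is significantly *below* wild type (criterion 1)
  and its $\delta$ is negative with two-sided $p < \alpha$
  (criterion 2). The two-sided test plus the sign requirement
  reproduces a "significance cutoff and lower-than" rule without
  committing to a one-sided alternative, which could not be
  established for the original analysis. Criterion 1 can judge
  significance on q-values computed across genes (default, mirroring a
  pFDR-screened single-mutant list) or on raw per-gene p-values
  (`criterion1 = "rawp"`); exact ties $\delta = 0$ are never
  candidates.

## Multiple testing

`pfdr_qvalues()` implements Storey's positive-false-discovery-rate
q-values. The null proportion is estimated as
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0.05, 0.10, \ldots, 0.95$ and read off at $\lambda = 0.95$
by linear interpolation, capped into $(0, 1]$ (a degenerate all-small-p
input falls back to $1/m$). This deliberately avoids an opaque
smoothing step; with $\hat\pi_0$ fixed at 1 the q-values are exactly
Benjamini-Hochberg adjusted p-values, which the test suite asserts.
q-values are enforced monotone non-decreasing in p.

## Normalization and summarization

Arrays are first compared by their value distributions
(`qc_distribution_summary()`; an array is flagged when its median sits
more than 1 log2 unit from the median of medians -- a screen for
inspection, not an automatic exclusion). Between-array trends are
removed by pairwise cyclic loess on MA coordinates
(`cyclic_loess_normalize()`, delegating to limma's pairwise method):
for each array pair the log-ratio M is regressed on the average
intensity A, and half the fitted trend is subtracted from one array and
added to the other, cycling over all pairs (span 0.3 of the points, 2
iterations by default, both configurable). The correction is pairwise
symmetric, so the grand mean is conserved to well under 0.01 log2.
Local regression has inflated variance at the intensity extremes, so a
second pass still moves a few extreme-intensity genes visibly; the
suite asserts near-idempotence for the bulk (99th percentile of
second-pass adjustments below 0.05 log2 at 2000 genes) rather than the
maximum. Probe-level rows collapse to probe-set values by the
arithmetic mean (`summarize_probesets()`); probes mapping to several
targets contribute to each, mirroring shared-probe behaviour on
three-prime expression arrays without requiring chip metadata.
Whether the original loess ran on raw or log2 intensities is not
recoverable; log2 is assumed throughout.

## Over-representation

Candidate sets are tested against flat term-to-gene maps by the
hypergeometric upper tail $P(X \ge k)$ (`hypergeom_upper_tail()`,
`enrich_terms()`), the probability of at least the observed overlap
under sampling without replacement. The universe defaults to the
profiled genes (an array is its own universe, not the genome), terms
are flagged at `p < 0.001` with no multiple-testing correction --
matching the screening convention this reproduces -- and an optional BH
column is available. No ontology-graph propagation is attempted: terms
are opaque gene sets. With the printed counts (7 of 31 candidates in a
118-gene family on a 22,810-feature universe) the upper tail is
1.96e-10; the value printed alongside those counts in the source
screen, 2.5e-10, is not reproducible from them at two significant
figures under either the tail or the point probability, consistent
with a slightly smaller (unprinted) annotated universe having been
used. The growth-regulating-factor family check requires a family size
that was never printed; with the family's nine members supplied
externally the tail is 6.4e-5, against 6.9e-5 printed -- a documented
approximate check, not an anchor.

## qRT-PCR verification

`normalized_expression()` quantifies at 100% amplification efficiency:
technical replicates are averaged on the Ct scale, then each biological
replicate contributes $2^{Ct_{ref} - Ct_{target}}$. This convention
yields values above 1 for targets amplifying earlier than the
reference, matching published wild-type values above 1 for an abundant
target, and makes the generator's round trip exact at zero noise.
Reference stability is checked pairwise (`reference_stability()`): the
per-replicate difference in Ct between two candidate references is
subjected to a one-way ANOVA by genotype; a stable pair shows no
genotype effect at $\alpha = 0.05$, and an all-constant difference is
flagged degenerate and treated stable. Group comparisons use the
Tukey-Kramer studentized-range test (`tukey_hsd()`, on pooled
within-group variance, valid for unequal group sizes) with a compact
letter display built by the insert-and-absorb algorithm: groups are
taken in descending-mean order, each significant pair splits every
letter column containing both, subset columns are absorbed, and two
groups share a letter exactly when they are not significantly
different -- an invariant the suite asserts against the p-value matrix
on every simulated case, and cross-checks against an independent
multiple-comparison implementation. The test runs on normalized
expression values by default; published letter patterns reconstructed
from means and SEMs alone are treated as consistency checks, since raw
Ct values were never published and borderline pairs can flip.

## The synthetic-data generator

`simulate_expression()` draws per-gene baselines
$\mu_0 \sim N(9, 1)$ log2 units (matching the 6.8-11.9 range of the
curated candidate LSmeans), single-mutant effects with configurable
mean and SD, and an interaction $d$ that is exactly zero for
non-synergistic genes and $N(s, 0.1|s|)$ for the synergistic fraction
(default shift $s = -1$, fraction 0.05) -- a sharp null so type-I error
is measurable. Replicate noise is homoscedastic Gaussian
($\sigma = 0.3$ log2 by default), deliberately matching the fitted
ANOVA; three replicates per genotype is the default (the replicate
count of the motivating experiment is not on record, and the curated
fixtures do not depend on it). The generator therefore emulates the
factorial design and the additive/non-additive structure, but not
heavy-tailed or intensity-dependent noise, probe-level chip geometry,
amplification chemistry, or correlated genes; passing calibration
tests demonstrate correctness of the statistics under the stated
model, not robustness to those real-data features.
`inject_intensity_distortion()` adds the smooth per-array curves that
loess normalization targets; `simulate_annotation()` plants one
enriched family with an exact candidate overlap among random decoys;
`simulate_qpcr()` generates Ct tables (default four biological
replicates in triplicate) whose expected normalized expression is
exactly $2^{\mathrm{level} - \mathrm{level}_{ref}}$, with biological
noise per replicate and technical noise per well, both in cycles, at
one cycle per doubling.

## Numerical and design notes

* Degenerate fits (zero residual df, or zero residual variance with a
  non-zero effect) carry `NA` statistics and a flag; all-constant genes
  get $F = 0$, $p = 1$. Noiseless, perfectly additive input therefore
  yields an empty candidate set rather than an error.
* The hypergeometric tail uses the survival function directly, stable
  at universe sizes in the tens of thousands and p-values past 1e-10;
  the suite verifies it against exact enumeration on every universe up
  to size 30 and against a log-space enumeration at array scale.
* Ties in the letter display are resolved by stable descending-mean
  ordering; contrast weights may be given by genotype name in any
  order.
* Screens are invariant to gene ordering, and all generators are
  bit-reproducible for a fixed seed.
* Problem sizes used by the calibration checks: 10,000 genes for
  test size under the additive null (three binomial SDs around 0.05),
  2,000 genes with a 5% planted synergistic fraction for the screen's
  operating point, 1,000 genes for normalization trend removal, and
  100-seed Monte Carlo for the qPCR knockdown round trip.

## Known limitations

* The screen's sensitivity is criterion-1-bound in small designs: with
  few replicates and small single-mutant effects, the single-mutant
  significance requirement is far weaker than the interaction test
  itself (and weaker still after q-value adjustment), so many genuinely
  synergistic genes fail criterion 1 even when their interaction is
  detected. The acceptance script reports the measured sensitivity and
  specificity on the calibration simulation; the conservatism is a
  property of the published selection cascade, not of the
  implementation.
* Variance is estimated per gene with no information sharing; with two
  or three replicates per genotype the t tests are valid but weak.
  Empirical-Bayes moderation is deliberately out of scope.
* One-way fixed-effect ANOVA only: no multi-factor models, no mixed
  effects, no probe-level error models.
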