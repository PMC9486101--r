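---
title: "Meta-QTL analysis for yield traits under contrasting water regimes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatmqtl)
```

## The problem

Hundreds of quantitative trait loci (QTL) for yield components have been
mapped in durum wheat biparental populations, each on its own linkage map,
in its own environment, with its own precision. Individually most explain
little variance and replicate poorly. Meta-QTL (MQTL) analysis pools them:
QTL from independent studies are placed on one consensus map and clustered
into consensus loci with refined positions and narrowed confidence
intervals. Because drought is the dominant stress for this crop, the QTL
catalog distinguishes two water regimes (irrigated vs rainfed), the
meta-analysis is run per regime, and regions where both regimes' MQTL
coincide are of particular interest: they mark loci stable across water
availability.

`wheatmqtl` implements the full chain: catalog ingestion and screening, CI
standardization, homothetic projection, per-chromosome clustering with
information-criterion model selection, cross-regime overlap detection, a
candidate-gene stage, and a synthetic-data generator with known ground
truth for validation.

## Confidence-interval standardization

Published QTL often lack a 95% CI. For those, the CI width (cM) is
estimated from the population design, the population size $N$ and the
proportion of phenotypic variance explained $R^2$:

$$
CI = \frac{530}{N R^2} \;(\text{BC, F}_2),\qquad
CI = \frac{287}{N R^2} \;(\text{DH}),\qquad
CI = \frac{163}{N R^2} \;(\text{RIL}).
$$

F$_{2:3}$ populations use the F$_2$ constant and MAGIC populations the RIL
constant (nearest design by inbreeding structure); the constant table is a
`constants` argument, so other conventions can be substituted. Reported
CIs always take precedence — the formula only fills gaps. A record with a
CI but no peak takes the interval midpoint as its peak (the formula
interval is symmetric, so this is the convention's own fixed point).
Intervals are clipped at 0 and, when a map is available, at the
chromosome length.

PVE scale is detected per file: a supplement whose values are mostly above
1 (and at most 100) is read as percent and divided by 100 with a logged
conversion; in a proportion-scale file, a stray value above 1 violates the
$R^2 \in (0,1]$ invariant and the row is rejected with a reason code
rather than silently rescaled.

## Homothetic projection

A QTL at position $x$ on its study map is moved to the consensus map by
linear rescaling between the tightest pair of markers shared by both maps
that brackets $x$:

$$
x' = c_L + (x - s_L)\,\frac{c_R - c_L}{s_R - s_L},
$$

where $(s_L, s_R)$ and $(c_L, c_R)$ are the anchor positions on the study
and consensus maps. Peak and both CI bounds are each projected through
their own tightest anchor pair (piecewise-linear homothety), which is how
consensus-projection tools behave when many shared markers exist, and
which preserves marker order and makes projection onto the source map the
exact identity.

Two conservative rules apply. First, no extrapolation: a peak outside the
span of all shared markers cannot be rescaled with any bounded error
guarantee, so the QTL is rejected with status
`rejected_no_shared_markers`. A CI *bound* outside the shared span (peak
still inside) is projected through the peak's anchor pair and flagged
`bound_extrapolated` instead of discarding the record. Second, a ceiling
on the projected CI width (default `max_ci_cm = 50`) removes QTL whose
low PVE makes their interval so wide it would smear across half a
chromosome; the literature states this rule without a numeric threshold,
so the ceiling is a configurable parameter and 50 cM — roughly a
chromosome arm on this consensus map — is the default.

Coordinates stay continuous throughout; nothing is rounded except in
printed reports (2 decimals).

## The clustering model

On each chromosome, within each regime, every projected QTL contributes a
position $x_i$ (consensus cM) and a standard deviation
$s_i = CI_i / 3.92$, the Gaussian 95% convention. The meta-model is a
$K$-component Gaussian mixture with *fixed per-observation variances*:

$$
x_i \sim \sum_{k=1}^{K} \pi_k\, \mathcal{N}(\mu_k,\, s_i^2),
$$

where only the MQTL positions $\mu_k$ and the weights $\pi_k$ are free
($p = 2K - 1$ parameters). The variances are data, not parameters: each
study's reported precision is taken at face value.

**More than ten QTL:** EM. The E step computes responsibilities; the M
step updates each $\mu_k$ as the responsibility-weighted
precision-weighted mean and $\pi_k$ as the mean responsibility. The
log-likelihood is verified non-decreasing at every iteration.
Initialization is a deterministic start at $K$ precision-weighted
quantiles of $x$ plus 10 seeded random restarts; convergence at relative
log-likelihood change below $10^{-8}$ or 2,000 iterations; a start that
collapses a component ($\pi_k < 1/(10n)$) is penalized so a
non-degenerate start wins whenever one exists. $K$ ranges over
$1..\min(n, 10)$. $K = 1$ needs no EM: the maximum-likelihood mean is the
precision-weighted mean $\left(\sum x_i/s_i^2\right)/\left(\sum 1/s_i^2\right)$ in
closed form.

**Ten or fewer QTL:** best contiguous partition. The position-ordered
observations are split into $k$ contiguous blocks, each block one
Gaussian mean with its members' fixed variances, maximizing the
classification log-likelihood by dynamic programming over block
boundaries (verified against exhaustive enumeration in the test suite).
Candidate block counts are $1..\min(n,4)$ plus $n$. To let the same
selection rule serve both paths, the five criteria are computed from the
classification log-likelihood with block weights equal to member
fractions and the same $p = 2k - 1$ count.

**Model selection.** Five criteria are computed for every candidate:

* $AIC = -2\ln L + 2p$
* $AICc = AIC + 2p(p+1)/(n-p-1)$, reported as $\infty$ when
  $n - p - 1 \le 0$ (inadmissible)
* $AIC3 = -2\ln L + 3p$
* $BIC = -2\ln L + p\ln n$
* $AWE = -2\ln L_c + 2p(3/2 + \ln n)$, with $\ln L_c$ the classification
  (hard-assignment) log-likelihood

The chosen $K$ is the candidate attaining the minimum of at least three
of the five; when no candidate reaches three votes the AICc minimizer is
used and the choice flagged as a fallback. Ties at a criterion's minimum
credit the smaller $K$.

**From components to MQTL.** Observations go to their argmax-posterior
component (exact posterior ties to the nearer mean, then the lower
index — fully deterministic). A component is admitted as an MQTL only
with at least 2 member QTL from at least 2 distinct studies; a single
population re-detecting its own QTL across environments is not
replication. The MQTL peak is the members' precision-weighted mean and
its 95% CI width is $3.92\,(\sum_i 1/s_i^2)^{-1/2}$ — precision addition,
which guarantees the MQTL CI is never wider than its narrowest member's
CI. Flanking markers are the nearest consensus markers at or outside the
CI bounds. Non-members remain singletons annotated with one of three
leftover rules, applied as interval tests against admitted MQTL CIs: the
QTL's CI overlaps no MQTL, it overlaps more than one (its CI is too
large to place), or its peak falls outside the single MQTL it overlaps.
Members plus singletons always account for every observation.

## Cross-regime overlap

Each MQTL contributes the interval peak ± CI/2 (clipped at 0). For every
chromosome, all pairwise intersections between one irrigated and one
rainfed interval are computed — touching endpoints count — and
intersections that themselves overlap merge into maximal regions whose
peak is the interval midpoint. Intersection of 95% CIs is the default
convention because it is the most conservative interpretable choice; the
published intervals for such stable regions are not reconstructible from
the per-regime tables under any peak ± CI/2 rule, so the region *count*
is comparable but exact intervals are not. The operation is symmetric in
its arguments, and widening any CI can only add regions.

## Candidate genes

An MQTL's flanking markers are located on the physical assembly through a
marker-position table; the bracketed interval (normalized ascending, both
markers required on one chromosome) is intersected with the gene-type
features of a GFF3 annotation under the any-overlap rule. Intervals are
handled as 1-based inclusive coordinates throughout, the R/Bioconductor
convention (`IRanges`), rather than half-open 0-based. Genes are kept
when their expression strictly exceeds a tpm threshold (default 3,
strict inequality) in at least one user-selected stress condition; which condition labels count as drought-related is
deliberately user-supplied, since published expression compendia label
experiments inconsistently.

## The synthetic generator

The generator emulates the curated catalog, not meioses: no genotypes are
simulated, only the QTL-report level the meta-analysis consumes.
Defaults are the catalog's gross structure: 14 chromosomes (1A–7B) of
188 cM (≈2,631 cM total), 724 QTL from 25 studies, ≈65% of QTL under the
rainfed regime (468/724), population sizes 93–338 with RIL designs
dominating, PVE from Beta(4, 25) — the unique Beta family member with
mean 0.138 and 84% of its mass below 0.20, matching the catalog's
reported distribution — and LOD loosely increasing with PVE. Marker
density defaults to 1 marker/cM, a tenth of the real consensus map's 11
markers/cM; the projection anchors are far denser than the QTL spacing
either way, and the full-density map is a parameter away. Three true
MQTL per chromosome, active under both regimes, sit jittered at 15–85%
of chromosome length. Study peaks scatter
$\mathcal{N}(\mu, \sigma_{between}^2)$ with $\sigma_{between} = 2$ cM
around their generating MQTL, expressed in study-map coordinates through
each study map's monotone piecewise-linear distortion (slopes within
±10%, 30% marker retention by default). Half the records omit their CI
to exercise the formula path; the others carry the formula width
explicitly.

Everything is deterministic per seed (R's Mersenne-Twister; each stage
derives its own sub-seed), and generated catalogs always pass the
inclusion screen.

**What passing recovery tests do and do not show.** The generator shares
the meta-model's geometry (Gaussian clusters on a line) but *not* its
variance assumption: a study's peak scatters by $\sigma_{between}$
regardless of how precise its own CI claims to be. That mirrors real
catalogs — reported CIs are frequently optimistic — and it makes the
recovery experiment a stress test of model selection, not a
rubber stamp. QTL whose formula CI implies $s_i \ll \sigma_{between}$
(large $N R^2$) sit several of their own standard deviations from their
cluster mean, and the likelihood then genuinely supports splitting the
cluster; AIC, AICc and AIC3 follow that support, while AWE (and often
BIC) resist it. As a consequence the five-criterion vote recovers the
true component count in only a fraction of stressed replicates (the test
suite and `scripts/acceptance.R` compute the exact rate), although
recovered *positions* stay accurate (RMSE well under 1.5 cM) and member
purity is essentially perfect — extra components split a true cluster
rather than inventing spurious loci, and admission rules prune most of
them. With self-consistent noise ($\sigma_{between} = 0$, distortion
only) recovery is exact. On real catalogs this means: trust MQTL
positions and membership more than the exact component count on
QTL-dense chromosomes, and read the per-chromosome criteria table (kept
in the fitted object) rather than the vote alone.

## Numerical choices and degenerate inputs

* CI→SD conversion 3.92 ($2 \times 1.96$); zero-width CIs are disallowed
  ($s_i > 0$), and projected widths are floored at $10^{-6}$ cM before
  conversion.
* EM tolerance $10^{-8}$ relative, cap 2,000 iterations; monotonicity
  asserted each iteration.
* Exact-position anchor hits project to the shared marker's consensus
  position directly; anchor pairs must have distinct consensus
  positions, else the search widens to the next admissible pair.
* A chromosome with a single projected QTL fits $K = 1$ trivially and
  yields a singleton (admission needs two studies).
* All randomness flows from one top-level seed recorded in the run
  manifest; rerunning a pipeline config reproduces result tables
  byte-identically.

## Known limitations

* Model-selection sensitivity to CI-vs-scatter inconsistency, described
  above; this is a property of fixed-variance mixture criteria, not of
  this implementation.
* The exact criterion variants of the reference desktop tool are not
  published; the formulas above are documented and standard, but
  numerical identity with that tool is not claimed.
* Marker matching between maps is exact string matching (after
  whitespace trimming); synonymous marker names are not resolved.
* The candidate-gene stage is file-driven; no genome browser or
  expression database access is attempted.
* Projection assumes locally linear map relationships between shared
  anchors; strong local inversions between maps are not modeled (marker
  order is assumed consistent).
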