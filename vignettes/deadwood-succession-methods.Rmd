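---
title: "Methods: functional-phylogenetic diversity and succession in deadwood beetle communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional-phylogenetic diversity and succession in deadwood beetle communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters and the
numerical choices, what the synthetic generator does and does not
emulate, and the design decisions that were genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The study design the data model encodes

Emergence records are indexed by deadwood log, calendar year and species.
Analyses run on *years since exposure*, computed per log as
`calendar_year - exposure_start`. The exposure origin is data, not code:
spruce logs uprooted in spring of their first sampling year start at year
0, while beech and fir logs cut the previous autumn start at year 1 in
their first sampled season. A sampling year can be missing (here 2020);
because all trend models treat year as a numeric covariate under
penalized smooths, the gap needs no imputation and is represented as
absent rows — never zero-filled. Sampled log-years without any beetle, by
contrast, are genuine zeros and enter the count models as such.

## Functional-phylogenetic distance and its null model

Functional distances are Gower distances over 13 morphological and 4
ecological traits. Continuous and rank-scaled ordinal traits contribute
`|x_i - x_j| / range`, categorical traits 0/1 matching, averaged over the
traits non-missing in both species (pairwise deletion; computed with
`cluster::daisy`). Three choices matter:

* **Transformation order.** Traits flagged for body-length
  standardization are divided by raw body length first; log
  transformation follows. Size-corrected ratios are the quantities for
  which a log transform is meaningful, so this order is fixed and the
  applied transformations are recorded in a provenance attribute. The
  per-trait assignments live in a schema file (trait, type, flags, level
  order) so they are configuration, not code.
* **Range normalization over the full pool.** Gower ranges are computed
  over the complete species pool and the matrix is subset afterwards,
  keeping distances comparable across assemblages and years.
* **Ordinal traits as scaled ranks** before the continuous formula — the
  common Gower dialect for ordered classes.

Phylogenetic distances are cophenetic (branch-length path sums). Species
missing from a reference phylogeny are grafted as sisters of their
closest known relative; the new tip's pendant branch (`epsilon`, default
0) is carved out of the relative's pendant edge so that all pre-existing
tip depths and pairwise distances are preserved exactly. `epsilon = 0`
makes the graft inherit its relative's position — legitimate for mean
pairwise distance, though degenerate for diagnostics that dislike zero
distances, hence configurable.

The blended distance is `(a P^p + (1-a) F^p)^(1/p)` after each source
matrix is divided by its own maximum. Endpoints reproduce the rescaled
sources exactly (`a = 0` functional, `a = 1` phylogenetic). The exponent
`p` defaults to the canonical quadratic blend `p = 2` and is exposed
because the blend family is defined for any positive exponent; rescaling
is on by default and recorded.

The null model is tip shuffling: species labels of the blended matrix are
permuted over the full pool observed in the study (not per-year pools),
with assemblage memberships held fixed. MPD is presence-based by default
(abundance weighting is available behind a flag). SES is undefined — and
flagged, not silently dropped to zero — when the null standard deviation
vanishes, e.g. for an assemblage equal to the whole pool; a relative
tolerance of `1e-10` guards against the floating-point jitter of sums
taken in permuted order. Because both the observed MPD and its null
rescale together, SES is invariant under any global rescaling of the
distance matrix. With 999 shuffles the SES of random assemblages is
calibrated to mean 0, SD 1 within sampling error (the test suite checks
500 assemblages, and checks exact equality with the enumerated 4!-
permutation null on a four-species pool).

## Trend models

All four responses (abundance, species number, species richness, SES
MFPD) share one structure, fitted with `mgcv::gam`:

* tree species as a fixed effect (baseline differences);
* one penalized smooth of exposure year per tree species
  (`s(year, by = tree_species)`, basis size `k_year = 10`, capped at the
  number of distinct years);
* an isotropic thin-plate smooth of the projected log coordinates
  (`s(E, N, bs = "tp")`, default basis 30, capped below the number of
  distinct coordinates and dropped when fewer than five exist) absorbing
  repeated-measures and spatial structure;
* negative binomial with log link for counts (dispersion estimated
  within the fit), Gaussian identity for SES;
* REML smoothing-parameter selection, pinned for reproducibility. On
  exactly degenerate responses (zero variance) REML's derivative-based
  optimizer fails and the fit falls back to GCV; this is documented
  behaviour, not an error path.

The richness model adds natural-log abundance as a fixed covariate to the
species-number response: flat, non-significant year smooths then say the
species number is explained by abundance alone (more-individuals
hypothesis), while residual year structure indicates changing niche
availability. Natural log was chosen (the base is not identified by the
modelling context; any base rescales one coefficient).

Adjusted R² is computed on the response scale as
`1 - [RSS/(n - edf_tot)] / [TSS/(n - 1)]` with `edf_tot` the summed
effective degrees of freedom, so it is one formula across families;
agreement with any backend's own "adjusted r-squared" is approximate by
construction. Smooth-term p-values are the backend's edf-adjusted Wald
tests, reported with the conventional marks (`***` < 0.001, `*` < 0.05,
`·` < 0.1). Prediction bands are formed on the link scale and
back-transformed, so count bands stay positive.

Residual spatial autocorrelation is tested with Moran's I: deviance
residuals averaged per unique coordinate, inverse-distance weights
row-standardized, analytic mean `-1/(n-1)` and variance under normality
(`ape::Moran.I`), two-sided.

## Blend-weight scan and trait ablation

`scan_a()` evaluates the SES trend model over an `a` grid (default step
0.025, i.e. 41 points including both endpoints) and selects the `a`
maximising adjusted R², ties broken toward smaller `a` (the parsimonious
functional-only end). One master seed drives the scan; by default a
single set of null permutations is drawn once and shared across the grid,
which removes null-sampling noise from the comparison between grid points
(per-point sub-seeded draws are available). Sub-seeds are counter-derived
from the master seed, so runs are bit-reproducible.

`ablate_traits()` removes one trait at a time from the Gower computation
only (the phylogenetic matrix is untouched), re-blends at a fixed `a`,
recomputes SES with the *same* permutations as the full model, refits the
trend model, and reports the change in adjusted R². Reductions of at
least 0.03 are flagged as substantial. Because Gower averages over
traits, removing even a perfectly redundant (duplicated) trait reweights
the remaining contributions (k-1 instead of k denominators); the change
is an order of magnitude below the 0.03 threshold but not numerically
zero.

## Composition

Bray–Curtis dissimilarities are computed on assemblages with at least
four species; conifer assemblages from the exposure-year-0 season are
excluded (their first season preceded a full exposure year). NMDS
minimises stress over 20 random starts on the untransformed
dissimilarities — no automatic data transformation, since silent
transforms make ordinations irreproducible — and the final configuration
is centred and rotated to principal axes, so axis 1 carries the greatest
variance. Convergence tolerance and start count are recorded; a
non-converged best solution is returned with a warning rather than an
error.

PERMANOVA uses sequential (type-I) sums of squares in the stated term
order — tree species, then year — with free row permutation (no strata;
the design has no reported restricted permutation scheme) and
`p = (1 + #{F* >= F}) / (1 + n_perm)`, so 999 permutations bound p below
at 0.001.

The year segmentation of the first ordination axis is a conditional
inference tree written for this package (no recursive-partitioning
backend with unbiased split selection is among the dependencies). At each
node the independence between scores and the year factor is tested with
the per-level score sums standardized by their exact permutation moments
(Strasser–Weber mean and covariance) and summarised as a quadratic form
with a chi-squared reference on levels-1 degrees of freedom; only on
rejection at `alpha = 0.05` is the binary partition maximising the
standardized two-sample statistic taken, respecting `min_leaf = 7`. Year
levels are ordered by default, so candidate splits are cutpoints and leaf
groups are contiguous year ranges; an unordered mode enumerating all
level bipartitions exists because a year factor does not force contiguity
in general.

## Temporal niches

Per species, yearly totals pooled over logs give the abundance-weighted
mean emergence year and the weighted standard deviation around it (niche
breadth). The SD is population-weighted (divide by total individuals, no
n-1): it describes the dispersion of the observed individuals over years,
not an estimator of a sampling distribution. The at-least-three-
individuals-in-some-year rule is a display flag only; summaries are
always computed.

## The synthetic generator

`simulate_community()` produces the inputs of every stage with known
truth. Expected counts follow

    lambda_{s,l,t} = exp(beta0 + beta_host * match(s,l) - delta * t)
                     * exp(-(t - mu_s)^2 / (2 sigma_s^2))
                     * exp(-gamma * d_s^2)  for t <= early_years,

with negative binomial observation noise (dispersion `theta`), where
`match` is host-tree compatibility (conifer-associated species on spruce
and fir, broadleaf on beech, generalists everywhere), the Gaussian kernel
is the temporal niche (its abundance-weighted mean and SD are therefore
analytically known and recoverable), and `d_s` is the species' distance
to an early-specialist optimum.

Defaults encode the study conditions: 10 beech, 10 fir and 10 mixed
plots plus 12 spruce logs (52 logs), 12 sampling seasons from 2013 with
2020 skipped, a 300-species pool, and per-year log-abundance decline
`delta = 0.35` (an early resource pulse). Niche breadths grow with niche
position (`sigma_s = 0.5 + 0.15 (mu_s - 1)` years), so early species are
temporally narrow. Host association (`beta_host = 2.5`, `beta0 = -2`)
was set so that species totals and tree-species overlap have the
magnitudes typical of such experiments (most species shared, a
substantial host-specific fraction). The default filter strength
`gamma = 12` makes early assemblages visibly clustered (SES around -1 in
years 0-2) before relaxing toward the plateau — the qualitative pattern
the generator is meant to emulate; `gamma = 0` switches colonization
independence on exactly.

Two generator choices deserve emphasis:

* **The early-specialist optimum is the edge of a populated region** of
  the distance space: among the most peripheral quartile of species, the
  one whose ten nearest neighbours are closest. A bare "most peripheral
  species" is frequently an isolated outlier with no guild around it, in
  which case a distance-to-point filter selects an essentially random
  community and no functional clustering exists to recover. Real early
  specialists are extreme but not unique phenotypes, and the guild-edge
  rule encodes exactly that.
* **Tree-free traits share a latent axis.** Under the `"white"` trait
  model each continuous trait loads (0.6) on a common species factor.
  Purely iid high-dimensional traits concentrate: every species is nearly
  equidistant from every other, and no trait-based filter can produce
  guild structure. Real morphology is strongly correlated (size/shape
  syndromes with pairwise r around 0.6), and the latent factor reproduces
  that while staying independent of the phylogeny — which is what makes
  functional and phylogenetic assembly separable in recovery experiments.
  Under the `"BM"` model the shared tree provides the correlation
  instead, at the price of coupling traits to phylogeny (as in real
  beetles).

What the generator does **not** emulate: wood chemistry and fungal
succession (the filter is a phenomenological penalty, not a mechanism),
dispersal between logs (no spatial kernel; logs differ only through host
species and coordinates), within-season phenology, trap failure, or
detection error. Passing recovery tests therefore show that the
estimators recover the *statistical* structures they target — not that
those structures are the true mechanisms in any field system.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed; sub-seeds are derived
deterministically (counter-based, kept below 2^31), so all pipelines,
scans and simulations are bit-reproducible. The test suite exercises the
null-model calibration with 500 assemblages at 999 shuffles; the
blend-weight recovery with 50 replicates per direction (120-species
pools, 17 logs, 8 seasons, grid step 0.125, 299 shared permutations); the
trait-ablation recovery with 50 replicates (host-tree-only filtering,
gamma = 8); trend-model recovery at n > 400 and 100 null richness
simulations; PERMANOVA calibration with 500 simulations at 99
permutations. `scripts/acceptance.R` runs the full pipeline at the
complete design (300 species, 52 logs, 12 seasons, 21-point scan, 199
shared permutations, 999 PERMANOVA permutations) in about two minutes on
one CPU.

## Known limitations

* The inference tree uses the asymptotic chi-squared reference for its
  quadratic-form statistic rather than Monte-Carlo permutation p-values;
  with the node sizes used here (dozens of observations per year level)
  the approximation is standard, but very small nodes stop early by the
  `min_leaf` rule anyway.
* Adjusted R² for non-Gaussian families is a response-scale convention;
  other conventions (deviance-based pseudo-R²) will disagree, which is
  why model selection only ever compares values computed by the same
  formula.
* The blend-weight scan inherits the flatness of its objective: when
  functional and phylogenetic distances are strongly correlated (high
  phylogenetic trait signal), neighbouring `a` values fit almost equally
  well and the selected `a` is accordingly imprecise. This is a property
  of the method, not of the implementation.
* Gower distances concentrate as the number of independent traits grows;
  distance-to-point filters lose contrast in that regime. The generator's
  latent-factor traits avoid it, and real trait tables (correlated
  morphology, few effective dimensions) sit closer to the structured case
  than to the iid one.
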