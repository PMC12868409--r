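# deadwoodAssembly

Community-assembly analysis for saproxylic (deadwood-dwelling) beetle
succession. Deadwood is a finite, intermediate-lived resource: freshly cut
logs carry an energy pulse (sugar-rich inner bark) that attracts massive,
functionally narrow colonizer communities, and the resource then decays
over a decade toward a depleted, structurally heterogeneous habitat. This
package implements the statistical pipeline used to ask which assembly
mechanisms — the *more-individuals hypothesis*, *habitat filtering*, the
*habitat-heterogeneity hypothesis* — structure beetle communities emerging
from experimental logs tracked yearly over such a decomposition period,
for three host tree species (spruce, fir, beech) with staggered exposure
origins and a skipped sampling year.

It is aimed at community ecologists who have long-format emergence records
(log x year x species counts), a mixed-type trait table, and a species
phylogeny, and want the full analysis — or who want to study the
behaviour of these methods on simulated communities with known ground
truth.

## What it computes

**Functional diversity as SES MFPD.** Pairwise species distances blend a
functional (Gower, mixed continuous/ordinal/categorical traits) and a
phylogenetic (cophenetic) matrix, each rescaled by its maximum:

    FPDist_ij(a, p) = (a * P_ij^p + (1 - a) * F_ij^p)^(1/p)

with phylogenetic weight `a` in [0, 1] and quadratic blend `p = 2` by
default. For every assemblage (one log in one year) the mean pairwise
distance (MPD) over its species is compared against a tip-shuffling null
(species labels of the distance matrix permuted over the full pool, 999
draws), giving a standardized effect size

    SES = (MPD_obs - mean(MPD_null)) / sd(MPD_null)

where negative values indicate functional clustering, i.e. habitat
filtering.

**Trend models.** Abundance, species number, species richness (species
number with `log(abundance)` as a covariate — the more-individuals test)
and SES MFPD are modelled with penalized additive models (`mgcv`):
tree-species fixed effect, one smooth of years-since-exposure per tree
species, a thin-plate spatial smooth of the log coordinates, negative
binomial or Gaussian family, REML smoothing selection, Moran's I check on
residuals.

**Model selection and trait importance.** `scan_a()` re-runs the SES
trend model over a grid of `a` values (0.025 steps by default) and keeps
the `a` with the highest adjusted R²; `ablate_traits()` removes one trait
at a time from the Gower matrix and flags traits whose removal costs at
least 0.03 adjusted R² as substantial drivers.

**Composition and phenology.** Bray–Curtis dissimilarities between
assemblages (at least four species; conifer year-0 assemblages excluded),
NMDS with principal-axis rotation, PERMANOVA (tree species, then year),
a conditional inference tree that segments the first ordination axis into
year groups, and abundance-weighted temporal niche positions/breadths per
species.

**Synthetic communities.** `simulate_community()` generates a phylogeny,
mixed-type traits (Brownian or latent-factor models), and emergence counts
with an early resource pulse, host-tree matching, Gaussian temporal
niches, and a trait-based early colonization filter — with every
generating parameter recorded, so each stage of the pipeline can be tested
against known truth.

## Worked example

```r
library(deadwoodAssembly)

cfg <- simulation_config(n_species = 80, seed = 42, n_beech_plots = 4,
                         n_fir_plots = 4, n_mixed_plots = 4,
                         n_spruce_logs = 5, n_years = 10)
res <- run_pipeline(cfg, a_grid_step = 0.1, n_rand = 199, n_perm = 499,
                    n_starts = 10, seed = 42, k_year = 6, k_space = 15)
print(res)
```

```
Deadwood succession pipeline
Survey design: 21 logs ( beech: 8, fir: 8, spruce: 5 )
Sampling years: 2013 - 2022 (no sampling in 2020 )
Species overlap summary
 tree_species n_species n_individuals
        beech        49           194
          fir        61           233
       spruce        56           136
Shared: beech-fir = 34, beech-spruce = 33, fir-spruce = 52 
Shared by all: 30 | total: 77 species, 563 individuals

Selected blend weight a = 0 (adjusted R2 = 0.158 )
Strongest trait (most negative delta R2): colour 
NMDS stress: 0.2004 
Leaf year groups: {3-4} {5-6} {7-8}
```

The selected blend weight `a = 0` says the SES trend is best explained by
purely functional distances — as expected here, since this synthetic
community is assembled by a trait-based colonization filter. The leaf
year groups are the compositionally distinct phases found by the
inference tree (early assemblages drop out of the composition analysis in
this small run because few of them reach four species). The abundance
trend model prints per-tree-species smooths with significance marks:

```r
print(res$trends$abundance)
```

```
Additive trend model: abundance ~ tree_species + s(exposure_year, by = tree_species, k = 6) + s(E, N, bs = "tp", k = 15)
Family: negative binomial (theta = 24.107) | adjusted R-squared: 0.569
                                term  edf     p signif
  s(exposure_year):tree_speciesbeech 3.70 0.000    ***
    s(exposure_year):tree_speciesfir 3.88 0.000    ***
 s(exposure_year):tree_speciesspruce 3.54 0.000    ***
                              s(E,N) 5.26 0.305
```

All artifacts (trend curves, SES table, scan curve, ablation table,
ordination scores, PERMANOVA table, split tree, niche summary, run log
with seeds and parameters) are written as CSV/JSON when `out_dir` is
given.

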