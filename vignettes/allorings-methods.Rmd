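---
title: "Root-shoot allometry from tree-ring series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root-shoot allometry from tree-ring series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allorings)
```

## The scientific problem

When a strip of canopy is cut out of a closed conifer stand, the trees left
along the new edge experience an abrupt change in light, water, nutrient
availability, and wind load. A classic hypothesis is that such trees shift
growth allocation belowground — wider roots improve both resource uptake and
anchorage. `allorings` implements a complete analysis of this question from
increment-core data: ring-width series from three compartments per tree
(stem, root collar, main root), tree dimensions measured at survey, and the
cutting year per site.

## Models

### Long-term allometry

Annual radii are reconstructed backward from the radius measured at survey
(half the diameter at the coring position) by subtracting each year's ring
width. The long-term root-shoot allometry of undisturbed (stand-interior)
trees is the log-log law

$$\ln(dr_i) = \alpha_0 + \alpha \, \ln(ds_i),$$

with $dr_i$, $ds_i$ the root and stem radii (mm) in year $i$, $\alpha_0$ the
allometric factor and $\alpha$ the allometric exponent. $\alpha = 1$ means
root and stem gain radius at the same relative rate (steady state);
$\alpha > 1$ means allocation to roots increases with tree size. Because
yearly radii of one tree are not independent, `fit_allometry()` estimates

$$\ln(dr) = \alpha_0 + \alpha_1 \ln(ds) + \alpha_2\,\mathrm{site}
  + \alpha_3 \ln(ds)\times\mathrm{site} + b_{\mathrm{tree}}$$

by REML (`lme4::lmer`) with a single random intercept per tree and no random
slope. Each site's exponent is the reference slope plus its interaction;
`site_alphas()` extracts them.

Increment cores are taken from the *top* of main roots, where eccentric
growth makes radii systematically wider than the mean cross-sectional
radius. Exponents are therefore also reported after division by an
overestimation factor (`correct_alpha()`, default 1.90 as estimated from
sectioned root disks whose upper radii averaged some 40 % above the disk
mean). The factor is a given constant here; its derivation from disk
measurements is outside the package's scope.

### Short-term allometry and PCA

The annual allometric slope

$$\alpha'_i = \frac{\ln(dr_i/dr_{i-1})}{\ln(ds_i/ds_{i-1})}$$

uses raw, non-detrended radii; it is 1 at steady state and is undefined in
years with a zero stem increment. The percentage change in allometric slope

$$\mathrm{PCA} = 100 \cdot \frac{A_a - A_p}{A_p}$$

contrasts the mean $\alpha'$ over the 10 years strictly before the cutting
year ($A_p$) with the 10 years strictly after it ($A_a$); positive PCA means
enhanced allocation to roots after the cutting. Note the deliberate
asymmetry: swapping the windows yields $100\,(A_p-A_a)/A_a$, not
$-\mathrm{PCA}$.

Design choices that matter here, all exposed as arguments:

* **Window placement.** The cutting year itself belongs to neither window
  (the most literal reading of "10 years before / after"); an inclusion
  toggle exists.
* **Invalid years.** Years with zero increments are dropped from the window
  means, not imputed; at least 5 usable years per window are required
  (`min_years`).
* **Winsorization.** $\alpha'$ is a ratio and explodes when the stem
  increment is near zero. Values with $|\alpha'| > 50$ are excluded from
  window means (`winsor_bound`, configurable). On the default synthetic
  data this touches well under 1 % of years.
* **Root input.** The tree-level mean *main-root* series is used; root
  collars are excluded from allometry because swaying and reaction wood
  affect the collar zone directly.

### The PCA response model

Per-tree PCA is explained by the stem radius prior to cutting ($R_p$, cm),
tree position (edge vs stand interior), and site:

$$\mathrm{PCA} = c_0 + c_1 R_p + c_2\,\mathrm{position} + c_3\,\mathrm{site}
 + c_4\,\mathrm{position}\times R_p + c_5\,\mathrm{position}\times\mathrm{site}.$$

`cooks_outlier_filter()` first fits the full model once and removes rows
with Cook's distance above $8/N$ ($N$ = number of rows), then the model is
refitted — a single pass, no iteration. `fit_pca_model()` then runs backward
elimination with `MASS::stepAIC`: the term whose removal most lowers AIC is
dropped, interactions always before their main effects (marginality), until
no removal lowers AIC. Only AIC *differences* matter for selection, so the
additive constant convention is irrelevant. Edge-vs-interior differences in
PCA are additionally tested per site with a two-sided Wilcoxon rank-sum
test: exact when both groups have at most 10 untied observations, normal
approximation with continuity correction (and mid-ranks) otherwise.

## Series processing

* **Averaging before indexing.** Cores of one tree and compartment are
  averaged on raw widths (`average_within_tree()`); growth direction
  (toward the cut strip vs toward the stand) is carried in the metadata but
  collapses at averaging, since directional differences in post-cutting
  increments are not systematic.
* **Missing rings** are width-0 years with a flag, never dropped, so the
  year axis stays gap-free through every stage (their detrending index is
  0; they invalidate $\alpha'$ in that year and the following one only via
  the zero increment).
* **Truncation and coverage.** Series are truncated to the site's common
  interval; trees whose stem series starts later than `cutting_year -
  window_pre` cannot support the pre-window and are excluded with a logged
  reason.
* **Detrending.** The exact detrending model matters only for the
  chronology plots, not for $\alpha'$/PCA (which use raw widths). The
  default is a cubic smoothing spline whose stiffness is tied to 67 % of
  the series length via an equivalent-degrees-of-freedom heuristic
  (`df ~ 1.2 n / (0.67 n) + 2`, i.e. 3-4 df for a 47-year series — stiff
  enough to track only the age trend); `neg_exponential` (with a
  linear-then-mean fallback chain) and `mean` are alternatives, and the
  method used is recorded in the output.
* **Quality statistics.** Mean sensitivity uses the standard
  `2|w_t - w_{t-1}|/(w_t + w_{t-1})` form. The cross-date index is composed
  as `CDI = GLK x t_BP / 100` — the common composition of sign agreement
  (Gleichlaeufigkeit) with the Baillie-Pilcher t value on 5-year
  moving-average high-pass ratios — because the original measuring-software
  definition is proprietary; CDI values are therefore comparable within
  this package, not across tools, and are floored at 0. Pointer years use a
  conventional criterion (75 % of trees deviating >= 10 % from their own
  5-year window mean) with all three knobs exposed. The cross-dating check
  is deliberately minimal: segment-wise lag scans against the master, no
  series editing.

## File formats

Ring widths are read and written in the decadal Tucson layout with integer
widths in 1/100 mm (the measurement resolution of stage-based systems).
Both 999 and -9999 are accepted as end sentinels on read; on write the
package emits -9999, because in 1/100 mm files a 999 *data* value is a
genuine 9.99 mm ring — such a value is bumped one resolution step to 998 so
that foreign readers treating 999 as a sentinel cannot truncate the series.
Tree metadata, site configuration (YAML), and long-form series tables carry
everything the Tucson format cannot.

## The synthetic-data generator

No field data ship with the package, so `simulate_dataset()` generates
datasets with exactly the statistical structure the analysis assumes — it
is the analytic inverse of the analysis, which makes it the cleanest
possible test surface:

* **Stem widths**: age trend `a exp(-b age) + c` x a site-shared AR(1) year
  effect (log scale) x lognormal noise, scaled so the final radius matches
  a survey target drawn lognormally around site-typical magnitudes
  (stem radii of 180-250 mm, i.e. dbh roughly 35-55 cm).
* **Root radii**: the allometric law applied to the stem radius path, with
  a tree-level random intercept and a slowly varying (AR(1), rho = 0.9)
  lognormal deviation. Root widths are the successive differences, floored
  at zero; flooring events and additionally injected missing rings
  (default rate 1.5 %) are flagged. Monotonicity is enforced with a
  running maximum, so radii never decrease.
* **Release**: edge trees multiply stem widths by `1 + 0.15 f` and root and
  collar widths by `1 + 0.45 f` during a boxcar window starting 2 years
  after the cutting and lasting 5 years (so the effect is gone 7 years
  after the intervention). The response factor
  `f = 1 + 0.15 (median R_p - R_p)` (clamped to [0.25, 2]) makes smaller
  trees respond more strongly, which is what produces a negative
  position x size interaction in the response model. Expected edge PCA
  under the defaults is on the order of +10 to +25 % depending on size,
  interior exactly 0.
* **Default intercepts.** The per-site intercepts (-17.8, -14.8, -8.9) are
  chosen so that, given each site's exponent (4.06, 3.54, 2.60), root
  diameters land in the realistic 16-21 cm range for site-typical stem
  radii. (A single shared intercept cannot do this across exponents that
  different.)
* **Root-noise scale.** The law's deviation has marginal sd 0.02 by default
  with high persistence: $\alpha'$ divides *differences* of log radii by
  stem log-increments of order 0.005-0.01, so even small independent noise
  would dominate the annual slope. Persistence keeps year-to-year
  deviations small (the realistic regime) while leaving the radius-scale
  noise visible to the long-term fit. Parameter-recovery checks that
  stress the long-term fit raise this to 0.1.

The generator's per-tree truth (exponents, intercepts, random effects,
release multipliers and window) supports `expected_pca()`, a noise-free
closed-form evaluation of the PCA a tree should show; on noise-free
simulations it matches the full pipeline to numerical precision.

What the generator does *not* emulate: climate-driven growth variation
beyond a single AR(1) year effect, competition and spatial structure,
double rings, dating errors, reaction wood, or bark. Passing tests
therefore demonstrate correctness of the estimators under the model's own
assumptions, not robustness to every pathology of real cores. One known
limitation carried deliberately: measured radii at survey are treated as
bark-free; if they include bark, radius levels (and hence exponent levels)
shift, which is why a configurable bark allowance would have to be applied
upstream of `reconstruct_radii()`.

## Problem sizes and determinism

The default simulated study comprises 3 sites and 71 trees (37 interior, 34
edge) over 1970-2016 (47 years), matching the scale of the motivating field
campaigns; recovery checks use 20 replicate seeds at 20 interior trees per
site. Datasets are deterministic functions of their configuration
(including the seed), and pipeline reports contain no timestamps, so
identical runs produce byte-identical outputs.

## A worked example

```{r, eval = FALSE}
d <- simulate_dataset(sim_config(seed = 1))
report <- run_pipeline(d, out_dir = "allorings-out")
report$allometry$alpha_table
report$response$fit
```

## Known limitations

* The mixed model assumes independent residuals within trees; yearly radii
  are cumulative, so residual autocorrelation is understated and standard
  errors are optimistic. The exponent estimates themselves are unbiased
  under the generator, which is what the recovery suite checks.
* The variance explained by individual terms of the response model depends
  on the partitioning convention; the package reports the model $R^2$ and
  coefficient table only and offers no variance decomposition.
* CDI and pointer-year values are convention-dependent diagnostics, not
  quantities comparable across software.
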