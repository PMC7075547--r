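---
title: "Methods: a child-based capability index from birth-history surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a child-based capability index from birth-history surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(childcap)
```

## The problem and the model

National human-development summaries hide where, within a country, children
fare badly. childcap implements a child-based analogue of the Human
Development Index built entirely from birth-recode household-survey
microdata (DHS-style files with one row per child ever born to an
interviewed woman). Three components are computed for each analysis cell —
a country or a first-level administrative unit:

* **U5S** — the survey-weighted share of children recorded alive, where a
  child counts as an under-five death if they died before 60 completed
  months of age;
* **Edu** — the weighted mean of maternal schooling in single years;
* **Wealth** — the weighted mean household wealth quintile (1 poorest to 5
  wealthiest), quintiles being cut from an asset-based household score.

Each component is rescaled to $[0,1]$ by min–max (goalpost) normalization,

$$\tilde{x}_{c,u} = \frac{x_{c,u} - x_{\min}}{x_{\max} - x_{\min}},$$

and combined as a geometric mean,

$$\mathrm{Index}_{c,u} = \left(\widetilde{U5S}_{c,u}\cdot
\widetilde{Edu}_{c,u}\cdot \widetilde{Wealth}_{c,u}\right)^{1/3},$$

so that a collapse in any one dimension cannot be linearly compensated by
the others; a zero component forces a zero index (no epsilon flooring — the
event is real and is surfaced, not hidden). Countries are ranked by the
national index; within-country dispersion is summarized by the unweighted
mean and sample SD of unit-level indices.

## Sample restrictions and coding conventions

The default sample keeps children born strictly fewer than 120 months
before the interview ("born in the past 10 years"), with 5-year and
full-birth-history variants; windows use century-month-code (CMC)
arithmetic only, so date handling is exact. The analysis is complete-case:
children lacking a survival status, maternal schooling, or a resolvable
household wealth measurement are excluded with per-reason counts, never
silently. Survival is the binary alive-at-interview variable: a death at or
after the fifth birthday is *not* an under-five death, and living children
currently younger than five count as survivors. This is a deliberate
synthetic-cohort simplification — no life-table correction is applied — and
it understates period mortality relative to a true $\,_5q_0$; it is,
however, exactly the variable the index is defined on, and the sensitivity
coders (infant survival, 5-year window, mothers aged 15–30, arithmetic
mean, provided quintiles) share its conventions. Boundary rules are
half-open throughout (death "under five" means death age $< 60$ completed
months) to avoid double counting.

## The wealth score

Households are scored by the first principal component of their
standardized binary asset/dwelling indicators, computed either pooled
across countries (for national comparisons) or within each country (for
subnational comparisons); the component's sign is oriented so more assets
means a higher score. First-PC scoring on standardized indicators is the
standard asset-index construction; it is adopted here as an explicit
assumption. Quintile cut points are *weighted quantiles over the
child-level distribution* — each child contributes its own sampling weight
— because the index is child-based and every child inherits its household's
quintile. This diverges from the DHS convention of cutting quintiles over
de-jure household members; keeping one weighting system end-to-end seemed
the lesser evil, and the divergence matters only when household size
correlates strongly with wealth. A household exactly on a cut point goes to
the lower quintile; an all-equal-score degenerate stratum collapses to
quintile 3 with a warning.

## Normalization modes and a deliberate discrepancy

Two modes are implemented. `observed_extrema` is the literal min–max
rescaling over the cells in scope; it is the right choice for subnational
visualization, where the point is to span each country's own development
spectrum. But across countries it forces the worst-off country to a
normalized component of 0 and hence (under the geometric mean) a national
index of exactly 0 — which contradicts the published ranking this package's
reference tables reproduce, where the minimum national index is 0.140. The
effective lower reference values behind that table are not recoverable from
the published text. The package therefore defaults national tables to
`fixed_goalposts` with natural bounds — survival $[0,1]$, schooling
$[0,15]$ years (15 years as the upper reference value), quintile $[1,5]$ —
and retains `observed_extrema` as the literal mode. The discrepancy is
documented rather than resolved; both modes are tested.

Other numerical conventions: rank ties break alphabetically by country name
(determinism across runs); the within-country SD uses the $n-1$ denominator
(configurable, since the published source does not state it); comparisons
against printed table cells round half-away-from-zero at the printed
precision; cells smaller than 25 children are flagged `low_n`, not dropped
(the floor is configurable because synthetic tests legitimately use small
cells while real first-level units are large).

## What the synthetic generator emulates

Because real birth-recode microdata are access-restricted, the package
ships a generator whose defaults *are* the study conditions used in every
test: 10 countries × 6 first-level units, 40 clusters of 20 households per
unit, one interviewed mother (aged 15–49, ages drawn with a mode near 28)
per household, and about 2,000 children per unit inside the ten-year window
(mean 3 births per decade for a mother observed over the full window —
high-fertility-setting levels). Unit-level under-five death probabilities
are uniform on $[0.006, 0.156]$ and unit mean schooling uniform on
$[0.7, 12.1]$ years — the national ranges of the reference tables. Latent
household wealth is normal around a unit mean; 30 binary indicators load on
it with logit slopes uniform on $[0.4, 1.0]$ (DHS wealth indices typically
use 30–40 indicators); schooling is a discretized truncated normal
(integers ≥ 0, SD 2.5 years) whose center shifts one year per SD of
household wealth; a child's death probability gets a small negative logit
shift (−0.05/year) in maternal schooling around the unit mean; cluster
weights are lognormal with CV 0.25, stored as DHS-style integers
(×1,000,000). A two-round mode revisits the same units with mortality
scaled by a trend factor (default 0.8).

The generator stores exact estimands alongside the data: per cell, the
weighted mean of child-level survival probabilities, of exact expected
schooling (the discretized-truncated-normal mean has a closed form as a sum
of normal tail probabilities), and of latent wealth; per household, the
latent wealth draw. Deaths are placed at an age drawn from a mixture (55%
infant) truncated at the child's current age, so the alive-at-interview
binary is exactly Bernoulli in the stored probability — the simplification
that keeps truth exact. What the generator does **not** emulate: birth
spacing, twins, migration, nonresponse, recall error, and any causal
pathway from education to mortality (the logit shift is a descriptive
gradient). Passing recovery tests therefore show the *pipeline arithmetic*
is right under known truth, not that the index is unbiased on real data.

## Test design and the one knowingly failing check

The recovery test compares estimated cell components against the stored
estimands within 3 Monte-Carlo SEs, for at least 95% of the 60 cells.
Demanding literally every cell stay inside a 99.7% band would fail by
design roughly a third of the time under its own null, so the ≥95%-of-cells
form is used for all components. SEs are computed on the weighted cell
mean clustered at the independent sampling unit — the child for survival,
the mother for schooling, the household for the quintile — since siblings
share their mother's schooling and household's quintile.

Survival and education pass comfortably. The wealth component does not,
and the reason is instructive: the quintile-scale truth is built by running
the same weighted-quintile assignment on the *true latent wealth*, and the
first-PC asset score classifies households into latent-wealth quintiles
with roughly 88% fidelity. The resulting cell-mean quintiles are attenuated
toward the center by about 12% of each cell's deviation — a systematic
measurement property of asset-based indices, not Monte-Carlo noise — so the
most extreme-wealth cells sit just outside a 3-SE band at typical seeds
(55/60 within the band at the default seed), and the index-within-0.02
check lands near its 95% line (56/60 at the default seed). The failing
check is left failing: weakening the band would only hide a real and
well-understood property of the wealth proxy. The acceptance script reports
the same four recovery rates at whatever seed it is given.

Problem sizes were chosen so the whole suite runs in well under a minute of
simulation: the recovery design is the default generator (~120,000
children); structural tests use a 2-country × 3-unit survey of a few
hundred children; oracle-equivalence checks run 100 random instances per
statistic against loop-based brute-force implementations at $10^{-10}$.

## Interpolated surfaces and maps

The development-spectrum figures interpolate cell survival over the
(normalized wealth, normalized education) plane with an exact thin-plate
radial-basis interpolant ($U(r) = r^2\log r$ plus affine terms, dense
solve), clipped to the observed survival range and cut into 10 equal-width
contour levels; collinear cell layouts fall back to a least-squares affine
surface with a warning. Exactness at source points is part of the test
suite ($10^{-8}$). Choropleth export classifies units into equal-count
deciles (ties by unit name), joins them to GeoJSON features on a
case-insensitive punctuation-stripped name key, reports every unmatched
name on both sides, and fails below a 50% join rate. Geometries are passed
through untouched; no projection management is attempted.

## Known limitations

* The alive-at-interview survival binary understates cohort mortality for
  recent births; trend comparisons between rounds inherit this.
* Quintile attenuation (above) biases cell-mean wealth toward 3; on real
  data the effect is larger than in the synthetic design.
* No design-based variance estimation for cell means is provided; the
  cluster-level SEs used in tests are Monte-Carlo tools, not survey SEs.
* The national reference values of the published ranking cannot be
  recomputed from raw data here because the microdata are access-restricted;
  the package reproduces the printed summary cells from its fixtures and
  validates the machinery on synthetic data instead.

```{r example}
res <- run_pipeline(run_config(
  simulate = generator_config(n_countries = 3, units_per_country = 4,
                              clusters_per_unit = 10,
                              households_per_cluster = 10),
  seed = 7))
res$index_national[, c("country", "index", "rank", "within_mean", "within_sd")]
```
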