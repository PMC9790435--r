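---
title: "Defining, projecting and stress-testing landscape fire regimes"
author: "pyromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining, projecting and stress-testing landscape fire regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyromes)
```

## The model

`pyromes` treats a fire regime as a recurring pattern of landscape-scale
burning, operationalised as a twelve-value descriptor per grid cell
computed from a multi-year archive of monthly burned area, fire counts and
mean fire sizes: the monthly and yearly means and coefficients of
variation (CV) of burned area, fire number and fire size. Monthly
statistics are taken over the 12-value monthly climatology, so the monthly
CV measures the shape of the average seasonal cycle; yearly statistics are
taken over per-year annual aggregates, so the yearly CV measures
interannual variability. Average fire-season length (mean number of months
per year with any burning) is computed alongside but is not part of the
clustering vector.

Three modelling commitments follow from the data this emulates:

* **Landscape scale.** Satellite burned-area products at ~500 m resolution
  cannot see fires below about 21 ha (0.21 km²). The detection floor is
  applied at event level in the synthetic generator, and cells with no
  detected burning over the whole record form the *no landscape-scale
  fire* (NLSF) class — a regime in its own right, excluded from clustering
  and carried through every downstream summary as label 0.
* **Regimes are relative.** Characteristics are min–max normalised to
  [0, 1] over the burned cells of the reference domain before clustering,
  and projection targets are transformed with the *reference* scaling
  parameters (values outside the reference range deliberately map outside
  [0, 1]). We default to reference-domain scaling rather than
  whole-domain scaling so that the regime definition is a property of the
  focal region alone; both are possible by passing explicit parameters to
  `normalise_characteristics()`.
* **Complete linkage.** Regimes are cut from an agglomerative hierarchy
  built with Euclidean distance and complete linkage — merges are ranked by
  the *maximum* pairwise dissimilarity between clusters, so a regime is a
  set of cells that are all mutually similar, not a chain. The number of
  clusters K is a configuration choice, not an automatic selection;
  `cut_height_diagnostics()` reports, for each candidate K, the height of
  the merge a K-cut refuses relative to the full tree height, flagging K
  values whose cut sits above half the tree (a strong natural break). Note
  that by this definition K = 2 always sits at ratio 1 on non-degenerate
  data; the diagnostic is informative for K ≥ 3, and a tree of identical
  points reports ratio 0 everywhere. Cluster labels are renumbered to
  ascend with cluster-mean total burned area, so label K is always the
  highest-fire regime and labels are invariant to input row order. Ward
  linkage is available behind `method = "ward"` for robustness comparison.

## Tropical projection with MESS

Each fitted regime is projected onto a larger domain with the multivariate
environmental similarity surface: per variable, a piecewise score that is
positive inside the reference range (peaking at 100 when half the
reference lies below the probe), and negative in proportion to the
distance beyond the range; the cell's similarity to a regime is the
minimum over the twelve variables. Classification applies three rules, in
order: NLSF cells keep label 0; burned cells at or below similarity 0 for
*every* regime are *dissimilar* (label −1) — fire conditions not
represented in the reference region; all other burned cells take the
regime of **maximum** similarity. The assignment rule for overlapping
surfaces is a package choice (the natural tie-break, but not the only
one); it is exposed prominently here because coverage statistics depend on
it. Cells where exactly one regime exceeds similarity 24 form the mutually
exclusive subset — the threshold is a configuration default, not a derived
quantity.

Two numerical points matter in practice:

* **The score is stepwise inside the range.** As a function of the probe,
  the MESS score is exactly linear below the reference minimum and above
  the maximum, but inside the range it is a step function of the
  below-fraction, jumping by up to 200/n as the probe crosses a reference
  value. The tests assert precisely this (linear tails, bounded steps)
  rather than global continuity, which the formula does not possess.
* **Degenerate variables need a tolerance.** A characteristic can be
  *deterministically* constant within a regime — for example, the
  seasonality CV of a cell that burns in exactly one month is √12
  regardless of how much burns. Such reference "ranges" are floating-point
  dust, and the raw formula would turn them into knife edges that reject
  every target cell. `mess_variable()` therefore treats a reference range
  below 10⁻⁹ (relative to scale) as degenerate: probes equal to the
  constant (within 10⁻⁸) score 100, others a large negative sentinel.

Out-of-range classification is also subject to an irreducible sampling
effect: for a target cell drawn from the same distribution as n reference
cells, the chance of falling outside the reference range on one variable
is 2/(n+1) regardless of the distribution. With twelve partially
correlated variables this compounds to a few percent of same-regime cells
classified dissimilar at n ≈ 1000 reference cells per regime, and
considerably more below n ≈ 100. Similarity-coverage figures must be read
with this in mind; the test scenarios size their reference regions so the
effect stays within the stated tolerances.

## Environmental overlap

Regime environments are compared between regions with Schoener's
D = 1 − ½ Σ |w_a − w_b| over occupancy grids on the first two axes of a
PCA fitted to the pooled domain (fire: 12 variables; vegetation: 6;
climate: 4; all standardised, constant variables dropped with a warning).
The pooled fit keeps regional score clouds directly comparable, and the
occupancy bounds always span the pooled cloud so every comparison shares
one discretisation. "Binary" overlap weights occupied bins equally before
normalisation (the occupancy pattern defines the niche); classical
density-based D is available as a mode. The default resolution is R = 100
bins per axis, appropriate for the 10⁴–10⁶ pixels of real gridded
archives; with a few hundred points per cloud, binary occupancy is
undersampled at that resolution and D is biased low, so the shared-niche
tests use R = 15 with about 1000 cells per side (bins comparable to the
sample's spatial granularity). No significance testing of overlap is
performed.

## Trends and rainfall decoupling

Regime-wide trends are ordinary least squares of annual burned area on the
year index per regime × region, reporting the slope, its two-sided t test,
and the relative change over the span, defined as
100 · slope · (n−1) / (fitted value at the first year). The fitted-first-year
denominator (rather than the observed first year or the series mean) makes
the statistic noise-robust and exactly −32 % for a noiseless series
falling from 100 by 2 per year over 17 years.

Pixel-wise *decoupled* trends regress annual burned area on the year index
plus the precipitation sums over the 6 and 24 months strictly preceding
the fire-year anchor month — drought and fuel build-up terms respectively.
The anchor defaults to the cell's climatological peak burning month, so
the antecedent windows precede the burning season; because the features
need 24 months of history, the decoupled analysis starts two years into
the record. The year coefficient is the trend precipitation cannot
explain; its t-value is the map statistic and its significance at
α = 0.05 (0.01 also reported) flags an anthropogenic trend. Residual
trends may still contain non-rainfall climate signals (e.g. wind); the
package reports "decoupled from precipitation" and nothing stronger. No
multiple-testing correction is applied across pixels — rates, not
individual pixels, are the interpretable output. A constant precipitation
feature is dropped with a warning, reducing the model to plain OLS (the
nested-model identity is tested), and regression outputs are verified
against a normal-equations oracle.

## Degradation metrics

Vegetation classes come from three per-cell NDVI statistics — the mean and
the interannual CV of yearly means, plus the seasonal CV of the monthly
climatology — with the mean normalised by the domain-wide maximum mean
NDVI, so the thresholds act on [0, 1] values: forest above 0.80 with
annual CV below 0.08; grassy in [0.06, 0.80) with monthly CV above 0.08;
everything else (including barren surfaces below the 0.06 floor) `other`.
The normalisation choice (domain-maximum rather than min–max) is a package
decision and is switchable by transforming the inputs. A 5-observation
centred rolling median (`smooth_ndvi()`) is provided for noisy
reflectance-level series.

Tree-loss fractions are Σ loss / Σ baseline cover over a cell set —
cover-weighted, so strata recombine exactly — and anomaly ratios divide a
stratum's fraction by the all-domain value: the all-domain ratio is 1 by
construction, and ratios above 1 flag anomalously high loss. Population
ratios are computed the same way from mean densities. The summary table
keeps one row per regime × region × vegetation-class combination including
`all` margins, reporting empty strata as explicit NA rows.

## The synthetic tropics

The generator exists to give every stage a ground truth; its defaults are
the study conditions of the test suite, chosen once:

* **Grid**: a rectangular lattice (default cell area 21 km², about a
  2.5 arc-minute tropical cell) split into contiguous column blocks for
  the focal, continental and other regions — contiguous so regional
  summaries carry spatial structure rather than an i.i.d. layout.
* **Archetypes**: five regimes spanning the low-variable → high-stable
  contrast. Annual totals rise from 2.5 to 60 km² per cell (about 2.5-fold
  per step), seasons lengthen from 1 to 11 months, interannual CV falls
  from 0.30 to 0.10, fire size rises from 0.3 to 1.3 km², and vegetation
  weights shift from forest-associated to grassy. The three high-fire
  regimes carry planted anthropogenic declines of 2.2–2.8 % of baseline
  per year; the two low-fire regimes carry none. Totals are set so that
  every climatology month clears the 0.21 km² detection floor in normal
  years — low-fire regimes that straddle the floor generate bimodal
  characteristic estimates that no clustering can segment cleanly, which
  is a statement about detection-limit artefacts rather than about regime
  structure, so the defaults avoid the floor and the floor's effect is
  tested explicitly in dedicated scenarios.
* **Interannual structure**: burned area per cell-year is the archetype
  total times a *shared* regime-level year factor (regionally coherent
  fire years, as common climate forcing produces in real archives) times a
  small cell-level factor, with the variance split 97 % shared / 3 %
  cell-level; both factors are bounded mean-1 multipliers (scaled Beta on
  [0, 2]) rather than lognormal, keeping realized CV estimates
  light-tailed. Linear coupling to the centred antecedent 6- and 24-month
  precipitation sums and a linear trend complete the annual expectation,
  which is then spread over months by the climatology shape — so the
  decoupled-trend regression is correctly specified on synthetic data by
  construction (a deliberate choice: misspecification robustness is a
  question about the method, not about its implementation, and is
  exercised separately via the confounded-precipitation scenario).
* **Events**: monthly burned area is decomposed into equal-size fire
  events within each cell-month (count = burned area / drawn size,
  bounded so each event clears the floor), making burned area = count ×
  mean size an exact identity and letting characteristics be recomputed
  from event records.
* **Environment**: forest cells get high-stable NDVI (normalised mean
  > 0.80, annual CV < 0.08 by construction), grassy cells a seasonal
  cycle with monthly CV > 0.08, `other` cells sparse NDVI; climate
  summaries vary along the regime gradient; population is lognormal with
  class-dependent scale; precipitation is a wet-season sinusoid with
  interannual factors and 24 months of lead history.
* **Tree-loss anomalies**: planted ratios are ratios *to the all-domain
  baseline*. Cells in a planted stratum lose trees at ratio × base rate,
  and all remaining cells form a background stratum whose rate is solved
  so the cover-weighted domain mean equals the base rate exactly — this is
  what makes the planted ratios recoverable as subset/baseline ratios. An
  inconsistent plant (background rate non-positive) is rejected.
* **Determinism**: all draws flow from one seed through an isolated RNG
  scope (the caller's random state is restored), and regime abundances are
  allocated by exact proportional counts rather than per-cell sampling, so
  planted composition is design, not noise. Identical configuration and
  seed regenerate every array bit for bit.

What the generator does *not* emulate: satellite artefacts (cloud gaps,
orbital drift), sub-cell geolocation, fire spread between cells, small-fire
fields below the detection floor, and any real geography. Passing recovery
tests therefore demonstrate that the pipeline's inference is correct when
its assumptions hold — not that those assumptions hold for any particular
satellite product.

## Problem sizes and tolerances

The test suite runs five kinds of recovery at sizes chosen to keep
sampling error inside the asserted tolerances: clustering recovery on 300
cells (ARI ≥ 0.9 against truth, and merge heights checked exactly against
a brute-force O(n³) oracle on 30 points); MESS vectorisation checked
exactly against direct piecewise evaluation on thousands of random pairs;
type-I error of the decoupled trend on 500 independent pixels × 15 years
(rate 0.05 ± 0.02); recovery of a planted −1 km²/yr decline (±20 %,
t < −2 in ≥ 90 % of pixels); anomaly ratios {1, 2, 4} on ≥ 1000 cells per
stratum (±10 %); and an end-to-end scenario on a 12,000-cell domain where
an archetype absent from the focal region contributes 10 % of burned area
(similarity coverage 0.90 ± 0.03, exclusive-mask purity ≥ 0.9). The
focal region of the end-to-end scenario holds ~1000 reference cells per
regime, sized so the 2/(n+1) out-of-range effect described above stays
within the coverage tolerance.

## Known limitations

* Real fire-regime boundaries are gradients; hard cluster labels and the
  maximum-similarity assignment rule impose discreteness the data may not
  have.
* Min–max normalisation compresses low-fire regimes when the burned-area
  range is dominated by high-fire cells; regime separation at the low end
  then rests on seasonality and size characteristics.
* Binary Schoener's D depends on occupancy sampling; values computed at
  different resolutions or sample sizes are not comparable.
* The decoupled trend removes only what two antecedent precipitation sums
  can express; nonlinear or finer-scale rainfall effects remain in the
  "anthropogenic" residual.
* Tree-loss anomalies do not distinguish old-growth, secondary and
  plantation cover, and population density is a coarse proxy for land-use
  pressure.
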