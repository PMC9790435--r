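# pyromes

Fire-regime classification from gridded burned-area records, with tropical
projection, niche overlap, trend decomposition and degradation metrics.

## The problem

Landscape fire is a structural part of tropical grassy biomes, yet regional
fire activity is often judged against intuition rather than against the rest
of the tropics. `pyromes` implements a comparative framework that makes the
judgement quantitative. Starting from a multi-year archive of monthly burned
area, fire counts and fire sizes on a regular grid, it:

1. **Characterises** every cell by twelve fire characteristics — monthly and
   yearly means and coefficients of variation (CV) of burned area, fire
   number and fire size — plus the average fire-season length. Monthly CVs
   measure seasonality of the climatological cycle; yearly CVs measure
   interannual variability. Cells with no burned area at landscape scale
   (no fire event of at least 21 ha = 0.21 km²) form the *no
   landscape-scale fire* (NLSF) class and are held out.
2. **Defines fire regimes** by agglomerative complete-linkage clustering of
   the min–max-normalised characteristic vectors (Euclidean distance), cut
   at K clusters; labels ascend with cluster-mean burned area, so label K is
   always the highest-fire regime.
3. **Projects** the regimes onto a larger domain with the multivariate
   environmental similarity surface (MESS). For one variable with reference
   values `r` and probe `p`, with `f` the percentage of reference values
   strictly below `p`:

   ```
   f = 0        : 100 (p - min r) / (max r - min r)
   0 < f <= 50  : 2 f
   50 < f < 100 : 2 (100 - f)
   f = 100      : 100 (max r - p) / (max r - min r)
   ```

   and the cell's similarity is the minimum over the twelve variables.
   Cells positive for at least one regime are classified by maximum
   similarity; cells negative for all regimes are *dissimilar* burned area;
   cells where exactly one regime exceeds 24 form the mutually exclusive
   subset used for distinct-regime comparisons.
4. **Quantifies environmental overlap** between regions per regime with a
   binary Schoener's D, `D = 1 − ½ Σ |w_a − w_b|`, over occupancy grids in
   PCA-reduced fire, vegetation and climate spaces.
5. **Estimates trends**: ordinary least squares on annual burned area per
   regime × region (slope, t, p, relative change over the span), and
   pixel-wise trends *decoupled from rainfall* by multiple regression of
   annual burned area on the year index plus the antecedent 6-month
   (drought) and 24-month (fuel build-up) precipitation sums; the year
   coefficient's t-value is the anthropogenic-trend map statistic.
6. **Summarises degradation**: vegetation classes from normalised NDVI
   statistics (forest: mean > 0.80 and annual CV < 0.08; grassy: mean in
   [0.06, 0.80) and monthly CV > 0.08), tree-loss fractions
   (Σ loss / Σ baseline cover), and anomaly ratios against the all-domain
   baseline, tabulated by regime × region × vegetation class.

A synthetic-tropics generator (`simulate_tropics()`) plants known regimes,
trends and tree-loss anomalies with a recorded seed, so every stage can be
tested by parameter recovery.

## Worked example

```r
library(pyromes)

grid    <- grid_spec(60, 80, region_fractions = c(focal = 0.45, continental = 0.25, other = 0.30))
tropics <- simulate_tropics(grid, years = 14, seed = 42)
chars   <- fire_characteristics(tropics$series)

fit <- fire_regimes(chars[grid$region == "focal", ], k = 5)
print(fit)
#> Fire regimes (complete-linkage clustering, k = 5)
#>   cells: 2160 (340 NLSF held out)
#>   cells per label (0 = NLSF):
#>   0   1   2   3   4   5
#> 340 363 360 370 359 368

proj <- predict(fit, chars)       # MESS projection over the whole domain
print(proj)
#> Regime projection over 4800 cells
#>   labels (-1 dissimilar, 0 NLSF):
#>  -1   0   1   2   3   4   5
#> 126 720 803 791 777 788 795
#>   exclusive (single regime > 24 ): 795 cells

total_ba <- rowSums(tropics$series$burned_area, dims = 1)
cov <- similarity_coverage(proj$labels, total_ba)
sprintf("similar to %.1f%% of burned area", 100 * cov$area_fraction)
#> "similar to 96.6% of burned area"

regime_trend_table(tropics$series, proj$labels, grid$region) |>
  subset(region == "focal")
#>   regime region   slope t_value  p_value relative_change_pct n_years significant
#> 1      1  focal    4.87   0.277 0.786207                7.84      14       FALSE
#> 2      2  focal   20.22   0.652 0.526578               12.74      14       FALSE
#> 3      3  focal -166.48  -1.888 0.083430              -41.36      14       FALSE
#> 4      4  focal -335.99  -4.804 0.000430              -39.61      14        TRUE
#> 5      5  focal -521.28  -4.644 0.000566              -31.80      14        TRUE
```

The clustering recovers the five planted regimes exactly (adjusted Rand
index 1.0 against the generator truth); the significant declines in the
high-fire regimes are the generator's planted anthropogenic trends
(−2.5 %/yr and −2.8 %/yr of baseline, compounding to the −30 to −40 %
relative changes shown). The 126 dissimilar cells are characteristic-space
edge cases outside every regime's reference range. `run_pipeline()` binds
all stages — including decoupled pixel trends and the degradation summary —
and writes CSV artifacts plus a JSON run log.

## Vignette

`vignettes/fire-regimes.Rmd` documents the model and its assumptions, every
tunable threshold with its default, what the synthetic generator does and
does not emulate, and the package's numerical choices and limitations.
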