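---
title: "Methods: spatiotemporal association analysis of environmental stressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal association analysis of environmental stressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressorscape)
```

## The problem

Health-impact studies of air pollution have to decide which
environmental covariates can enter a model together. Daily
meteorological variables (temperature, precipitation, vapor pressure,
UV irradiance) and pollutant concentrations (O3, NO2, PM2.5, PM10)
over a region are strongly interdependent, in ways that change with
season and with the urban/rural gradient. stressorscape quantifies
those interdependencies three ways:

1. **Pooled and stratified Pearson correlation matrices** with a
   coarse strength taxonomy, including per-calendar-month matrices and
   an accounting of which variable pairs flip correlation sign between
   months.
2. **Lagged auto- and cross-correlation** of the region-mean daily
   series, at day and calendar-month resolution.
3. **Local Moran's I hot/cold-spot detection** (LISA) on per-area
   period means, with conditional-permutation inference, and summary
   tables of the stressor distributions inside the detected strata.

Because regional reanalysis panels are large and not redistributable,
the package ships a seeded synthetic generator that reproduces the
*structure* of such a panel — the generator is first-class, tested
code, and every statistical claim the test suite makes is made against
panels it produces.

## Derived variables

**Vapor pressure.** `magnus_vapor_pressure()` implements the
Magnus/Bolton form
\( e = 6.112 \exp\!\left(\frac{17.67\,T_d}{T_d + 243.5}\right) \)
(hPa, dewpoint in °C). Some sources print the denominator as
\(T_d - 243.5\); that form returns about 1.26 hPa at a 20 °C dewpoint,
which is not a physical vapor pressure (tabulated saturation pressure
at 20 °C is 23.388 hPa, and the `+243.5` form gives 23.369 hPa, within
the formula's documented ~0.3% accuracy). We therefore use `+243.5` as
the default and expose the printed variant behind a `strict_literal`
flag for auditing.

**UV.** Reanalysis UV comes as accumulated energy (J/m²);
`uv_to_watts()` divides by the integration period in seconds. The
accumulation period is dataset-specific, so it is an explicit argument
rather than an assumption.

**Population density.** Density is inhabitants/km²
(`population / area_km2`), categorized into four bins. The printed
category labels (0–150, 151–300, 301–1000, >1000) describe integer
boundaries; we define the bins as half-open intervals
`(0,150], (150,300], (300,1000], (1000,∞)` so that fractional
densities are always assigned: a density of exactly 150 is category 1
and 150.5 is category 2.

## Temporal analysis

Two pooling modes are offered because both framings are legitimate:
the "all data" correlation matrix pools *area-days* (every area, every
day is a row), while monthly matrices and all lagged analyses use the
*region-mean daily series* (`bw_mean_series()`), in which the spatial
separation is deliberately neglected. The pooled mode emphasizes
spatial contrasts; the region-mean mode isolates shared temporal
dynamics. `monthly_matrices()` exposes both via `mode`.

Correlations use pairwise-complete deletion; no imputation is
performed. An entry whose overlap is shorter than two rows or whose
variable is constant is *undefined* and reported as `NA`, never as 0.
In `sign_change_count()` a zero coefficient never participates in a
sign change (conservative counting).

**Cross-correlation.** For series \(x(t)\), \(y(t)\) and lag \(k\),
the coefficient is the Pearson correlation of the pairs
\((x(t), y(t+k))\) over the overlap window where both are observed,
using that window's own means and sums of squares. Restricting every
moment to the overlap window keeps every coefficient in \([-1, 1]\) at
every lag — implementations that reuse full-series means can exceed 1
at large lags. Positive lags pair \(x(t)\) with later values of
\(y\), so a peak at \(k > 0\) reads "x leads y by k steps"; the
convention is recorded on every result object. The reversal identity
\(\mathrm{ccf}_{x,y}(k) = \mathrm{ccf}_{y,x}(-k)\) holds exactly.

**Strength taxonomy.** `classify_strength()` maps \(|r|\) to
almost perfect (>0.9), very large (0.7–0.9], large (0.5–0.7],
moderate (0.3–0.5], small (0.1–0.3], trivial (≤0.1). The printed
scheme this follows leaves the exact point 0.1 unassigned; we close
the gap downward (0.1 is "trivial") so the function is total.

## Spatial analysis

**Weights.** `build_weights()` derives queen (shared vertex) or rook
(shared edge) contiguity from the polygon rings by snapped-vertex
matching — exact for lattice cells and for polygon layers whose shared
boundaries carry shared vertices (the usual situation for
administrative layers; a non-conforming shapefile would need
preprocessing). The default is queen contiguity with row-standardized
weights, the conventional LISA reading in which the spatial lag is the
neighbor average; binary weights are retained for audits. Areas
without neighbors are *islands*: they are excluded from the global
mean, the variance term and all statistics, and surface as an explicit
"isolated" stratum, mirroring the practice of dropping isolated
postal-code areas from cluster maps.

**Local Moran's I.** For area \(i\),
\[
I_i = \frac{x_i-\bar X}{S_i^2}\sum_{j\neq i} w_{ij}\,(x_j-\bar X),
\qquad
S_i^2 = \frac{\sum_{j\neq i}(x_j-\bar X)^2}{n-1},
\]
with \(\bar X\) the global mean over included areas. The leave-one-out
\(S_i^2\) (the default, `variance = "leave_one_out"`) varies slightly
with \(i\); the common description of it as "a constant for all
locations" is exactly true only for the global second moment
\(m_2 = \sum_j (x_j - \bar X)^2 / n\), offered as
`variance = "global"`. Under the global variant and row-standardized
weights the additivity identity mean\((I_i)\) = global Moran's I holds
exactly, and the test suite uses it as a cross-check oracle. The two
variants give *identical* permutation p-values, because either
denominator is fixed per area under permutation of the remaining
values. The statistic is invariant under location shifts and positive
rescaling of the values; all-equal values are a degenerate-input
error.

The LISA input value for a variable is its per-area mean over the full
study window (configurable), matching the construction of a single
cluster map for a multi-year study period.

**Inference.** `permutation_pvalues()` uses conditional permutation:
\(x_i\) is held fixed and the remaining \(n-1\) values are randomly
assigned to its neighbor positions, `n_perm` times (a shared set of
random index rows is reused across areas, the standard
implementation). With \(R\) permuted statistics at least as extreme as
the observed one on the observed sign's side, the directional pseudo
p-value is \((R+1)/(M+1)\). The folded one-tailed value (reported by
some GIS tools) rejects at about *twice* the nominal rate under a
spatially random field — each tail contributes its own \(\alpha\) — so
the package default is `alternative = "two.sided"`, the directional
tail doubled and capped at 1, which is calibrated: on iid fields about
5% of areas fall below \(p = 0.05\) (the test suite verifies the
pooled rejection fraction across 50 replicates of a 20×20 lattice lies
in [0.03, 0.07]). The directional value remains available as
`alternative = "directional"`. p-values are never zero; the smallest
attainable two-sided value is \(2/(M+1)\), so resolving the strictest
display bin (p < 0.001) requires `n_perm` ≥ 2999. The default
`n_perm = 999` resolves the 0.05 and 0.01 bins.

Raw p-values are thresholded at 0.05/0.01/0.001 without
multiple-testing correction, following the descriptive cluster-mapping
convention; users needing familywise control can apply `p.adjust` to
the returned p column.

**Quadrants.** Significant areas are classified by the signs of the
deviation and the spatial lag: HH (hot spot), LL (cold spot), HL/LH
(spatial outliers). Zero deviations or lags are assigned to the "low"
side, a tie-break that only matters for pathological inputs. Stratum
summaries pool *daily* values (not period means) within hot, cold,
isolated and non-significant strata — HL/LH outliers are counted with
the non-significant stratum, keeping the four-way partition — so the
reported min/max are daily extremes.

## The synthetic generator

`simulate_panel()` builds each variable as

> static spatial Gaussian random field (exponential covariance,
> correlation length `range` cells) + seasonal sinusoid keyed to day
> of year over 365.25 + region-wide stationary AR(1) daily noise +
> iid measurement noise,

with structural couplings on top:

- dewpoint = Temp − (positive depression); VP = Magnus(dewpoint) —
  forces the near-perfect Temp–VP correlation;
- PM10 = PM2.5 + independent coarse mode — forces the near-perfect
  PM2.5–PM10 correlation;
- a region-wide wet-day indicator drives zero-inflated gamma
  precipitation and reduces UV — the negative Prec–UV correlation;
- O3 = base + `beta_uv_o3`·UV + warm-season term −
  `titration_strength`·(NO2 anomaly)·winter weight − density effect;
  NO2 has a winter-peaking cycle, a density term and a small
  summer-weighted UV coupling. In winter the titration term dominates
  (NO2–O3 negative), in summer the shared UV driver dominates (NO2–O3
  positive) — the seasonal sign flip, produced by weighting rather
  than by chemistry integration, which is out of scope;
- NO2, PM2.5 increase and O3 decreases linearly in log10 population
  density (+3.0, +1.5 and −4.0 µg/m³ per decade of density), giving
  strictly monotone category gradients on lattices of a few hundred
  cells.

Defaults (bases near 9.7 °C, 15.4 W/m², 12.2 / 51.5 / 11 µg/m³ etc.)
are set to the magnitude of a central-European daily panel. The
spatial covariance of real reanalysis panels is not identifiable from
published summaries, so the field range is a free knob; the default of
1 cell (neighbor correlation ≈ 0.37) gives visible clustering without
making the whole lattice one cluster. Per-variable spatial sds (e.g.
0.8 °C for Temp, 2–3 µg/m³ for pollutants) are modest relative to the
temporal spreads, as in real panels.

What the generator does **not** emulate: atmospheric transport and
chemistry, georeferenced coordinates (everything is planar), irregular
polygon shapes, missing data, instrument changes, and long-range
spatial trends. Passing the recovery and structure tests therefore
shows the *methods* behave correctly on panels with this covariance
anatomy, not that any particular real-world estimate is reproduced.

Determinism: every stochastic step runs under a single seed
(`withr::with_seed`), and the pipeline derives per-stage seeds from
its top-level seed by a fixed multiplicative rule, so one integer
reproduces a whole report bundle checksum-for-checksum.

## Validation experiment sizes

The test suite's experiments use a 20×20 lattice (400 areas) and
three-year panels: oracle equivalence on 50 random lattices up to 6×6;
permutation calibration pooled over 50 iid replicates at
`n_perm = 999`; cluster recovery with a 3×3 block shifted by five
spatial-field sds at `n_perm = 2999` (the smallest count resolving
p < 0.001 two-sided). The recovery experiment's specificity clause —
no same-sign cluster at p < 0.001 more than one cell outside the
planted block — is stochastic: the background random field itself
occasionally (in a few percent of seeds) contains a genuine cluster
that strong, which a correct method must report. That is a property of
the study conditions, not an error of the detector.

## Known limitations

- Contiguity is vertex-based; polygon layers whose shared borders are
  digitized with disjoint vertex sets need snapping beforehand.
- Pearson correlation measures linear association only; rank-based or
  nonlinear measures are out of scope.
- The raster aggregator assumes rectangular, axis-aligned,
  non-overlapping cells in the same planar coordinates as the
  polygons; no geodesic correction or reprojection is performed.
- `daily_mean()` drops incomplete days (default <75% of hours) rather
  than imputing.
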