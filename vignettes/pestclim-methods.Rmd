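---
title: "Calibrated temperature ensembles and pest performance models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated temperature ensembles and pest performance models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestclim)
```

## The problem

Small ectotherms experience temperature at the scale of their bodies and
habitats, not at the scale of climate grids. In the heterogeneous
agricultural mosaics of the equatorial high Andes — sub-hectare fields of
potato, bean, corn, alfalfa and pasture between ~2700 and 3300 m — the air
temperature inside a crop canopy can differ systematically from the air
temperature 1.5 m above ground, and both differ from a 1-km monthly
climatology. `pestclim` provides the machinery to ask how much this choice
of temperature dataset matters for predicting monthly abundances of potato
tuber moths, using synthetic data with known ground truth throughout.

Three dataset resolutions are represented as *monthly ensembles*: for each
calendar month, a set of temperature values. The climatology contributes a
single value per month; the station dataset contributes one value per
simulated year (between-year variance); the microclimate dataset contributes
one value per year and field (between-year plus across-field variance).

## Standardizing a station record

A simulated logger record (30-minute resolution over 3 years by default) is
aggregated to monthly means and decomposed additively into trend, seasonal
and random components, using the conventional algorithm: trend by a centred
12-term moving average with half-weight endpoints, seasonal as the month-wise
means of the detrended series centred to sum to zero, random as the
remainder. The seasonal profile is checked against the reference climatology
by the lag-0 Pearson cross-correlation; in the packaged experiment this is
0.83–0.95, so the climatology is adopted as the seasonal backbone. The
random component is fitted by maximum likelihood as a Gaussian; Shapiro–Wilk
statistics are *reported, never enforced* — if normality is rejected, a
warning is emitted and the Gaussian fit proceeds. Edge months where the
moving-average trend is undefined are excluded from the fit rather than
imputed, the standard practice for classical decomposition.

Simulated station ensembles then draw, for month $m$ and year $y$,
$$T(m, y) = \mathrm{ref}[m] + \varepsilon,\qquad
\varepsilon \sim N(\mu, \sigma),$$
so that simulated temperatures live on the absolute Celsius scale. Passing
the reference monthly values themselves (rather than a zero-centred seasonal
figure) is a deliberate choice: the climatology has one value per month, so
its seasonal component and its monthly values coincide up to the annual
mean, and keeping the absolute scale lets every later stage work in degrees
Celsius.

### Why the station generator has a month-scale anomaly term

The logger simulator has additive structure
`seasonal + trend + diurnal + anomaly(month) + N(0, noise_sd)`. A
reading-level noise term alone cannot produce a realistic random component:
a month of 30-minute readings averages ~1400 values, shrinking reading noise
by a factor ~38, which would leave the monthly series essentially
deterministic and the fitted $\sigma$ near zero. Real month-to-month weather
anomalies are shared by all readings within the month, so the generator adds
a per-calendar-month Gaussian anomaly (`monthly_anomaly_sd`, default 0 for
the bare generator; the packaged experiment uses 0.5 °C, which yields fitted
$\sigma$ of ~0.2–0.4 °C, consistent with intra-annual SDs of 0.5–0.7 °C at
these sites). The diurnal term (3 °C amplitude sinusoid peaking at 15:00) is
irrelevant after monthly aggregation but exercises the aggregator.

## The microclimate model

In-canopy temperature is modelled as a linear function of air temperature,
one coefficient pair per elevation band × crop × phenological stage; the
packaged table holds the 20 fitted relations (slopes 0.31–1.36). Slopes
below one buffer extremes — canopies are warmer than air on cold days and
cooler on warm days — and the package asserts this compression property on
constructed all-slope<1 model sets. Bare soil passes air temperature through
unchanged, since air temperature differences in the first 2 m above bare
ground are negligible. The relation is held constant over the year, and no
residual noise is re-added when applying a fitted line: the transform is
deterministic.

Fields advance monthly along a cyclic rotation track. The packaged default
track cycles each crop through stage 1 (3 months) then stage 2 (3 months)
before the next crop in a fixed order; bare-soil fields persist unless the
track lists them. The default is a YAML-overridable stand-in chosen to
preserve the mechanism that matters — stage- and crop-dependent thermal
buffering varying over the year — without claiming to reproduce any
particular local rotation calendar. Initial stages are drawn 50/50 between
stages 1 and 2 (configurable), and each site's crop mix defaults to uniform
across the five crops plus 10% bare soil (configurable). Elevation bands
split at 3000 m, matching the grouping of the four packaged sites
(2713/2727 m vs 3152/3280 m).

## Performance curves

Survival and development rates use the Sharpe–Schoolfield thermodynamic
model with gas constant R = 1.987 cal mol⁻¹ K⁻¹ and the 298.16 K reference
temperature kept verbatim. Inputs are °C throughout the pipeline and
converted as $T_K = T_C + 273.15$ at the point of evaluation. Survival uses
the same functional form as development with its own parameter set, clamped
to $[0, 1]$. Exponent arguments are capped at 700 before exponentiation so
the rate is finite for any finite temperature; the denominator is $\ge 1$,
so no division blow-up is possible.

Fecundity uses a gamma-type curve
$F(T) = o + p\,e^{-x}\left(\frac{x+s-1}{s-1}\right)^{s-1}$ with
$x = (T-q)/r$, defined where $x + s - 1 > 0$ and clamped to the baseline
$o$ outside. Setting $\partial \log F/\partial x = -1 + (s-1)/(x+s-1) = 0$
gives the analytic maximum $x = 0$, i.e. $F(q) = o + p$ — a property the
tests confirm by grid search. The packaged species parameters are
placeholder sets producing biologically plausible curves (thermal optima at
15–20 °C, survival peaking near 0.6, development ~0.04 d⁻¹); real analyses
should substitute literature-fitted values per species.

Curves are evaluated on *every ensemble member*, then summarized per month
by mean and quartiles (type-7 interpolation). Evaluating members rather than
monthly means is what lets ensemble variance propagate into performance: by
Jensen's inequality, spreading an ensemble across a concave region of the
curve lowers the mean performance, which is exactly the mechanism by which
dataset resolution changes predictions. When several species parameter sets
are supplied, the metric values are averaged across species before
summarizing.

## Abundance regression

Replicate monthly counts are joined to the performance summary of their
site × month. Candidates are the four means (`S`, `D`, `F`, `temp`) plus
first and third quartiles of each (`q1S` … `q3temp`, 12 columns); the
climatology's single value per month makes its quartiles degenerate, so
climatology designs use means only, and any exactly duplicated candidate
columns (e.g. after a single-year simulation where q1 = mean = q3) are
dropped to keep the design full rank. Selection is bidirectional stepwise
AIC from the full model with lexicographic tie behaviour, delegated to the
standard greedy search. The reported AIC is the full Gaussian form
$n\log(2\pi \widehat{RSS}/n) + n + 2(k+1)$; the search criterion differs
only by an additive constant in $n$, so the selected model is identical, but
absolute AIC values are not comparable to environments that drop the
constant. Abundances are modelled untransformed, and predictions are not
clipped at zero (clipping is a property of the count generator, not of the
linear model).

Temporal validation runs a two-sample Student t-test of observed against
predicted values (a paired option is exposed; the two-sample form is the
default) plus $R^2 = 1 - RSS/TSS$. Spatial validation predicts site-level
mean abundance at extra sites, reports the mean of
$|{\rm pred}-{\rm obs}|/{\rm obs}\times 100$, and regresses per-site
absolute percent error on elevation, flagging degradation with altitude at
the 0.05 level.

## The synthetic experiment

`run_experiment()` wires the stages together for the four packaged sites.
The generator defaults define the emulated study conditions:

* climatology fixtures: a fixed cosine seasonal shape peaking in February
  (warm season ~November–May), rescaled to each site's packaged annual mean
  and intra-annual SD — only the mean, SD and seasonal phase are
  consequential downstream, so the shape itself is the simplest smooth
  choice;
* a 3-year, 30-minute logger record per site (trend 0.02 °C yr⁻¹, reading
  noise 0.8 °C, monthly anomaly 0.5 °C);
* 30 simulated years per ensemble (tests and the packaged determinism checks
  use 3–10 years to keep runtimes in seconds);
* ground-truth abundances from
  $N = 20 + 150\,S + 0.5\,q3F + N(0, 15)$, rounded and clipped at zero,
  6 replicates per site × month — coefficients chosen once so counts land on
  the observed ~85–140 monthly scale;
* 15 extra sites on a 2600–3600 m gradient for spatial validation, with
  temperatures from a −0.0056 °C m⁻¹ lapse rate anchored at the lowest site,
  and a site-level abundance offset whose SD grows with elevation
  (replicate-level noise averages out of site means, so an
  error-vs-elevation gradient must be injected at the site level).

Seeds are per-stage (small offsets of one base seed) so stages can be rerun
independently; the manifest records the configuration hash, seeds, fitted
random-component models, cross-correlations, selected models and both
validations, with output paths relative to the run directory so identical
configurations produce byte-identical manifests. Plot files are optional
artifacts and never load-bearing. A thin command-line wrapper around these
functions ships in `inst/scripts/run_pipeline.R`; the exported functions are
the primary interface.

## What passing tests do and do not show

The generator emulates additive station series, linear canopy relations with
Gaussian residuals, landscape mosaics with exact field counts, and counts
from a known linear model. It does *not* emulate soil temperatures (where
part of the moth life cycle occurs), precipitation, farmer practices,
dispersal, density dependence, trap-level placement, or non-Gaussian weather
anomalies — so green tests certify the pipeline's internal correctness and
its behaviour under the stated data model, not fidelity to any particular
field system.

Two behaviours of the real machinery deserve emphasis:

* **Dataset ordering.** When abundances are driven by microclimate-scale
  summaries, the fitted models order microclimate ≤ station ≤ worldclim by
  AIC in a majority of seeds — the finer dataset wins on its own structure.
* **Term identification is ill-posed.** Over the sites' ~9.6–14.4 °C range
  every thermal summary is a smooth monotone function of temperature;
  candidate predictors correlate at 0.995–0.999 pairwise. Stepwise selection
  then freely substitutes collinear proxies for the generating terms (the
  AIC cost of swapping `S` for `q1S` is far below the noise floor, which is
  itself bounded below by count rounding), and fitted coefficients split
  arbitrarily across the collinear set. Whole-model quantities — predictions,
  AIC, R² — are unaffected by such substitution, but term-level recovery of
  a planted model is not achievable at realistic noise, and the package's
  acceptance suite records this honestly as a failing expectation rather
  than weakening the check. Users should interpret selected terms as a
  *thermal-information summary*, never as mechanism attribution.

## Numerical choices and degenerate inputs

* Decomposition requires ≥ 24 consecutive months and errors on gaps; the
  random-component fit requires ≥ 3 non-missing values and reports W = 1,
  p = 1 for a (numerically) constant random component, where the
  Shapiro–Wilk statistic is undefined.
* Quantiles use R's default type-7 interpolation; tests pin them to a
  sort-based oracle.
* The Gaussian σ is the maximum-likelihood estimate (divisor $n$).
* `cross_correlation_lag0` refuses zero-variance profiles rather than
  returning NaN.
* Stepwise errors on singular designs, naming the collinear columns; with a
  single site (12 distinct predictor rows against 12 candidates) the full
  model is inherently singular, which is why pooled multi-site designs are
  the intended use.
* All generators are pure functions of their arguments and seed; R's
  default Mersenne-Twister stream is set locally per call.
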