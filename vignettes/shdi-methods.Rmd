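---
title: "Constructing subnational human development databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing subnational human development databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shdikit)
library(dplyr)
```

## The problem

National human development indices hide within-country disparity. To study
development subnationally one needs, for every region and every year, the
four indicators behind the index — life expectancy at birth (LEXP), log
gross national income per capita in 2011 PPP dollars (LGNIc), expected
years of schooling (EYS) and mean years of schooling of adults 25+ (MYS) —
even though regional data exist only at irregular survey and census years,
sometimes only through proxy covariates, and come from heterogeneous
sources whose definitions drift. The construction device that makes this
tractable is a complete *national* reference series: if the
population-weighted mean of the regional values is forced to equal the
national value in every year, the subnational panel inherits the national
temporal dynamics, and only the cross-sectional *variation between regions*
has to be estimated from the sparse regional data.

`shdikit` implements that construction as a tested pipeline, together with
a synthetic-data generator that emulates the statistical structure the
pipeline assumes, and a simulated error study for the gap-filling step.

## The pipeline

`build_shdi()` runs five stages.

**1. Proxy bridges.** Household surveys rarely measure life expectancy or
income directly, but they do measure under-five mortality (U5M, deaths per
1000 births) and asset wealth (the International Wealth Index, IWI, a
0–100 score). For countries with no direct LEXP or LGNIc data,
`fit_bridge()` regresses the *national* indicator on the *national* proxy
by ordinary least squares — LEXP on U5M and U5M² (mortality's effect on
life expectancy flattens at high mortality), LGNIc linearly on IWI — with
a linear year control, and `predict_subnational()` applies the fitted
curve to the regional proxy values. `select_bridge()` makes the
linear-versus-quadratic choice by adjusted R². Predictions are clipped to
the indicator's validity range *before* anchoring (the alternative order
would let a clip break the anchor). The bridge coefficients are always
fitted from the panel at hand, never hard-coded: the procedure, not a
particular coefficient vector, is the method. Optional global-region
factors and special-case indicator columns (oil exporters, crisis years)
enter additively; we read "controls for year" minimally as a linear term,
switchable to a factor.

**2. Education imputation.** Where EYS is missing but MYS exists,
`impute_eys()` transfers the regional MYS variation onto the national EYS
anchor: $E_i = E_n M_i / M_n$. Where attendance tables exist,
`eys_from_enrolment()` sums the 19 age-specific attendance shares (ages
6–24); where only attainment levels exist, `attainment_to_years()` applies
a configurable schedule (primary 6, lower secondary 9, upper secondary 12,
bachelor 15, master 16 years).

**3–4. Anchoring and gap filling.** `fill_panel()` completes each
country-indicator series over the year window. Interior missing years are
linearly interpolated between the nearest bracketing observed years;
exterior years carry the nearest observed regional values unchanged;
countries with no observations at all receive the national value (flag
code 4). Every cross-section — observed or filled — is then multiplied by
the scaling coefficient $c = x_n / \bar{x}_w$ so its population-weighted
mean $\bar{x}_w$ equals the national value $x_n$. Because $c$ is a
positive scalar, regional rankings and ratios are untouched; for carried
years this means the regional *shares* of the national value are those of
the nearest observed year while the level tracks the national series.
Income is anchored on the log scale (LGNIc is the stored indicator; its
values are strictly positive since incomes exceed one dollar), with a
`income_space = "level"` switch for scaling income levels instead — the
published scaling diagnostics treat LGNIc as the scaled object, so log is
the default. Quality flags record, per cell, the provenance code and the
gap length: distance to the anchor for extrapolation, and the *larger* of
the two anchor distances for interpolation (so a 10-year interpolation gap
means the anchors can be up to 20 years apart). A year counts as observed
for a country-indicator only when every region reports a value, since the
rescale needs the complete cross-section; survey-driven gaps are
country-wide, so this matches per-region observation in practice.

**5. Indices.** `dimension_index()` caps each indicator into its goalposts
(LEXP 20–85, GNIc 100–75,000 normalized on the natural-log scale, EYS
0–18, MYS 0–15) and maps it to $[0,1]$; capping is applied at both
goalposts for all indicators — an index outside $[0,1]$ would break the
geometric means downstream — and *after* scaling, since capping first
would destroy the weighted-mean anchor. The education index is the
geometric mean of the two schooling indices, and the SHDI the geometric
mean of the three dimension indices. Indices are kept at full float
precision internally and rounded to six decimals only at serialization.

## The synthetic world

`generate_world()` emulates the structure the pipeline assumes: countries
with 2–12 (up to 51) regions; smooth national trajectories over 1990–2017,
shaped as logistic growth toward the goalposts so values saturate
realistically near the maxima (a `"linear"` trend variant exists for
exactness checks); persistent multiplicative regional offsets (SD 0.08
around 1, truncated to [0.6, 1.4]) plus Gaussian cell noise on the
indicator scale, truncated to validity ranges; and log-normal region
populations (meanlog 13, sdlog 0.7, roughly 0.1–3 million people), held
constant over time since nothing in the source schema requires
time-varying weights. Each country-year is anchored at generation, so the
weighted-mean identity holds by construction, and the national HDI is
computed from the national indicators with the same index module — both
exact references for tests. Defaults for the free parameters (regional
dispersion, noise SDs of 0.5 years LEXP, 0.05 log points, 0.2 schooling
years) were chosen once as plausible magnitudes for subnational indicator
data; no published dispersion figures exist to calibrate against, and they
are documented as free parameters.

`generate_proxies()` attaches IWI and U5M by inverting the generative
bridge relations at the (noise-shifted) target, so a zero noise SD yields
the exact cell-by-cell relation. Because the noise then enters the proxy
through the inverse, the proxy and the error are weakly correlated — a
small attenuation of order (noise SD / indicator SD)²; the default noise
SDs keep it well below one standard error at the sample sizes used. For
clean parameter-recovery studies, `simulate_bridge_data()` generates
proxy-first data (smooth declining U5M or rising IWI country trajectories,
then the forward relation plus independent noise), the textbook OLS
setting.

What passing tests on this world shows — and does not. The generator
reproduces the *mechanics* real data exercise: sparsity patterns, weighting,
anchoring, proxy links. It does not emulate survey measurement error,
boundary changes, source-definition drift, or regional shocks that real
compilations contain; results on synthetic data validate the pipeline's
correctness, not the accuracy of any real-world database built with it.

## The error study

`error_study()` quantifies what inter/extrapolation costs. From the
observed years of each country-indicator it enumerates *every* feasible
simulation: each ordered pair of observed years gives a forward or
backward extrapolation (pooled in the output), each observed triple
$a < t < b$ an interpolation of the middle year — bounded at 15
extrapolation years and 10 interpolation years, beyond which real data
yield too few simulations to be informative. Each simulated cross-section
is produced by the same two-step procedure as production (carry or
interpolate, then rescale to the target year's national value) and
compared to the observed (anchored) values by the relative error
$100\,|sim-obs|/obs$; cells with an observed zero are excluded with a
counted warning. Distributions are summarized per indicator, method and
gap length by ventiles, computed with linear interpolation between order
statistics (`stats::quantile` type 7). The study is pure enumeration —
identical inputs give identical tables — and has an exact fixed point:
when regional shares of the national value are constant over time,
carry-plus-rescale reproduces the observations to machine precision.

## Quality summaries

`quality_report()` aggregates the flags two ways: a mutually exclusive
country-year classification (real if any indicator is real under the
default best-status rule — switchable to worst-status, since the
aggregation rule is a genuine judgment call — else interpolated, else
extrapolated by at most five years, else longer, else national), and a
count of high-quality dimensions per country-year, where high-quality
means real or interpolated and the education dimension requires *both*
schooling indicators to qualify by default (`"either"` relaxes it; the
mapping of four indicators onto three dimensions does not dictate a rule,
so the conservative reading is the default). Both summaries are reported
overall and split at a configurable year.

## Numerical choices and limitations

* Anchoring is exact to floating point; the package's own acceptance bound
  is $10^{-9}$ relative.
* Multiplicative scaling requires a strictly positive weighted mean and
  national target; a nonpositive slice is a domain error, not a silent
  skip. Zero-population regions are excluded from the mean but still
  scaled.
* Interpolation anchors are the *nearest* bracketing observed years, not
  the window endpoints — this maximizes the use of real data when more
  than two surveys exist.
* Ties between past and future anchors cannot occur for strictly exterior
  years; the past anchor would win if the situation were ever constructed.
* Gap length 0 is reserved for real and national-value cells; code-4 cells
  get `polyears = 0` as the natural convention for "no temporal
  estimation".
* Problem sizes in the test suite and acceptance script (worlds of 3–5
  countries with up to 8 regions, 100 bridge replicates of 150 × 28
  observations) were chosen so the full suite completes in well under a
  minute while leaving every statistical check comfortably powered.
* The package deliberately does not implement spline or trend
  extrapolation, additive anchoring, inequality-adjusted index variants,
  or acquisition of real source data; the file formats are plain CSV
  mirrors of the published schemas (SPSS/STATA/Excel writers are out of
  scope). There is no shell entry point: the exported functions and this
  vignette are the interface, with `scripts/acceptance.R` as a worked
  orchestration example.

## A complete run

```{r example}
w <- generate_world(world_spec(n_countries = 2,
                               regions_per_country = c(2, 4), seed = 7,
                               years = 2000:2010))
masked <- mask_panel(w$panel, c(2002, 2007), pattern = "mixed")
res <- build_shdi(masked, w$national, w$regions)
res$indices |> head(3)
res$flags |> count(polated)
res$coefficients |> summarise(min = min(coefficient),
                              max = max(coefficient))
```
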