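---
title: "Detecting soil water vapor adsorption in eddy-covariance records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting soil water vapor adsorption in eddy-covariance records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svaflux)
```

## The process and the detection problem

Soil water in the dry range is held at strongly negative water potential,
and the relative humidity of the air in the soil pores is tied to that
potential by the Kelvin equation,

$$ RH_s = \exp\!\left(\frac{M_w\,\Psi_s}{\rho_w\,R\,T}\right), $$

with $M_w = 0.018$ kg mol$^{-1}$, $R = 8.31$ J K$^{-1}$ mol$^{-1}$ and
$\rho_w = 1000$ kg m$^{-3}$. A soil in equilibrium with 80 % relative
humidity sits near $-3.0\times10^{5}$ hPa; 95 % corresponds to roughly
$-6.9$ MPa at 20 °C. When the atmosphere above a dry soil is *more* humid
than the soil pore air ($RH_a > RH_s$), the vapor pressure gradient points
downward and water vapor adsorbs into the soil — at an eddy-covariance
tower, a negative latent heat flux ($\lambda E < 0$).

Individual nocturnal half hours cannot be trusted: nighttime $\lambda E$ is
small and the random flux error is of comparable magnitude and symmetric.
What *is* detectable is dominance: if downward fluxes dominate
systematically in the region of the $(RH_a, VWC)$ plane where the gradient
physics allows adsorption — dry soil, moist air — and upward fluxes
dominate elsewhere, the pattern is a fingerprint of soil vapor adsorption
rather than noise. The package formalizes this as template classification.

## Boundary templates

The zero-gradient boundary in $(RH_a, VWC)$ space is the soil's retention
relationship expressed through the Kelvin equation. Rather than fitting a
multi-branch retention model, templates use a one-parameter family that is
log-linear in potential (the Campbell–Shiozawa form commonly used for the
dry, adsorptive range): in pF units ($\log_{10}$ of suction in hPa) the
water content falls linearly from its value at 80 % RH (pF $\approx 5.48$)
to zero at oven dryness, taken at pF 6.8 as is conventional for oven-dry
retention work (configurable via `psi_dry`). The single index

* `vwc_rh80` — the volumetric water content (vol-%) in equilibrium with
  80 % relative humidity

names each template. This preserves exactly the property the classifier
consumes — a monotone boundary ordered by `vwc_rh80`, so that adsorption
regions nest as the index grows — without claiming laboratory fidelity.
Users with dry-range laboratory measurements can instead supply anchor
pairs, interpolated piecewise-linearly in $(\ln RH, VWC)$
(`evea_template(anchors = ...)`, `read_template_anchors()`).

Conversions between humidity and potential inside templates use a fixed
reference temperature of 293.15 K: over the meteorological range the
temperature sensitivity of the Kelvin relation is second-order (the package
asserts $|RH(\Psi, 278\,\mathrm{K}) - RH(\Psi, 308\,\mathrm{K})| < 0.03$
down to $-3\times10^7$ Pa). Points exactly on the boundary are classified
as *not* adsorption-capable — the conservative tie rule. At exactly 100 %
RH the parametric boundary is unbounded (zero suction), so any water
content counts as below it; in practice the dew-exclusion rule governs that
corner. The default library spans an 11-point grid from sand-like to the
pure-clay end member (11.03 vol-%) plus the reference best-fit values 2.31,
4.20, 8.08 and 11.0; the 11-point grid is a synthetic stand-in for
texture-class averages, chosen to cover the plausible range, not a
reproduction of any laboratory set.

## Filters and binning

The classifier sees only defensible data: measured, good-quality latent
heat flux (QC flag 0), no day with recorded rain (any positive daily total
in local tower time — evaporation of intercepted or ponded water would
mask the signal), no half hour below 5 °C (frost and sensor issues), soil
moisture within $(0, 100]$ vol-%. Filtering marks records invalid without
altering values, and attributes each exclusion to the first failing rule
(QC → rain day → temperature → moisture → missing) so the filter report
sums cleanly. Classification uses nighttime records only, where random
error is small and symmetric for both flux directions; the dataset's own
night flag is trusted and never re-derived when present. Atmospheric
relative humidity is derived from VPD and air temperature with the Magnus
equation (Sonntag coefficients a = 6.112 hPa, b = 17.62, c = 243.12 °C)
and clipped to $[0, 100]$ % to absorb sensor-level VPD slightly above
saturation.

Valid night records are binned into 5 % RHa × 2 vol-% VWC cells (half-open
intervals, the top humidity cell absorbing 100 % exactly). A cell with at
least 20 observations — about ten hours of measurements — is classified by
its fraction of negative fluxes: *atmosphere* below 0.45, *soil* above
0.55, *noise* in the inclusive band between, consistent with symmetric
random error around a weak mean.

## Scoring and two deliberate design choices

Soil-dominant cells are the positive class. Each template predicts, per
cell, whether downward flux should dominate; agreement over cells gives
TP/FP/TN/FN, accuracy, true/false-positive fractions. Cells whose whole
humidity range lies at or above 75 % RHa and whose center is too wet for
adsorption under the template are excluded from scoring as likely dew or
fog deposition. The best-fitting template maximizes accuracy, with ties
broken toward the smaller `vwc_rh80`; the null template's accuracy is the
baseline, and a null winner means adsorption is absent or undetectable.

Two choices here were genuinely open, and the package settles them as
follows:

* **Prediction is evaluated on the cell's own observations, not at the
  cell center.** A cell is predicted positive when more than 55 % (the same
  dominance cut applied to the data) of its observations lie strictly below
  the boundary. Fixed-point evaluation (e.g., the center) breaks down in
  boundary-straddling cells, where the observed dominance is computed from
  records on both sides: on a noiseless series the center rule leaves a few
  contradictory cells, while the symmetric rule makes predicted and
  observed fractions coincide cell by cell, so a noiseless site scores
  accuracy 1 exactly. The dew-exclusion mask, a coarse geometric veto, still
  uses cell centers.
* **Noise-band cells count as observed negatives** (with
  `score_template(..., noise = "exclude")` available to drop them
  instead). The positive claim is "downward flux dominates here"; a cell
  with no dominant direction is evidence against that claim, not missing
  data. The practical consequence is calibration under the null: on
  gradient-free series, marginal cells leave the noise band by chance in
  both directions, and if they are dropped, the maximum over a dozen
  templates harvests the soil-side flukes — the baseline is then beaten
  spuriously and the selected index is arbitrary. Counting noise cells as
  negatives makes every chance soil-side cell below a candidate boundary
  cost as much as it pays, and the null template wins on null data, as it
  should.

## Event statistics

Once a template is fixed, the event census returns to individual half
hours, now over the full 24 h of filtered data (a `night_only` switch
restricts it): a true-positive half hour has $\lambda E < 0$ under
conditions where the template allows adsorption. Days with at least 3 h of
such half hours are SVA days; both the floored and the raw day counts are
kept per year. A site enters network-level reporting when at least one year
has 10 or more SVA days. Median days per year are computed over all
observed years, median hours per day over SVA days only; calendar years
with fewer than 300 observed days are flagged partial but summarized.

## The synthetic generator

`generate_site()` emulates exactly the statistical structure the analysis
assumes, with ground truth attached:

* diel air temperature (sinusoid peaking at 15:00, day-to-day offsets) and
  an air vapor-pressure cycle lagged to 18:00, so relative humidity peaks
  in the cold night hours;
* rain days drawn per day, soil moisture jumping to a wet value at each
  pulse and relaxing exponentially toward a dry residual;
* soil pore-air humidity obtained by inverting a known boundary template at
  the current water content; nocturnal flux = signal × sign of the
  humidity gradient + symmetric noise (Gaussian by default, Laplace
  optionally); daytime flux is a positive solar-shaped hump plus the same
  noise;
* above 95 % RHa the nighttime flux is forced negative and flagged as dew —
  deliberately distinct from the 75 % analysis threshold, so the
  dew-exclusion rule has genuine condensation to exclude;
* QC is uniformly good and the night flag is a fixed 10-h window; rain is
  recorded so the pipeline's own filter removes those days.

`generate_null_site()` keeps the meteorology and soil dynamics but replaces
the nocturnal flux with pure noise; `generate_twin_towers()` attenuates the
surface signal (gradient and dew alike) by a decoupling factor to emulate
tall-tower measurements, reducing to the null site at full decoupling.

Defaults are the package's documented study conditions: 180-day seasons, a
nocturnal signal of 5 W m⁻² against noise of 5 W m⁻² SD, truth template
8.08 vol-%, residual moisture 2 vol-%, wet moisture 28 vol-%, 12-day
drydown, 5 % rain-day probability. The signal-to-noise ratio of one is a
synthetic calibration — chosen so single half hours are unreliable (the
regime the method is designed for) while 20-observation bins are decisive —
and not a claim about field magnitudes. Under these conditions the test
suite demonstrates: recovery of the generating template within one library
step in at least 90 % of 20 seeded runs with mean accuracy improvement
above 0.1; null-template selection in the majority of 20 gradient-free
runs with mean improvement at most 0.02; and, with noise and dew switched
off, perfect template scores and exact half-hour agreement between labeled
and true adsorption.

What the generator does *not* emulate — and what passing tests therefore do
not establish about field data: heteroscedastic flux error growing with
flux magnitude, gap-filled records, storage and advection effects,
vertical soil-moisture structure (one layer only), hysteretic or
temperature-dependent retention, realistic dew microphysics, and
instrument drift. Synthetic validation shows the chain is correct, not
that any particular field site behaves this way.

## Numerical and degenerate-input conventions

* Water potentials are suctions, stored ≤ 0 in Pa; pF views are derived.
* RHa is clipped to [0, 100] %; binning is half-open with the top humidity
  cell closed; a flux of exactly zero counts as non-negative (upward).
* Confusion fractions with zero denominators are `NA`, never 0/0; a grid
  with no scorable cells yields a flagged fit with the null template.
* Duplicate timestamps are an error; gaps are allowed; soil moisture read
  as m³ m⁻³ (all values ≤ 1) is rescaled to vol-%.
* `-9999` sentinels become missing values at read time.
* Generators restore the caller's RNG state; identical seeds give
  byte-identical series.

## Problem sizes

The shipped tests run entirely on generated data: single sites of 60–180
days for unit checks, and 2 × 20 seeded 180-day sites for the
recovery/null calibration properties, which complete in seconds. The same
code paths scale to multi-year tower archives; only the binning counts
grow.

## Known limitations

Template selection is only as good as the (RHa, VWC) coverage: sites whose
soil never dries below the candidate boundaries, or whose humidity range is
narrow, yield few discriminating cells and the fit degenerates toward the
tie-break. The dew rule is a blunt threshold, not a condensation model.
Flux magnitudes are deliberately never integrated to water amounts — the
method reads directions only. Soil moisture is taken from a single
(shallowest) sensor; where the sensing depth differs from the adsorbing
skin, the boundary index absorbs that bias rather than correcting it.
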