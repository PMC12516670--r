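# svaflux

Detection of **soil water vapor adsorption (SVA)** from half-hourly
eddy-covariance records.

Dry soil takes up water vapor from the atmosphere whenever the relative
humidity of its pore air — fixed by the soil water potential through the
Kelvin equation — falls below the humidity of the overlying air. At a flux
tower this process appears as persistent, small, *negative* nighttime latent
heat fluxes (λE < 0, vapor moving toward the ground) confined to a
characteristic corner of the (atmospheric relative humidity × soil water
content) plane. `svaflux` finds that signature, separates it from random
flux noise and from dew deposition, and turns it into per-site event
statistics.

## The method in brief

Water potential Ψ (Pa, ≤ 0) and equilibrium relative humidity are linked by
the Kelvin equation

    RH = exp( Mw · Ψ / (ρw · R · T) )

with Mw = 0.018 kg mol⁻¹, R = 8.31 J K⁻¹ mol⁻¹, ρw = 1000 kg m⁻³. At 20 °C,
80 % RH corresponds to ≈ −3.02 × 10⁵ hPa and 95 % RH to ≈ −6.9 MPa. The sign
of the vapor flux between soil and atmosphere follows the sign of the
humidity gradient RHa − RHs.

The pipeline:

1. **Read & filter** FLUXNET-style half-hourly CSVs (`read_fluxnet_csv`,
   `apply_filters`): keep measured good-quality λE only (QC = 0), drop whole
   rain days, half hours below 5 °C, and implausible soil moisture.
2. **Bin** valid nighttime records into 5 % RHa × 2 vol-% VWC cells
   (`assign_bins`) and classify each cell with ≥ 20 observations by its
   fraction of negative λE (`classify_bins`): toward the *atmosphere*
   (< 0.45), toward the *soil* (> 0.55), or *noise* (in between).
3. **Score templates** (`score_template`, `fit_site`): each candidate
   boundary — a vapor-equilibrium curve VWC_eq(RHa) indexed by VWC_RH80,
   the water content in equilibrium with 80 % RH — predicts where downward
   flux can dominate. Observed vs. predicted dominance gives a confusion
   table (soil-dominant = positive class); cells above 75 % RHa that are too
   wet for adsorption are excluded as likely dew. The template with the
   highest accuracy wins; the null template (VWC_RH80 = 0, adsorption
   nowhere) is the baseline.
4. **Count events** (`label_tp`, `summarize_days`, `summarize_site`): a half
   hour with λE < 0 under dry-side conditions is an SVA half hour; a day
   with ≥ 3 h of them is an SVA day; a site qualifies when some year has
   ≥ 10 SVA days.

A synthetic tower generator (`generate_site`, `generate_null_site`,
`generate_twin_towers`) produces series with known ground truth — diel
temperature and humidity cycles, rain-pulse/drydown soil moisture, flux sign
set by a known retention boundary, symmetric nocturnal noise, forced dew at
very high humidity — so the whole chain is testable end to end.

## Worked example

```r
library(svaflux)

g    <- generate_site(synth_config(seed = 3))     # 180-day synthetic site
s    <- apply_filters(g$series)
grid <- classify_bins(assign_bins(select_night(s)))
fit  <- fit_site(grid, template_library())
fit
#> Site fit 'SYN-SVA-3': best template VWC_RH80 = 8.08 vol-%
#>   baseline ACC = 0.69, best ACC = 0.981, improvement = 0.29

fit$best
#> Template VWC_RH80=8.08: TP=22 FP=0 TN=29 FN=1 | ACC=0.981 TPF=0.957 FPF=0
#>   set aside: 0 noise, 11 dew-excluded, 136 insufficient

lab <- label_tp(s, fit$best_template)
summarize_site(summarize_days(lab, s))
#> SVA event report: included = TRUE
#>   median 61 SVA days/yr, median 8.5 h/day, SVA in 100% of years
```

The generator's true boundary is VWC_RH80 = 8.08 vol-%: the fit recovers it
exactly, lifting classification accuracy from the null baseline 0.69 to
0.98 with zero false-positive bins. The event census then counts the half
hours of detected adsorption per day (here a median of 8.5 h on 61 SVA days
in the simulated season — this generator runs a single warm season, so the
annual numbers refer to it). `run_pipeline(pipeline_config(...))` wraps the
same stages for one or many sites and writes grid matrices, a site-fit
table, event tables and a run log as CSV/JSON.

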