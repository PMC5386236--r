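# chamberflux

Processing and analysis of soil CO₂ efflux measured with multichannel
automated chamber systems, with a full synthetic-campaign generator for
offline validation.

Automated chamber systems measure soil respiration by briefly closing a
lid over a soil collar and recording the rise of the CO₂ mole fraction
with an infrared gas analyser (IRGA).  A typical installation cycles
15 chambers through sequential 240-s closures each hour, logging 10-s
averaged records; in soil-warming experiments the chambers are split
into control plots (total efflux *R*ₛ), root-trenched plots
(heterotrophic respiration *R*ₕ), and trenched + heated plots
(*R*ₕ𝓌).  `chamberflux` is for the people who run or reuse such data:
it takes the raw datalogger stream to quality-controlled hourly fluxes
and on to the treatment-level science products — warming effect, Q₁₀
temperature sensitivity, spatial variability, annual carbon sums.

## The core computations

**Flux estimation.** For a closure with concentration slope
∂C/∂t (µmol mol⁻¹ s⁻¹), chamber-height air pressure *P*air (kPa), air
temperature *T*air (°C) and effective volume-to-surface ratio
*V/S* = 0.5 m, the soil CO₂ efflux (µmol m⁻² s⁻¹) is

```
Rs = 60.14 · Pair / (Tair + 273.15) · ∂C/∂t ,     60.14 = 1000·(V/S)/8.314
```

with two slope estimators: the *linear model* (OLS slope over the whole
closure) and the *average model* (mean of per-interval concentration
changes).  The full form with the water-vapour dilution term
`C/(1000−W)·∂W/∂t` is available as `flux_full()`.  The pressure must be
the chamber-height ambient pressure, not the IRGA cell pressure (≈5 kPa
higher), which would bias fluxes by several percent — `compute_fluxes()`
exposes both so the bias can be quantified.

**Quality control.** Each closure passes through dead-band removal
(first 2–3 records), iterative OLS outlier rejection (records with
residuals beyond 3 × the residual s.d. removed, regression repeated —
three fits in total), and a usability threshold |r| ≥ 0.95 on the final
fit, with a guarded exception for near-zero winter fluxes.

**Treatment analysis.** Pre-treatment calibration coefficients
`Qc = Rs(all trenched) / Rs(treatment)` correct initial spatial
heterogeneity; the warming effect (% °C⁻¹) is

```
Fe = (Qcw·Rhw − Qch·Rh) / (Qch·Rh·(Tsw − Tsh)) × 100
```

Q₁₀ is fitted by log-linear OLS (`ln R = a + bT`, `Q10 = exp(10b)`),
spatial variability as the mean hourly cross-chamber CV, and annual
sums via 1 µmol m⁻² s⁻¹ · h = 0.04324 g C m⁻², optionally gap-filled
from the fitted Q₁₀ response.

**Synthetic campaigns.** `simulate_campaign()` emulates the full
measurement system — sequential closure schedule, dead band, IRGA
noise, instrument faults (pump stoppage, lid leak, fan failure),
seasonal/diel forcing, +2.5 °C soil warming, lognormal chamber "hot
spot" heterogeneity — and returns the raw records together with a
ground-truth bundle (true fluxes, Q₁₀, Fe, fault positions), so every
downstream stage can be validated without field data.

## Worked example

```r
library(chamberflux)

camp <- simulate_campaign("2009-07-01", "2009-07-08", seed = 42)
seg  <- segment_closures(camp$raw, camp$meta)
qc   <- qc_closures(seg)
qc
#> <closure_qc>
#>   2,520 closures, 2,520 usable (100.0%)
#>   records: 52,901 kept / 60,480 total; 7,560 dead band, 19 outliers

fluxes <- compute_fluxes(qc, model = "linear")
dplyr::select(head(fluxes, 3), time, chamber, treatment, flux, r, usable)
#>   time                chamber treatment  flux     r usable
#> 1 2009-07-01 00:00:00       1 control    8.38 1.000 TRUE
#> 2 2009-07-01 00:04:00       2 control    5.16 1.000 TRUE
#> 3 2009-07-01 00:08:00       3 control    6.49 1.000 TRUE

chamber_cv(fluxes)
#>   treatment       cv_pct n_hours n_skipped
#> 1 control           17.1     168         0
#> 2 trenched          26.9     168         0
#> 3 warmed_trenched   36.8     168         0
```

One week of July closures: every closure survives QC (the dead band is
7,560 records = 3 per closure; 19 noisy records were rejected by the
3σ filter), midsummer fluxes run 5–8 µmol m⁻² s⁻¹, and the hourly
cross-chamber CV per treatment reflects the generator's lognormal
spatial offsets.  Longer campaigns feed `calibrate_qc()`,
`warming_effect()`, `fit_q10()` and `annual_sums()`; `run_pipeline()`
wires all stages from a single (YAML-serialisable) configuration and
writes CSV outputs plus a JSON run manifest.

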