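---
title: "Chamber flux processing and warming-experiment analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber flux processing and warming-experiment analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberflux)
```

## The measurement and its model

A flow-through non-steady-state automated chamber measures soil CO₂
efflux by closing a lid over a soil collar for a few minutes while a
pump circulates chamber air through an infrared gas analyser.  Under a
closed lid the CO₂ mole fraction rises approximately linearly; the
efflux follows from the ideal gas law applied to the chamber headspace.
With pressure $P_0$ (Pa), effective volume $V$ (m³, including tubing),
soil surface $S$ (m²), air temperature $T$ (°C), CO₂ mole fraction $C$
(µmol mol⁻¹) and water vapour mole fraction $W$ (mmol mol⁻¹):

$$R_s = \frac{P_0 V}{R\,S\,(T + 273.15)}
        \left(\frac{\partial C}{\partial t}
        + \frac{C}{1000 - W}\frac{\partial W}{\partial t}\right)$$

The dilution term corrects for water vapour displacing dry air.  Field
IRGAs of the class emulated here do not measure $W$, and for short
(240 s) closures with long sampling tubes the term is under 1% of the
flux, so routine processing uses the simplified form with $V/S = 0.5$ m
and pressure in kPa:

$$R_s = 60.14\,\frac{P_\mathrm{air}}{T_\mathrm{air} + 273.15}\,
        \frac{\partial C}{\partial t},
        \qquad 60.14 = \frac{1000\,(V/S)}{8.314}.$$

`flux_full()` implements the complete form (and reduces exactly to the
simplified one when $\partial W/\partial t = 0$); `compute_fluxes()`
implements the simplified form with two slope estimators:

* **linear model** — the OLS slope of $C$ against closure time over all
  retained records;
* **average model** — the mean of per-interval changes
  $\Delta C/\Delta t$ over retained consecutive record pairs.

On a noise-free linear rise the two coincide; with noise the linear
model is more efficient (the average model telescopes to the endpoints
under even spacing).  Both are exposed because their agreement
(correlation ≥ 0.99 on realistic campaigns) is itself a useful data
quality diagnostic.  The per-interval sum is divided by the number of
intervals ($n-1$); dividing by $n$ — an alternative reading of the
averaging convention — is available via `interval_divisor = "n"`.

Slopes are always computed against actual record timestamps rather than
an assumed 10-s grid, so closures with missing records are handled
correctly.  The pressure must be the chamber-height ambient pressure:
the analyser cell runs about 5 kPa above ambient in this class of
system, and using it (or the 101.32 kPa standard) biases fluxes by
several percent — `pressure_source = "cell"`/`"standard"` reproduce
that bias deliberately.  Air temperature is averaged over the retained
records of each closure; when a chamber's sensor fails, the site-level
probe value can be substituted (`t_air_fallback`), mirroring standard
field practice.

## Quality control

Three stages, in `qc_closures()` (vectorised) or the per-segment
functions `strip_dead_band()`, `reject_outliers()`, `usability()`:

1. **Dead band.** After lid closure it takes 20–30 s (2–3 records) for
   chamber air to reach the analyser — lid switching time, tube transit,
   analyser response.  The first `dead_band` records (default 3) are
   discarded.  The default is the upper end of the typical range; it is
   configurable because the lag depends on tubing length and pump rate.
2. **Iterative outlier rejection.**  OLS of $C$ on time; records with
   $|e_i| > m \cdot \mathrm{sd}(e)$ removed (default $m = 3$); refit.
   Default `passes = 3` total fits — an initial fit plus two repeats,
   consistent with both "repeated twice" and "triplicate regression"
   descriptions of the procedure.  The residual s.d. uses denominator
   $n-1$ (the s.d. of the residuals, not the regression standard error);
   with zero residual scatter nothing is removed and no division occurs.
   The $3\sigma$ criterion is applied at each pass.
3. **Usability.**  A closure is usable when the final fit has
   $|r| \ge 0.95$ (Pearson correlation; configurable) and at least
   `min_points = 10` records (about half a closure) remain.  Instrument
   faults — stopped pump, leaking lid, failed mixing fan — break the
   linear rise and push $r$ well below the threshold, while normal
   operation keeps $r > 0.99$.

**Near-zero fluxes.**  $r$ is undefined or meaningless when the true
slope is ≈ 0, yet cold-season fluxes are real data.  A closure whose
fitted slope's 95% CI includes zero *and* whose residual scatter is
below `zero_noise_max` (default 1 ppm, an instrument-noise bound) is
marked `usable_zero` and retained with its (near-zero) flux, rather
than rejected for low $r$.  Setting `zero_noise_max = NULL` restores
the strict threshold.

## Treatment-level analysis

**Calibration.**  Trenched and warmed-trenched chamber groups differ
initially through spatial heterogeneity alone.  Over a pre-treatment
window (the convention is ~18 days before the heaters switch on),

$$Q_c(\mathrm{treatment}) =
  \frac{\overline{R}_{\mathrm{all\ trenched}}}
       {\overline{R}_{\mathrm{treatment}}}$$

with means over paired hours.  Because chamber offsets are
multiplicative and persistent, $Q_c$-scaling aligns the group means
exactly in expectation.  The reference set is all trenched chambers
(both groups); `reference_treatments` makes this configurable since the
convention could also be read as trenched-only reference.

**Warming effect.**  With calibrated period means and the 5-cm soil
temperature difference $\Delta T = T_{sw} - T_{sh}$:

$$F_e = \frac{Q_{cw}\overline{R}_{hw} - Q_{ch}\overline{R}_h}
             {Q_{ch}\overline{R}_h\,\Delta T} \times 100
        \quad [\%\ ^\circ\mathrm{C}^{-1}]$$

The defining equation is written with mean quantities, so the
period-mean formulation is the default; a per-hour variant
(`per_hour = TRUE`, Fe computed per paired hour then averaged) is
provided because the two differ under seasonally varying ratios.
$\Delta T \approx 0$ is an error: the per-degree effect is undefined.

**Q₁₀.**  `fit_q10()` fits $\ln R = a + bT$ by OLS on positive fluxes,
$Q_{10} = e^{10b}$, reference flux $e^{a + bT_\mathrm{ref}}$ at
$T_\mathrm{ref} = 10$ °C.  Log-linear OLS (rather than nonlinear least
squares) is the standard choice for this model and weights
proportional errors evenly; fits are refused below a 5 °C temperature
span or 30 points, where the exponent is ill-determined.  Non-positive
fluxes cannot enter the log fit; their count is reported.

**Spatial variability.**  Per hour and treatment, the CV is
$100\,\mathrm{sd}/\mathrm{mean}$ across chambers (sample sd, $n-1$);
the summary is the mean over hours.  `exclude` lets the analyst probe
how much a single "hot spot" chamber drives the treatment mean —
efflux hot spots are real fine-scale soil heterogeneity, not sensor
error, so exclusion is an analysis choice, not QC.

**Carbon sums.**  1 µmol CO₂ m⁻² s⁻¹ sustained for 1 h emits
$12.011 \times 3600 \times 10^{-6} = 0.04324$ g C m⁻²; a constant
1 µmol m⁻² s⁻¹ year is 378.8 g C m⁻² = 3.788 t C ha⁻¹.  Daily sums are
24 × the mean over available hours of the day; missing hours can be
gap-filled from the fitted Q₁₀ response evaluated at measured soil
temperature (standard practice, clearly labelled, off by default), with
the fill fraction reported.  Annual sums are exactly the sum of daily
sums.  Days are classified missing when fewer than half the expected
closures are usable (`daily_coverage()`), and `missing_fraction()`
reports the percentage to one decimal.

## The synthetic-data generator

`simulate_campaign()` emulates a 15-chamber system at a warm-temperate
evergreen broadleaf forest site.  Its defaults *are* the study
conditions, not tuning knobs:

| parameter | default | basis |
|---|---|---|
| chambers / closure / records | 15 × 240 s × 10 s | system schedule; 56 min open, 4 min closed per hour |
| dead band | 3 records (30 s) | upper end of the 2–3 record lag |
| CO₂ record noise | sd 0.5 ppm | 10-s-averaged small IRGA noise, i.i.d. Gaussian |
| cell − ambient pressure | +5 kPa | pump-side analyser cell |
| pump flow | 5 l min⁻¹ | diaphragm pump rating |
| seasonal temperature | sinusoid through 7.0 °C (mid-Jan) and 27.9 °C (mid-Aug peak) | printed monthly means |
| diel semi-amplitude | air 4 °C, soil 1 °C (2 h lag) | typical below-canopy/5-cm damping |
| warming offset | +2.5 °C at 5 cm | heater target |
| Q₁₀ / Fe | 2.5 / 9.4 % °C⁻¹ | centre of reported ranges |
| baselines at 10 °C | control 1.65, trenched 1.25 µmol m⁻² s⁻¹ | chosen so simulated annual sums land near 16 / 12 t C ha⁻¹ yr⁻¹ |
| chamber offsets | lognormal, sd 0.25 (log), mean 1 | hourly cross-chamber CVs of ~20–40% |
| soil moisture | base 0.30 m³ m⁻³ + Poisson rain events, clipped [0, 0.6] | wet monsoon site |

The concentration ramp of each closure is generated as the exact
inverse of the simplified flux equation
($s = R_\mathrm{true}(T_\mathrm{air}+273.15)/(60.14\,P_\mathrm{air})$),
so the pipeline recovers the truth to floating precision at zero noise
— the round-trip identity the test suite asserts.  Air temperature,
pressure and soil temperature are held constant within a 240-s closure
(their real drift over 4 min is below sensor resolution); dead-band
records follow a smooth quadratic transition from ambient onto the
ramp.

The warmed-trenched true flux is the trenched Q₁₀ response evaluated at
the *unwarmed* soil temperature times $(1 + F_e \Delta T/100)$: the
configured $F_e$ encapsulates the entire warming response (including
any temperature-pathway component), so the warming-effect estimator has
a well-defined truth to recover, while the *recorded* soil temperature
in warmed chambers carries the +2.5 °C offset.

**Faults** (`fault_spec()`, applied by `inject_fault()`):

* `pump_stop` — concentration holds at its closure-start value for the
  first half of the closure, then decays slowly (stagnant cell air);
  flow drops to ≈ 0.  A linear fit across this plateau-then-decay shape
  yields $|r| \approx 0.85$–$0.92$, below the usability threshold —
  the signature the QC stage must catch.
* `leak` — the ramp saturates as $(1-e^{-\lambda t})/\lambda$;
  $\lambda = 0$ is exactly the identity (verified), so attenuation is
  continuous in the parameter.
* `fan` — record scatter inflated by a factor (default 8), emulating a
  poorly mixed headspace.

Every fault window, outlier spike and dead-band setting is logged in
the returned `truth_bundle`, which is what makes detection-power
experiments (≥ 95% of pump stops flagged, ≤ 1% clean closures lost)
scoreable.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about field data: drifting analyser
calibration, autocorrelated (non-Gaussian) noise, partial lid seals
shorter than a closure, rain-on-lid transients, moisture limitation of
respiration (a multiplicative moisture modifier exists but is off by
default, because no functional form is established for this site),
root-exclusion artefacts in trenched plots (decaying severed roots,
altered moisture), and long-term SOC depletion under warming.
Parameter-recovery results on synthetic campaigns demonstrate the
*estimators* are consistent under the stated noise model, not that the
field values are correct.

## Numerical choices and edge cases

* Grouped OLS is computed from group sums (`rowsum`), identical to
  `lm()` to ~1e-10 relative on realistic magnitudes; catastrophic
  cancellation limits agreement to ~1e-11 in residual s.d., which is
  why test tolerances are 1e-8 rather than machine epsilon.
* Zero residual variance short-circuits outlier rejection (no division);
  a perfectly flat trace has undefined $r$, slope 0, and is handled by
  the usable-zero rule.
* Segmentation splits at chamber-id changes, cycle boundaries and gaps
  > 30 s; offsets are relative to the first record of the segment, so
  no schedule knowledge is required for real files.  Segments under 12
  records are flagged short.  Invalid rows (missing-value sentinel) are
  retained and counted, never silently dropped.
* Timestamps are Japan standard time (UTC+9, no DST); a closure belongs
  to the hour containing its start.
* Determinism: all randomness in a campaign flows from one integer seed
  (`withr::with_seed`), and `run_pipeline()` reruns byte-identically
  (manifest timestamp aside).

## Validation problem sizes

The test suite exercises: unit fixtures at single-closure scale;
one-to-two-day campaigns (3–15 chambers) for round-trips, determinism
and fault mechanics; a 20-day 15-chamber September campaign with 100
injected pump stops for QC power; one full simulated year (15 chambers,
~3.2 M records) for model agreement; a year plus an 18-day
pre-treatment window for Fe recovery; and 50 replicate years of hourly
fluxes (lognormal noise, sd 0.1) for Q₁₀ recovery.  These sizes give
Monte-Carlo error comfortably inside the assertion tolerances while the
whole suite runs in a few minutes.

```{r example, eval = FALSE}
camp <- simulate_campaign("2008-12-20", "2009-12-31",
                          warming_start = "2009-01-07", seed = 11)
qc <- qc_closures(segment_closures(camp$raw, camp$meta))
fx <- compute_fluxes(qc)
cal <- calibrate_qc(fx, window = c("2008-12-20", "2009-01-07"))
warming_effect(fx, camp$env, cal, camp$meta,
               period = c("2009-01-07", "2009-12-31"))
#> <warming_effect>
#>   Fe = 9.40 % per degC  (deltaT = 2.50 degC, period_mean)
```

## Known limitations

* Only linear concentration models: short closures show no curvature in
  this system, so nonlinear (e.g. saturating) flux models are out of
  scope by design; data from long-closure systems need other tools.
* The usable-zero rule trades a small false-accept risk at low flux for
  not discarding winters wholesale; analyses sensitive to near-zero
  fluxes should inspect the `usable_zero` flag.
* Gap-filling inherits the Q₁₀ model's biases (no moisture term); fill
  fractions are reported so users can bound the exposure.
* The generator's file dialect is a documented stand-in: real logger
  files are read by supplying a column map, not auto-detected.
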