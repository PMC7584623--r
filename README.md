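# floatbloom

Phytoplankton bloom cycles in the Southern Ocean, derived from
biogeochemical profiling-float observations.

## The scientific problem

Whether a phytoplankton bloom forms is set not by the division rate μ
alone but by the *net* biomass rate of change

r = (1/P) dP/dt = μ − l,

the small residual between division (μ, d⁻¹) and losses l (grazing, viral
lysis, sinking). In the Southern Ocean, profiling floats observe the full
water column year-round — including under sea ice — and make it possible
to resolve r, μ and their seasonal phasing in situ. `floatbloom`
implements that analysis chain as a tested R package:

- **Biomass from optics.** Particulate backscattering at 700 nm is
  converted to particulate organic carbon, POC = 3.12×10⁴ · b_bp(700) + 3.0
  (mg m⁻³), and phytoplankton carbon C_phyto = 0.19 · POC, with a
  deep-reference (900–2000 m) offset correction and negative-value
  screening.
- **Division rates from photoacclimation.** A carbon-based productivity
  model: μ(z) = μ_max · NSI(z) · LSI(z), with μ_max = 2 d⁻¹, a nutrient
  saturation index NSI = (Chl:C − Chl:C_{μ=0})/(Chl:C_max − Chl:C_{μ=0})
  diagnosed from the local chlorophyll-to-carbon ratio, and a light
  saturation index LSI = 1 − e^(−5·PAR(z)). The underwater light field
  uses a chlorophyll-dependent attenuation
  Kd = 0.0166 + 0.0773·Chl^0.672 m⁻¹.
- **The switching algorithm for r.** Between consecutive casts,
  r = (2/Δt)(x₂ − x₁)/(x₂ + x₁), where x is the mixed-layer *mean*
  concentration when the mixed layer shoals and the vertically *integrated*
  inventory when it deepens (or is stationary). This removes apparent
  biomass changes caused by entrainment dilution and detrainment, leaving
  the ecological balance μ − l.
- **Phenology and climatologies.** Weekly day-of-year climatologies
  (circularly smoothed, interpolated to 365 days), bloom initiation and
  termination (zero crossings of r), the autumn r-minimum, and bloom
  magnitude (summer Nov–Jan minus winter May–Jul mean mixed-layer
  biomass), per zone (STZ/SAZ/PAZ/SIZ latitude bands).
- **A lagged-loss sensitivity experiment.** The loss rate is modeled as μ
  lagged by a fitted number of days (the disturbance–recovery closure;
  the lag is selected by RMSE over 1–10 days), the climatological μ cycle
  is damped by 10–60 % (summer down, winter up), and the biomass annual
  cycle is re-integrated to quantify bloom-magnitude and NPP responses.
- **A seeded synthetic float-array generator** that emulates Argo-like
  sampling (5 m bins in the upper 100 m, coarsening below; 5–10-day
  cadence; under-ice position gaps; lognormal sensor noise) with known
  truth fields, so every stage is testable offline, plus satellite-PAR and
  dissolved-iron matchup engines (same-day nearest pixel; 500 km / same
  month / upper 200 m haversine matchup).

## Worked example

```r
library(floatbloom)

cfg     <- truthConfig(seed = 1)               # 8 floats, 2 years, 10-day cadence
floats  <- emitFloatProfiles(simulateTruth(cfg))
derived <- processProfiles(floats$profiles, floats$par_matchups)
derived
#> DerivedProfileSet: 584 usable casts ( 0 dropped )
#>   MLD 41-150 m, pbar 1.7-20.3 mg C m-3

rates <- netRateOfChange(derived)
rates
#> RateSeries: 576 intervals ( 288 concentration / 288 inventory ), 0 skipped

clim   <- buildClimatology(derived, rates)
events <- detectBloomEvents(dailyCycle(clim)$r)
#> bloom initiation day 78, termination day 294, r minimum day 362

fit <- fitLossLag(dailyCycle(clim)$mu, dailyCycle(clim)$r)
#> fitted loss lag: 2 days (RMSE 0.0026 d-1)

sweep <- runSensitivitySweep(clim)
round(sweep$response[, c("s", "bloom_magnitude", "npp_annual_mean")], 2)
#>     s bloom_magnitude npp_annual_mean
#> 1 0.0            1.71         1858.14
#> 2 0.1            0.90         1264.91
#> 3 0.2            0.41          925.93
#> 4 0.3            0.12          736.82
#> 5 0.4           -0.05          635.37
#> 6 0.5           -0.16          584.64
#> 7 0.6           -0.21          562.85
```

Reading the output: the pipeline recovers the 2-day loss lag built into
the generator; the bloom (r > 0) runs from day 78 to day 294 of this
synthetic annual cycle, with the strongest net biomass loss (r minimum)
on day 362; and progressively damping the seasonal μ contrast (s = 0 →
0.6) flattens the modeled biomass cycle, shrinking the summer−winter
bloom magnitude (1.71 → −0.21 mg C m⁻³, i.e. past flat) and the annual
mean vertically integrated production (units mg C m⁻² d⁻¹).

A command-line surface with `simulate`, `process`, `climatology`,
`phenology`, `sensitivity` and `matchup` subcommands lives at
`inst/cli/floatbloom.R` (YAML config, CSV artifacts).

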