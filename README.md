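# seepsim

Transport–reaction modelling of methane seepage and gas-hydrate stability
in shallow marine sediments.

Porewater sulfate profiles with a "kink" — a near-seawater upper segment
over a steep decline to the sulfate–methane transition zone (SMTZ) — record
a recent increase in upward methane supply.  `seepsim` is for scientists who
want to (i) date such a pulse from a measured sulfate profile, (ii) test
whether seasonal or decadal bottom-water warming can destabilize shallow
gas hydrate, and (iii) screen candidate mechanisms (seawater intrusion,
mass-transport deposits, porosity caps, methane pulses, upward advection)
for non-steady-state porewater profiles.

At its core are:

* a 1-D Crank–Nicolson finite-volume kernel for
  `∂(φC)/∂t = ∂/∂z(φ D_s ∂C/∂z)` with operator-split kinetics and upwind
  advection;
* a reduced sulfate–methane model closed by dual-Monod anaerobic oxidation
  of methane, `R = k_max · [SO4]/(K_SO4+[SO4]) · [CH4]/(K_CH4+[CH4])`
  (k_max = 2 mol m⁻³ yr⁻¹, K_SO4 = 0.5, K_CH4 = 5 mol m⁻³), inverted by
  `fit_onset()` over a tortuosity bracket θ ∈ {1.5, 2.2};
* a conductive heat model (κ = 33.4273 m² yr⁻¹, geothermal gradient
  0.044 °C m⁻¹) with a seawater structure-I methane-hydrate phase boundary
  anchored at 4.05 °C / 60 mbsf;
* a simplified multi-species diagenetic network (SO4, ΣHS, TA, Fe²⁺, Ca²⁺,
  Mg²⁺, NH4⁺, CH4, acetate, H2 + five solid phases) for the five-scenario
  screening;
* synthetic-data generators with known truth for estimator validation.

See the methods vignette (`vignettes/porewater-dating.Rmd`) for the models,
assumptions and design decisions.

## Worked example

Generate a synthetic rhizon-style core from a seep whose methane pulse
began 18 years ago, then date the pulse from the (noisy) sulfate profile
alone plus the observed hydrate depth:

```r
library(seepsim)

ds  <- generate_porewater_dataset(synthetic_profile_spec(seed = 11,
                                                         noise_sd = 0.56))
fit <- fit_onset(ds$profile, reduced_model_config(),
                 hydrate_depth = ds$truth$hydrate_depth,
                 site_id = "synthetic core")
fit
#> Methane-pulse onset fit for synthetic core
#>   tortuosity 1.5: onset 16 yr before present
#>   tortuosity 2.2: onset 17.5 yr before present
#>   onset interval: 16 - 17.5 yr
```

The fit recovers the 18-year truth to within its noise-limited uncertainty
(a few years at 2% measurement noise); the two tortuosities bracket the
plausible porous-medium diffusivities, and the slow-diffusion end always
needs more elapsed time.  `summary(fit)` adds the kink depth, the fitted
weak methane supply and the misfit; `predict(fit)` and `plot(fit)` return
and draw the fitted profiles.

Thermal screening with the same defaults:

```r
seasonal <- run_warming_scenario("seasonal")
seasonal
#> gas-hydrate stability report
#>   maximum destabilization depth: 2.71 mbsf
#>   full column never destabilized

slow <- run_warming_scenario("slow")    # 0.005 degC/yr for 300 yr
slow$time_to_full_column_destabilization
#> [1] 285.8
```

Seasonal temperature swings only disturb hydrate in the uppermost couple
of metres; a sustained 1.5 °C warming eventually destabilizes the whole
60-m column, after a lag of decades to centuries set by conductive
propagation.

A thin command-line front end (`exec/seepsim`) exposes the same pipeline:
`seepsim fit-onset --profile core.csv --hydrate-depth 2.0 --out results/`.

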