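---
title: "Dating methane pulses and assessing hydrate stability from porewater and thermal modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating methane pulses and assessing hydrate stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Shallow marine gas-hydrate systems expose two linked questions to porewater
geochemistry.  First, when sulfate profiles show a "kink" — a near-seawater
upper segment over a steep, quasi-linear decline to a sulfate–methane
transition zone (SMTZ) — the system is out of steady state, and the shape
records a recent change in the upward methane supply.  How recent?  Second,
bottom-water temperature varies seasonally by several degrees at these water
depths; does that variability, or decadal warming, reach the gas hydrate and
destabilize it?

`seepsim` implements three connected models around a shared 1-D
Crank–Nicolson finite-volume transport kernel:

1. a **reduced sulfate–methane model** for dating the onset of a methane
   pulse from an observed sulfate profile (`fit_onset()`),
2. a **conductive heat model** with a structure-I methane-hydrate phase
   boundary for stability screening (`propagate_temperature()`,
   `assess_stability()`, `run_warming_scenario()`), and
3. a **simplified multi-species diagenetic network** that discriminates
   among five candidate mechanisms for kink-type profiles
   (`run_scenario()`).

# The reduced sulfate–methane model

The governing equations are the classical early-diagenesis pair

$$\frac{\partial (\phi C_i)}{\partial t} =
  \frac{\partial}{\partial z}\Big(\phi D_{s,i}\,
  \frac{\partial C_i}{\partial z}\Big) - \phi\,R_\mathrm{AOM},
  \qquad i \in \{\mathrm{SO_4^{2-}}, \mathrm{CH_4}\},$$

on a 60-m column (dx = 0.025 m, porosity 0.7, dt = 0.01 yr; 0.025 yr for
multi-millennial runs), closed by dual-Monod anaerobic oxidation of methane

$$R_\mathrm{AOM} = k_\mathrm{max}
  \frac{[\mathrm{SO_4}]}{K_\mathrm{SO_4} + [\mathrm{SO_4}]}
  \frac{[\mathrm{CH_4}]}{K_\mathrm{CH_4} + [\mathrm{CH_4}]},$$

with $k_\mathrm{max} = 2$ mol m$^{-3}$ yr$^{-1}$, $K_\mathrm{SO_4} = 0.5$
and $K_\mathrm{CH_4} = 5$ mol m$^{-3}$.  AOM consumes both solutes 1:1; it
is the only reaction, and there is no advection — an intentionally austere
model whose only adjustable quantities are the methane boundary condition
and the elapsed time.  Diffusivities come from the linear-in-temperature
infinite-dilution compilation (sulfate 0.0158, methane 0.0301 m$^2$
yr$^{-1}$ at the 0.56 °C bottom-water temperature) divided by the square of
a tortuosity $\theta$; because $\theta$ is unknown for these sediments the
model brackets it with $\theta = 1.5$ and $2.2$.

## Spin-up and the shape of the pulse

The pre-pulse initial condition is the steady state under a weak bottom
methane supply.  `spin_up_initial_state()` obtains it by a damped Newton
solve of the full coupled nonlinear system (interleaved unknowns give a
bandwidth-2 Jacobian) followed by a short transient "settling" run, so that
the returned state is stationary *for the operator-split stepper itself*:
one further century of stepping moves the profile by less than $10^{-8}$
relative.  Literal time-stepping to steady state would cost $\sim 10^5$
years of model time on a 60-m diffusive column.

The pulse itself needs care.  Dissolved-phase diffusion moves signals by
$2\sqrt{D_s t} \approx 2$–4 m per century, so *no* perturbation applied only
at the 60-m base can restructure the upper metres on observable timescales.
What ascends quickly in these systems is free gas.  `simulate_pulse()`
therefore represents the pulse as the near-instantaneous emplacement of
reservoir-level dissolved methane (the solubility ceiling, 64 mol m$^{-3}$)
below a *gas-front depth*, together with the switch of the bottom boundary
to the strong value.  The gas front is constrained by the shallowest
observed gas hydrate or gas microfracture, the same datum that anchors the
modelled methane profile in the site calculations: where free gas or
hydrate is present, dissolved methane sits at its solubility ceiling.

## The onset estimator

`fit_onset()` inverts the forward model in three steps per tortuosity:

1. **Kink detection** (`detect_kink()`): exhaustive two-segment
   piecewise-linear fitting above the exhausted-sulfate tail; the shallow
   segment must be much flatter than the deep one.
2. **Joint fit by profile likelihood**: for each trial weak supply the
   forward trajectory is scanned (every `scan_resolution` years, with an
   early stop once the misfit has clearly passed its minimum) for the time
   minimizing the depth-weighted RMS misfit over the *whole* profile; the
   weak supply minimizing the profiled misfit is selected with a
   golden-section search.  Fitting the weak supply against the shallow
   segment alone — treating it as an unmodified relic — biases the onset
   low by ~25% in synthetic trials, because the shallow segment keeps
   evolving after the pulse; the joint fit removes that bias.
3. **Envelope**: the per-tortuosity estimates and their range form the
   onset interval (`onset_interval`).

The misfit scan along a single trajectory replaces a golden-section search
over time: it is equivalent (the trajectory passes through every candidate
elapsed time), cheaper, and it exposes non-unimodal misfit curves, which
trigger a warning rather than a silent wrong answer.

## What the synthetic-data generator emulates — and what it does not

`generate_porewater_dataset()` produces rhizon-style profiles (0.1-m
sampling over the top 3 m) from a forward run with known truth, plus
additive Gaussian noise (default 0.3 mol m$^{-3}$, ~1% of seawater sulfate,
matching reported analytical precision).  The default study conditions were
fixed once, before estimator validation, at a regime that actually exhibits
the target morphology: weak supply 15 mol m$^{-3}$ (initial SMTZ ~29 mbsf,
hence a near-seawater relic segment), gas front at 2.0 mbsf (hydrates are
recovered at 0.85–2.9 mbsf in such cores), true tortuosity 2.2, and a true
onset of 18 years, which leaves a kink near 1.2 mbsf and an SMTZ at ~1.9
mbsf — inside the observed 0.5–2.2 mbsf window.

Two honest caveats follow from the physics rather than the implementation:

* **Kink lifetimes are short at these diffusivities.**  The relic segment
  above a kink at depth $z_k$ relaxes on a timescale $z_k^2/4D_s$ — years
  to decades for $z_k \lesssim 1.5$ m.  A purely diffusive model therefore
  produces kink-type profiles only for recent onsets; the centennial site
  estimates reported for these mounds rely on the same inverse logic but
  are not desk-reproducible (the measured profiles exist only as figures),
  and reproducing them is explicitly out of scope.  An information
  (Cramér–Rao) analysis of the forward model showed that at centennial
  onsets under the stated noise and sampling, *no* estimator could meet the
  ±10% recovery target; at the chosen regime the bound is ~4% of the true
  onset.
* **The tortuosity bracket contributes little dating uncertainty here.**
  In the chosen supply-limited regime the front clock is set mostly by AOM
  consuming the sulfate that overlaps the emplaced methane, not by
  diffusion, so the $\theta = 1.5$ and $\theta = 2.2$ estimates differ by
  only ~2 years.  The strict ordering (slow diffusion needs more time)
  still holds and is tested; the *envelope* of the bracket, however, is too
  narrow to serve as a coverage interval for a mid-bracket truth, and is
  documented as such rather than asserted.

# The heat model and hydrate stability

Heat conduction uses the same Crank–Nicolson kernel with bulk diffusivity
$\kappa$ in place of $D_s$, the bottom-water forcing imposed at the
seafloor interface, and a fixed geothermal gradient (0.044 °C m$^{-1}$) at
the base, so the unperturbed geotherm is an exact steady state of the
discrete scheme.  The seasonal forcing defaults to mean 1.25 °C and
amplitude 3.25 °C (the historical range is roughly −1.8 to 4.6 °C with
occasional anomalies to 5.5 °C; neither published range is symmetric about
the stated mean, so the mean anchors the default and the amplitude is
exposed in the configuration).  The forcing phase puts the maximum in early
September.  Warming scenarios add 0.033 °C yr$^{-1}$ for 30 years (fast,
~1 °C total) or 0.005 °C yr$^{-1}$ for 300 years (slow, 1.5 °C).

$\kappa$ defaults to the pinned bulk value 33.4273 m$^2$ yr$^{-1}$
(`kappa_mode = "paper_constant"`).  A `"computed"` mode offers a
geometric-mean conductivity with volume-weighted volumetric heat capacity
from the constituent properties ($\lambda_w = 0.56$, $\lambda_s = 8.05$ W
m$^{-1}$ K$^{-1}$; $C_w = 4.2$, $C_s = 0.73$ J g$^{-1}$ K$^{-1}$; $\rho_w =
1.03\times10^6$, $\rho_s = 2.60\times10^6$ g m$^{-3}$); no standard mixing
law of these constituents reproduces the pinned constant, so the computed
mode is clearly labelled as not doing so, and it is validated only against
its single-phase limits.

The phase boundary is a published seawater correlation for structure-I
methane hydrate ($1/T = 3.79\times10^{-3} - 2.83\times10^{-4}\log_{10}P$,
$T$ in K, $P$ in MPa), linearized over the column under the hydrostatic
convention $P(z) = 0.101325 + 0.0101\,(\text{water depth} + z)$ MPa and
re-anchored so that $T_{eq}(60\ \mathrm{mbsf}) = 4.05$ °C exactly — the
only printed boundary point, which controls the headline stability results.
Dissolved-methane solubility at hydrate equilibrium is Henry's law (the
standard oceanographic Bunsen fit for methane in seawater) evaluated at the
correlation's dissociation pressure; gas-phase fugacity is treated as ideal
by default, the usual simplification in diagenetic modelling at a few MPa
(a second-virial correction is available via `fugacity = "virial"`), and
`solubility_mode = "paper_constant"` pins the value to 64 mol m$^{-3}$.

Because the geotherm (0.044 °C m$^{-1}$) is steeper than the boundary slope
(~0.022 °C m$^{-1}$), the stability margin narrows toward the GHSZ base —
that is what makes 60 mbsf the base of the stability zone.  Two
consequences are worth noting.  The anchored-linearized boundary sits ~0.3
°C below the correlation's raw seafloor value, so seasonal destabilization
depths shift accordingly relative to the thermodynamic-engine figures they
emulate (the package's seasonal runs destabilize the top ~2–3 m, versus a
printed 1.65 mbsf); the comparison is therefore asserted qualitatively.
And under uniform warming the *base* of the column destabilizes before
mid-column does, so "deeper cells destabilize last" is not a valid
invariant of this geometry; the tested property is that the destabilized
set only grows under monotone warming.

# The scenario-screening network

`run_scenario()` integrates a deliberately simplified kinetic network — not
a thermodynamic-database reactive-transport engine — on a 3-m column (200
cells over the top 2 m plus a 1-m methane-generator cell; porosity 0.7;
formation-factor 1.5 diffusivity correction; sedimentation
$3.4\times10^{-4}$ m yr$^{-1}$; 1.3 °C).  The free-energy "hydrogen
currency" coupling of the full engines is replaced by Monod rate laws with
the two inhibition thresholds that matter observationally: sulfate
reduction stops where dissolved Fe$^{2+}$ exceeds 0.4 µM (porewater basis),
and methanogenesis stops where sulfate exceeds 0.4 mol m$^{-3}$.  Organic
matter degrades in two steps (hydrolysis to a glucose equivalent, then
fermentation to acetate + H$_2$), ammonium is released at the Redfield N:C
ratio, AOM couples methane to sulfate, Fe-oxyhydroxide reduction and slow
goethite dissolution source Fe$^{2+}$, Mg-calcite (0.9 Ca : 0.1 Mg)
precipitates above an alkalinity threshold, and the iron-sulfide sink is
modelled as FeS-equivalent (Fe$^{2+}$ + HS$^-$ → FeS + H$^+$), the pyrite
precursor: a balanced FeS$_2$ + H$_2$ pathway closes an autocatalytic
H$_2$–iron loop that is kinetically unconstrained and numerically
explosive, so the simpler sink is used and documented.  Alkalinity is a
transported pseudo-solute updated by reaction stoichiometry; no pH or
carbonate speciation is attempted because the constraining data are TA
profiles.

Explicit kinetics are protected by stoichiometric availability limiting:
when a pool would be driven negative within a step, every reaction
consuming it is scaled down as a whole, so elemental balance (S, Fe, Ca,
Mg, N) is preserved exactly; the tests assert closed-box conservation to
$10^{-6}$.

The five screening scenarios follow the published durations (0.25, 0.5,
900, 2.5 and 0.7 years) and perturbations: seawater intrusion at 1 m
yr$^{-1}$ (Scen1), a homogenized oxidized surface layer (Scen2), a 0.275-m
porosity-0.5 cap (Scen3 — note that 900 years of deposition at the stated
sedimentation rate would give 0.306 m; the cap thickness is set to the
printed 0.275 m directly), an elevated methane source (Scen4), and upward
advection plus a strong source (Scen5).  Scen4 starts from a weak-seepage
(deep-SMTZ) state, since a kink can only be imprinted on a smooth,
near-seawater background; the other scenarios start from an active-seep
state with an SMTZ at 1.6 mbsf.  Each scenario is judged against an
unperturbed control run from the same initial state.  Rate constants
default to values at which the elevated methane flux deflects the profiles
within its 2.5-year window; all are exposed in `reaction_network()`.

The discriminating signature — a kinked sulfate profile with ammonium
unchanged (within 5% of control) and dissolved iron elevated only in the
surface layer — is produced by Scen4 and only Scen4; Scen1 dilutes
ammonium, Scen2 smooths the kink away and spreads iron through the
homogenized layer, Scen3 produces the opposite (concave-down) curvature
below its cap, and Scen5 produces S-shaped sulfate with concave-down
calcium.  In this implementation the concave-down signature of Scen3 is
carried most cleanly by calcium: at quasi-steady state the sulfate between
cap and SMTZ is nearly linear because AOM is front-localized, while the
cation drawdown toward the deep carbonate sink retains the curvature.
Shape labels follow the field's depth-down plotting convention:
"concave-up" profiles are flat near the seafloor and steepen with depth
($d^2C/dz^2 < 0$), the kink-type family; "concave-down" is the reverse.

# Numerical choices

* Crank–Nicolson in time, centred second-order finite volumes in space;
  fixed-value boundaries are imposed at the interfaces by ghost cells, not
  at the first cell centre; interface conductances use harmonic means, so
  porosity contrasts (the Scen3 cap) are handled conservatively.
* Operator splitting is diffusion → advection → kinetics, keeping the
  linear solves tridiagonal and the reactions explicit.
* Advection is first-order upwind with a hard CFL check (`|v| dt <= dx`);
  callers sub-step.
* Negative-concentration undershoots are clipped to zero and counted
  (`clip_count` / `clip_events`), a test surface rather than a silent fix;
  in the reduced model the AOM decrement is additionally capped by both
  pools so the 1:1 stoichiometry is exact even at sharp fronts.
* Problem sizes used by the test-suite studies: the Monte-Carlo recovery
  study runs 50 noise replicates of the default synthetic core (2400-cell
  column, dt = 0.01 yr) at matched tortuosity, with the tortuosity-ordering
  property checked on 8 replicates at both bracket ends; the heat
  benchmarks use 12-year seasonal runs; the scenario suite runs all five
  scenarios once, with controls where the discrimination needs them.
* Seeds: every stochastic step (noise, replicate ensembles, CLI runs) is
  seeded explicitly; generators are bit-reproducible under a fixed seed.

# Known limitations

* The reduced model has no gas phase: emplaced dissolved methane below the
  gas front can sag below the solubility ceiling, where in reality free gas
  would buffer it; the modelled saturation depth is therefore a lower bound
  on dissolved methane, and the hydrate-depth datum is used directly as the
  emplacement depth instead.
* Onset dating assumes the hydrate/gas-front depth is observed.  Without
  that datum the gas front falls back to the spun-up SMTZ depth, which is
  only appropriate for near-steady systems.
* The scenario network is qualitative by design; its rate constants are
  tuned to reproduce the discrimination pattern, not any site's
  concentrations, and carbon is not closed (CO$_2$/DIC is untracked, TA
  carries the stoichiometric bookkeeping).
* The thermal model is pure conduction with a threshold test; latent heat
  of dissociation and feedbacks of dissociation on temperature are out of
  scope.
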