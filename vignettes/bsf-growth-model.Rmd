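---
title: "Modelling black soldier fly larval growth and development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling black soldier fly larval growth and development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsfgrow)
```

## The model

Larvae of *Hermetia illucens* (the black soldier fly, BSF) are reared on
organic substrates for feed protein and waste valorization. Production
decisions — feeding regime, climate control, harvest timing — hinge on two
quantities this package models jointly: the larval **dry mass** `B_dry` (g
per larva) and a **development sum** `T_sum` (h), an "apparent age" that
counts hours of suitable growing conditions and generalizes degree-days to
several environmental factors at once.

The state equations are a regulated mass balance and a regulated clock:

$$\frac{dB_{dry}}{dt} = \epsilon_{inges}\, r_{assim}\, k_{inges} B_{dry}
  \;-\; r_{mat}\, k_{maint} B_{dry},
\qquad
\frac{dT_\Sigma}{dt} = r_{dev}\, k_{devts}.$$

`k_inges` and `k_maint` are the specific maximum ingestion and combined
maturity-plus-maintenance rates (g g⁻¹ s⁻¹); `epsilon_inges` is the
digestion efficiency. The ingested flux partitions into an excreted
fraction `k_alpha_excr`, a digestion cost `k_alpha_assim`, and the
effective assimilate flux that funds growth and maintenance
(`flux_partition()` reports all six fluxes and conserves the ingested mass
exactly). Maturity and maintenance are combined into a single drain because
the two expenditures cannot be separated by mass measurements and are
active together throughout the larval phase.

The three **regulators** are products of normalized factors in `[0, 1]`,
so any single exhausted resource throttles the corresponding process:

* `r_assim` — stage factor × temperature × feed (growth Monod) × moisture ×
  airflow;
* `r_mat` — stage factor × temperature × feed × airflow (moisture does not
  limit maintenance metabolism);
* `r_dev` — temperature × feed (development Monod) × moisture × airflow,
  independent of the larval state.

### Environmental rate functions

* **Temperature**: two interchangeable thermal performance curves. An
  Arrhenius response with low/high boundary corrections
  (`arrhenius_rate()`), and a modified Logan-10 curve (`logan10_rate()`)
  whose high-temperature branch decays to zero instead of going negative.
  The Logan-10 form is the default inside the regulators
  (`profile$temperature_model`) as it fits rearing data with one fewer
  parameter; the Arrhenius alternative is normalized by its numerically
  located maximum, cached on the profile.
* **Feed density** (g dry feed d⁻¹ per larva): Monod (type-II) saturation,
  with separate instances for development (`k_B_half_dm`) and growth
  (`k_B_half_gm`) — development saturates at much lower rations than
  growth.
* **Moisture** (kg water per kg wet substrate): a product of two piecewise
  factors — assimilation impossible below `k_W_med_C1` (dry feed cannot be
  ingested), ramping to full above `k_W_med_C2`; respiration unconstrained
  below `k_W_med_C3` and ceasing at `k_W_med_crit`, where larvae drown.
* **Airflow** (l min⁻¹): Monod saturation by default; the logistic
  alternative (`airflow_logistic_rate()`) is implemented exactly as
  written, which means it *decreases* with airflow unless the transition
  parameter `k_A_trans` is negative. Because no fitted values ship for the
  logistic form, it is optional in profiles and the caller owns the sign
  convention.

### Stage regulation

Three development-sum milestones structure the life cycle: assimilation is
fully open until `k_T_sum_1`, ramps to zero at `k_T_sum_2` (the larva stops
feeding as its mouth parts change before pupariation), and maturity
allocation stops at `k_T_sum_3` (end of the prepupal stage — after which
the model holds the mass constant; pupal metamorphosis is out of scope).
Ingestion is additionally throttled by `1 - B_dry / k_B_asy`, the feeding
potential relative to the asymptotic dry mass, floored at zero — a larva
at its asymptotic size cannot assimilate regardless of stage.

### Smoothed switching

All piecewise switches are replaced inside the ODE by logistic transitions
(`smooth_step()`), both because biological transitions are gradual and
because a differentiable right-hand side is what adaptive solvers need.
The package-wide convention is slope `k = 4 / width` with the midpoint at
the ramp centre, which matches the ramp's own slope at its midpoint. The
consequences are fixed by construction: the smoothed switch deviates from
the piecewise form by `1/(1+e²) ≈ 0.119` at the ramp endpoints and by
`1/(1+e⁶) ≈ 0.0025` one full ramp-width outside — the acceptance suite
checks exactly these bands. The maturity switch at `k_T_sum_3` has zero
ramp width, so a smoothing width must be chosen: `w_mat = 10` h by default
(about 3 % of the development span, wide enough not to stall the solver,
narrow against every stage interval), configurable in `stage_params()`.

## Parameters

Two profiles ship with the package (`load_profile()`):
`"table3_original"`, the published estimates obtained from pooled
normalized literature sweeps, and `"table3_recalibrated_D1D5"`, the
variant whose feed half-saturations (`k_B_half_dm` 0.0137, `k_B_half_gm`
0.0717 g d⁻¹) were re-estimated on a two-trajectory subset after a feed
change; the latter is the default for trajectory work. Three constants
have no published value and carry package defaults: `k_r_max_W = 1`
(normalized; it cancels in every regulator), `k_dev_ts = 1/3600` h s⁻¹
(apparent age advances one hour per real hour under optimal conditions),
and the smoothing width `w_mat` above.

One stored inconsistency is deliberate: the published digestion efficiency
(`epsilon_inges = 0.79`) contradicts the value implied by the published
partition fractions, `1 - k_alpha_excr - k_alpha_assim = 0.2103`. The
profile keeps `epsilon_inges` as an independent parameter and flags the
disagreement (`epsilon_consistent = FALSE`); passing
`epsilon_inges = NULL` to `growth_params()` selects the strict
mass-balance mode in which it is derived from the fractions.

## Simulation

`simulate_larva()` integrates the two ODEs with an adaptive Dormand–Prince
4(5) scheme (`deSolve`), at `rtol = 1e-8`, `atol = 1e-12` g — strict
because regulator products span orders of magnitude near switches and
trajectories can traverse many e-folds of mass. Environment schedules are
held constant between samples (experiments hold conditions piecewise
constant); linear interpolation is available. Milestone crossings are
located by root-finding on a monotone interpolant of `T_sum(t)`, well
below 0.01 h resolution.

**Peak-event semantics.** With the shipped rates, any constant environment
drives the dry mass to a quasi-equilibrium near its stage-adjusted
asymptote long before the first milestone: the ratio of time-to-asymptote
to time-to-milestone depends only on the two feed half-saturations and is
bounded near 0.26. The trajectory then sits within solver accuracy of its
maximum for hundreds of hours, and under smoothed switches the logistic
tails let the literal argmax drift far ahead of the visible decline. The
reported `B_dry_peak` therefore resolves ties within a relative tolerance
(`1e-6`, about the integration accuracy) to the *latest* attaining time —
the shoulder where the maturation decline begins, which is the
biologically meaningful harvest point. The exact stage structure (peak
strictly between the first and third milestone crossings, flat plateau
after the third) is realized by the piecewise switching mode
(`smooth = FALSE`), which the acceptance suite uses for that check.

## Estimation workflow

Static sweeps follow the five-step calibration pattern: convert
development times to rates (`development_time_to_rate()`), normalize each
dataset by its observed maximum (`normalize_dataset()`), pool datasets
that vary the same factor (`group_datasets()`; pointwise averaging over a
common grid is available as an alternative reading of "averaged"
datasets), fit the pooled normalized data (`fit_static()`), and map the
fitted maximum-rate parameters back to the observed scale
(`rescale_to_observed()`).

`fit_static()` and `fit_dynamic()` minimise unweighted squared residuals
with bounded Levenberg–Marquardt (`minpack.lm`) from a stratified
multi-start: the first start is the current parameter set (shipped
defaults, or the profile under calibration), the rest a seeded
Latin-hypercube sample of the bound box, log-spaced for parameters
spanning decades. The best converged start by RSS wins; everything is
bit-reproducible given the seed. Default bounds are generous boxes per
model (temperatures within physically sensible ranges, fractions in
`[0, 1]`, dynamic parameters within a factor 5 of their current value)
and can be overridden.

**Identifiability anchors.** Two thermal parameters are fixed rather than
fitted by default, on structural grounds. In the Arrhenius model the
reference temperature is exactly redundant with the reference rate, and
the boundary-correction pairs move the response by a fraction of typical
observation noise over a 10–42 °C sweep, so the default free set is
`{k_r_ref_T, k_T_A}`. In the Logan-10 model the lower threshold
`k_T_base` enters the response only through
`k_gamma · exp(k_rho_T · k_T_base)`, so fitting it jointly with
`k_r_base_T` is rank-deficient; the threshold is an anchor and the base
rate is estimated at it. Any parameter can still be freed explicitly.

Dynamic fits compare simulated and observed dry mass only (the measured
quantity in trajectory datasets); the development sum is latent.
`calibrate_subset()` wraps the joint fit to produce a named profile
variant with only the masked parameters changed — the workflow used to
carry the model to a new feed type by re-estimating the two feed
half-saturations on a data subset.

## Synthetic data

The generators in `generate_response_dataset()`,
`generate_trajectory_dataset()` and `make_fixture_suite()` emulate the
*shape* of the calibration data classes — temperature, feed, moisture and
airflow sweeps, and dry-mass trajectories under different feeding rates —
by sampling the model and adding seeded observation noise (Gaussian, 5 %
of the response maximum by default, truncated at zero; a
fraction-of-maximum noise model matches the normalized fitting workflow).
Default grids mirror the literature ranges: temperature 10–42 °C and
moisture 0.10–0.95 uniformly, as in the source experiments; feed
(0–0.2 g d⁻¹) and airflow (0–3 l min⁻¹) as geometric series plus a zero
point, the standard design for saturating dose–response curves whose
half-saturation lies decades below the range maximum. Trajectories start
at 2 mg dry mass, the weight of the ~8-day-old neonates used to seed
rearing experiments. What passing recovery tests show is therefore
*self-consistency* — the estimation machinery finds the parameters that
generated model-shaped data. They do not show that real rearing data
satisfy the model's assumptions (single pooled maintenance pool, no
substrate depletion, instantaneous environmental response).

## Numerical choices, in one place

* Exponential arguments are capped at ±700 before `exp()`: every rate
  function is finite for any representable temperature.
* The Monod response is evaluated as `r_max / (1 + k_half/x)` so the
  half-saturation identity `monod_rate(k_half) = r_max/2` is exact in
  floating point.
* Inside fitting objectives, candidate parameter vectors are written into
  the profile without validation; out-of-order candidates (for example
  crossed moisture thresholds) evaluate finitely and lose on residual
  value rather than crashing a start. Failed integrations mark that start
  failed; remaining starts continue.
* Fitting-loop simulations use `lsoda` at the same tolerances (it agrees
  with the Dormand–Prince default to ~1e-10 relative and is several times
  faster); reported trajectories use the default solver.
* Profile files store numerics as text with 17 significant digits: YAML
  round trips are lossless.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script runs use deliberately desk-scale
problems: sweeps of 30–50 points, 20-replicate noise studies, single
trajectories of 600–800 h sampled every 12 h, and multi-starts of 4–16
points. These sizes make every check reproducible in seconds while leaving
the recovery tolerances (1e-4 noiseless, 1–10 % noisy/dynamic) meaningful.

## Known limitations

* Substrate depletion, substrate water/heat balance, gas concentrations
  and wet mass are not modelled; feed density is an exogenous driver, and
  the flux outputs let callers do their own substrate bookkeeping.
* Pupal and adult stages are outside the model: after `k_T_sum_3` the
  maturity drain is zero and the mass plateaus.
* The joint recovery of all five free Logan-10 parameters to within 10 %
  from 5 %-noise sweeps of 50 points is not statistically achievable —
  the per-parameter sampling deviations of the shape parameters are
  themselves of order 6–9 % under those conditions, so the corresponding
  stochastic acceptance check documents a failure rate rather than a
  defect in the optimizer. The curve itself, as opposed to its
  parameters, is recovered with high fidelity (see the R² checks).
* Population-level effects (density, mortality, microbiome) are out of
  scope; the state is one average larva.
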