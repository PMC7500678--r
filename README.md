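# bsfgrow

Dynamic growth and development modelling of black soldier fly
(*Hermetia illucens*) larvae.

BSF larvae are reared at industrial scale on organic substrates for feed
protein and waste valorization. Planning a rearing process — feeding
regime, climate set points, harvest timing — needs a model that predicts
both *how much* larval biomass accumulates and *where in the life cycle*
the animals are, under conditions that change over time. `bsfgrow` is for
rearing engineers, process modellers and insect scientists who need such
a simulator and the machinery to calibrate it against their own data.

## The model

Two coupled states: dry mass per larva `B_dry` (g) and a development sum
`T_Σ` (h) — an apparent age counting hours of suitable growing
conditions, generalizing degree-days to several environmental factors:

    dB_dry/dt = ε_inges · r_assim · k_inges · B_dry − r_mat · k_maint · B_dry
    dT_Σ/dt   = r_dev · k_devts

The regulators `r_assim`, `r_mat`, `r_dev` ∈ [0, 1] are products of
normalized single-factor responses:

* temperature — Arrhenius with boundary corrections, or a modified
  Logan-10 thermal performance curve that decays to zero (instead of
  going negative) above the lethal maximum;
* feed density — Monod (type-II) saturation, with separate half-saturation
  constants for development and growth;
* substrate moisture — piecewise ramps between four thresholds
  (ingestibility, optimum plateau, oxygen-diffusion decline, drowning);
* airflow — Monod saturation (a logistic alternative is included);
* development stage — assimilation shuts down between the milestones
  `k_TΣ1` and `k_TΣ2`, maturity allocation stops at `k_TΣ3`, and ingestion
  is throttled by `1 − B_dry/k_B_asy` towards the asymptotic mass.

Inside the ODE all switches are smoothed logistically (slope = 4/width).
Published parameter estimates ship as two named profiles. Multi-start
bounded Levenberg–Marquardt fitting, dataset normalization/pooling,
subset recalibration, seeded synthetic-data generators and a small CLI
complete the toolkit.

## Worked example

Simulate a full larval cycle under constant favourable conditions with a
moderate ration of 0.05 g dry feed per day per larva:

```r
library(bsfgrow)
prof <- load_profile("table3_recalibrated_D1D5")
env  <- reference_env(prof, B_feed = 0.05)   # 31.3 degC, moisture 0.725, 2 l/min
traj <- simulate_larva(prof, env, t_end_h = 700)
traj
#> <larva_trajectory> profile: table3_recalibrated_D1D5 (smoothed switches)
#>   1401 points over 700.0 h; final B_dry 0.07028 g, final T_sum 395.8 h
#>   events:
#>     k_T_sum_1    t =   414.46 h  (value 234.3)
#>     k_T_sum_2    t =   469.55 h  (value 265.5)
#>     k_T_sum_3    t =   526.14 h  (value 297.5)
#>     B_dry_peak   t =   298.50 h  (value 0.1093)
```

Reading the events: the larva peaks at 109 mg dry mass around 300 h,
feeding stops as the development sum passes the second milestone
(~470 h), and development completes at 526 h — after which the mass has
dropped to 70 mg (assimilates burned during the prepupal transition) and
stays flat. `traj$data` holds the state, the three regulators and the
six-component flux breakdown on the output grid; `write_trajectory()`
exports both tables as CSV.

Generate a noisy synthetic feeding sweep and recover the growth response:

```r
ds  <- generate_response_dataset("monod_grw", load_profile("table3_original"),
                                 n = 50, noise = noise_spec("gaussian", 0.05),
                                 seed = 8)
fit <- fit_static(ds, "monod_grw", n_starts = 8, seed = 1)
fit
#> <fit_result> model monod_grw on monod_grw (50 points)
#>   RSS 0.3207 | R^2 0.9821 | best start 6 of 8 (8 converged)
#>  k_r_max_gm k_B_half_gm
#>  2.06974000  0.00587207
```

The generating values were `k_r_max_gm = 2` and `k_B_half_gm = 0.00532`;
with 5 % observation noise over 50 points both come back within a few
percent, and the fit explains 98 % of the response variance.

The same operations are available from a shell via the bundled CLI:

```sh
bsfgrow simulate --temp 31 --feed 0.05 --moisture 0.72 --airflow 2 \
        --t-end 700 --out traj.csv --events-out events.csv
bsfgrow evaluate --model monod_dev --at 0.0137    # prints the half rate
```

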