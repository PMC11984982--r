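# protestdyn

Compartmental modelling of street-protest dynamics under policing: forward
simulation, inverse-problem parameter estimation from mixed participant and
arrest observations, sensitivity/identifiability analysis, and
counterfactual policing scenarios, with a synthetic-data generator so the
whole pipeline is testable end to end.

## The science

Repeated mass protests behave like behavioural epidemics. `protestdyn`
models a closed adult population split into susceptibles *S*, novice
protesters *I*, experienced protesters *C*, retired participants *R* and
detainees *D*:

    dS/dt = -β₁SI - β₂SC + γR
    dI/dt =  β₁SI + β₂SC - χI - δ₁I - ε₁(t)I
    dC/dt =  χI - C·ω(I+C) - ε₂(t)C
    dR/dt =  δ₁I + C·ω(I+C) - γR + ε₃D
    dD/dt =  ε₁(t)I + ε₂(t)C - ε₃D

with the collective withdrawal law

    ω(N) = δ₂ + (δ₁ - δ₂) · C₀ⁿ / (Nⁿ + C₀ⁿ),   N = I + C,

a decreasing Hill function of crowd size: a large movement retains its
experienced core (ω → δ₂), a shrinking one loses it at an accelerating rate
(ω → δ₁), which is what terminates a wave without exhausting the population.
Policing enters as piecewise-constant detention rates ε₁(t), ε₂(t) — long
weak phases interrupted by short active phases — and the model carries the
cumulative detention flux A(t) so that arrest records ("8,700 arrested
between days 1–126", "1,500 on day 21") can be compared with A(b) − A(a).

The package provides:

* `simulate_protests()` — compiled adaptive Dormand–Prince 5(4) integration,
  exact at schedule breakpoints, plus observables `participants()`,
  `arrests_in_window()`, `protest_duration()`;
* `fit_protests()` — deterministic seeded estimation of the structural
  parameters from participant counts and mixed-dialect arrest records
  (relative least squares; local Levenberg–Marquardt/Nelder–Mead cascade
  with a differential-evolution global stage);
* `sensitivity_matrix()` and `orthogonal_rank()` — semi-relative
  sensitivities qⱼ·∂f/∂qⱼ and the greedy orthogonal identifiability
  ranking with per-iteration perpendicular norms;
* `no_policing()`, `scale_active_phase()`, `add_active_phase()`,
  `sustained_increase()`, `summarize_trajectory()` — counterfactual
  policing experiments;
* `generate_observations()` / `yvm_fixture()` — synthetic weekly protest
  waves with lognormal noise from a documented reference parameter set;
* `run_command()` and the `exec/protestdyn` script — a thin CLI
  (`synth | simulate | fit | sense | rank | scenario`) writing CSV
  artifacts plus a JSON run manifest.

## Worked example

```r
library(protestdyn)

p <- reference_params()
init <- initial_state(55.5e6, 288000)   # 55.5M adults, 288k first-day protesters
traj <- simulate_protests(p, init, t_end = 260)
traj
#> Protest trajectory: 261 time points on [0, 260] days
#>   participants: start 288000, peak 288000 (day 0), end 1
#>   cumulative arrests at end: 80764

summarize_trajectory(traj)
#> Scenario summary: peak 288000 protesters on day 0, duration 218 days,
#>   2.784e+07 person-days, 80764 total arrests
```

The wave starts at its first-day maximum, dips into a trough in weeks 5–8
after the day-21 active policing phase, partially rebounds, and terminates
(fewer than 1,000 participants) after 218 days. Removing policing roughly
doubles the duration, and the wave then overshoots its first-day size — a
rebound to a higher secondary peak:

```r
summarize_trajectory(simulate_protests(no_policing(p), init, 600))
#> Scenario summary: peak 303179 protesters on day 158, duration 427 days,
#>   9.693e+07 person-days, 0 total arrests
```

Parameter recovery from a synthetic weekly dataset:

```r
ds  <- yvm_fixture(seed = 1)                  # 33 weekly counts + 3 arrest records
cfg <- fit_config(reference_params(), seed = 1)
fit <- fit_protests(ds$obs, init, cfg)
fit$objective                                 # 3.3e-07: recovery to the rounding floor
round(fit$par / unlist(reference_params()[names(fit$par)]) - 1, 4)
#>   beta1   beta2     chi       n      c0  delta1  delta2
#> -0.0002  0.0006  0.0003  0.0004  0.0003 -0.0001  0.0016
```

Identifiability at the reference set:

```r
orthogonal_rank(sensitivity_matrix(p, init, seq(7, 224, 7)))
#> Identifiability ranking (most -> least identifiable):
#>    1. delta1   |perp| = 1.01885e+08
#>    ...
#>    9. eps1     |perp| = 23.1033
```

δ₁ (novice withdrawal) is by far the best-identified parameter and the
weak-phase detention rates the worst — seven decades apart — matching the
qualitative identifiability picture such models show.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch: generates the weekly fixture from the
reference parameters, re-estimates the structural parameters from it,
computes the sensitivity matrix and identifiability ranking at the fitted
values, and runs the no-policing and sustained-increase scenarios, then
writes the acceptance JSON to `--out`. All randomness derives from
`--seed`.
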