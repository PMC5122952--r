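# isoforage

Dual-tracer classification of coastal and oceanic foraging strategies in
post-nesting sea turtles: satellite telemetry labels a tracked training
cohort, and skin stable isotopes (δ¹³C, δ¹⁵N) assign everyone else.

## The problem

Female sea turtles nesting on one beach can disperse to radically different
foraging habitats — shallow productive shelf waters or the open ocean. Only
a handful of animals ever carry a satellite tag, so the population-level
split between strategies is invisible to telemetry alone. Skin δ¹³C,
however, records the carbon source of the foraging ground (nearshore food
webs are ¹³C-enriched relative to pelagic ones), and it can be sampled from
every nesting female. This package implements the combined design, for
movement ecologists and conservation planners who need population-level
foraging proportions from a small tracked cohort plus a large isotope
screen:

1. **Tracks** — Argos fixes are cleaned with a 240 km d⁻¹ maximum-speed
   filter and a best-location-class-per-day rule; gap days are interpolated
   by a Bayesian first-difference correlated random walk (DCRW) fitted by
   MCMC,

   x_t = x_{t−1} + γ·T(θ)(x_{t−1} − x_{t−2}) + ε_t, ε_t ~ N(0, σ²I),

   with Student-t observation error scaled per Argos location class.
   Residence behaviour (daily speed < 5 km d⁻¹ sustained ≥ 15 d) in water
   shallower than the 50 m isobath inside the coastal polygon labels a
   tracked animal **coastal**; otherwise it is **oceanic**.
2. **Isotopes** — δ notation δX = (R_sample/R_standard − 1)·10³, replicate
   QC by pooled within-individual σ, and per-individual aggregation.
3. **Assignment** — MANOVA (Pillai's trace) confirms group separation;
   a two-class linear discriminant (class means, pooled covariance, equal
   priors) trained on the tracked cohort assigns each untracked individual
   wherever its posterior exceeds 0.80 (strictly), validated by jackknife
   (leave-one-out) cross-validation; population proportions use half-up
   integer percentages, and (1 − p)ⁿ bounds the chance that n independently
   tracked animals would all miss the coastal strategy.
4. **Synthetic studies** — a generator fabricates complete studies (tracks
   with Argos-class noise, bimodal δ¹³C mixtures, schematic shelf/basin
   geography) with known truth, so the whole pipeline is testable without
   any field data.

See `vignettes/dual-tracer-foraging.Rmd` for the model details and design
rationale.

## Worked example

```r
library(isoforage)

study  <- simulate_study(synthetic_config(), seed = 7)   # 16 tracked + 80 untracked
report <- run_analysis(
  study,
  pipeline_params(ssm = ssm_config(n_iter = 5000, burn_in = 2000)),
  seed = 11
)
print(report)
```

```
Dual-tracer foraging analysis
  tracked: 16 animals (8 coastal, 8 oceanic by telemetry)
  modelled daily positions: 4.7%
MANOVA (Pillai): V = 0.8399, F(2, 13) = 34.092, p = 6.747e-06
  jackknife: 15/16 correct (94%)
Assignment of 80 untracked individuals (16 tracked in training):
  coastal     42 (53%)
  oceanic     31 (39%)
  unassigned   7 (9%)
  P(none of 9 prior-tracked coastal | p = 0.575) = 4.49e-04
```

Reading the output: all 16 tracked animals were classified by telemetry
(here recovering the generator's 8/8 truth exactly); 4.7% of daily positions
came from the state-space model rather than a raw fix; the MANOVA confirms
the two telemetry groups differ in isotope space; the jackknife estimates
out-of-sample assignment accuracy; and of the 80 untracked animals, 73
cleared the 80% posterior rule (42 coastal, 31 oceanic — an assigned coastal
fraction of 0.58 against a true simulated fraction of 0.5) while 7 stayed
unassigned. The final line is the binomial probability that nine
independently tracked turtles would all have missed the coastal habitat if
the assigned coastal fraction were the truth.

Individual stages are plain functions — `speed_filter()`,
`best_daily_fix()`, `fit_ssm()`, `merge_daily()`, `classify_strategy()`,
`aggregate_individuals()`, `lda_train()`, `jackknife_cv()`,
`proportion_report()` — and `write_study_bundle()` /
`read_study_bundle()` exchange all inputs as plain CSV/GeoJSON.

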