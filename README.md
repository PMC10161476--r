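# hrvbeta

Tools for studying whether worse cardiac autonomic function — measured as
lower 24-hour heart rate variability (HRV) — is associated with worse
beta-cell response to a glycemic load, the way a population-based
epidemiological analysis would do it: per-subject metric extraction,
composite scoring, and a covariate-adjusted regression ladder, exercised on
calibrated synthetic cohorts.

The package is for biostatisticians and physiologists who want a tested,
reproducible reference implementation of this analysis chain:

* **HRV** (`beat_series`, `extract_nn`, `hrv_profile`, `hrv_composites`) —
  NN-interval extraction from labelled beats with non-sinus exclusion, the
  Task-Force time-domain indices (SDNN, SDANN, RMSSD, SDNN index, NN50,
  pNN50, SDSD), full-record FFT band powers (TP, ULF, VLF, LF, HF), the
  18-h minimum-duration rule, and per-domain composite z-scores
  ([SDNN + RMSSD + SDANN + SDNN index + pNN50]/5 and
  [TP + ULF + VLF + LF + HF]/5).
* **Beta-cell response** (`fit_betacell`, `forward_simulate_ogtt`,
  `deconvolve_isr`, `cpeptidogenic_index`, `overall_insulin_secretion`,
  `matsuda_index`, `betacell_composite`) — a C-peptide based secretion
  model fitted through Van Cauter-type two-compartment kinetics,

      ISR(t) = P(t) [b0 + s (G(t) − G_b)] + r (dG/dt)+ ,

  with glucose sensitivity `s` (the dose-response slope,
  pmol min⁻¹ m⁻² mM⁻¹), rate sensitivity `r` on rising glucose, basal
  secretion `b0`, and a mean-one potentiation factor `P(t)` whose excursion
  is P(120)/P(0); plus the formula-based indices (C-peptidogenic index
  ΔCP₃₀/ΔG₃₀, CP_AUC/G_AUC, Matsuda 10000/√(G₀·I₀·Ḡ·Ī)) and the
  re-standardized five-index composite.
* **Associations** (`run_ladder`, `standardized_fit`, `interaction_test`,
  `stratified_ladder`, `tertile_logistic`) — standardized betas per SD
  *lower* HRV through a cumulative adjustment ladder (crude; +age, sex,
  education; +Matsuda; +lipids, BMI, smoking, alcohol; +blood pressure and
  antihypertensives), with effect-modification tests, stratified ladders
  and a tertile logistic sensitivity analysis.
* **Synthetic cohorts** (`sem_config`, `solve_sem_paths`,
  `draw_cohort_scores`, `synthesize_beat_series`, `synthesize_ogtt`,
  `simulate_cohort`, `run_pipeline`) — a standardized linear-Gaussian
  structural-equation generator whose population crude *and* adjusted
  coefficients are calibrated in closed form, plus a signal-level mode
  emitting raw labelled beat series and OGTT curves.

See `vignettes/methods.Rmd` for the models, assumptions, identifiability
analysis and default parameter rationale.

## Worked example

Fit the secretion model to a noisy synthetic OGTT (truth: glucose
sensitivity 95, rate sensitivity 700, basal secretion 100, flat
potentiation; 4% assay CV):

```r
library(hrvbeta)
kin <- cpeptide_kinetics(age = 60, sex = "M", bmi = 27, gms = "NGM")
rec <- synthesize_ogtt(list(glucose_sensitivity = 95, rate_sensitivity = 700,
                            basal_secretion = 100, potentiation_ratio = 1),
                       gms = "NGM", kinetics = kin, noise_cv = 0.04, seed = 42)
fit <- fit_betacell(rec, kin)
print(fit)
#> Beta-cell secretion model fit (7-point OGTT)
#>   glucose sensitivity:     85.4 pmol/min/m^2/mM
#>   rate sensitivity:       548.4 pmol/m^2/mM
#>   basal secretion:        121.4 pmol/min/m^2
#>   potentiation ratio:      0.95 (P120/P0)
#>   C-peptide RMSE: 26.3 pmol/L; converged
```

The recovered slope (85.4 vs truth 95) is consistent with the recovery
error the test suite measures at this noise level (median well under 15%),
and the flat truth potentiation is recovered as ≈1. Then draw
one calibrated cohort of n = 2,007 and run the ladder for the overall
beta-cell composite:

```r
cohort <- draw_cohort_scores(sem_config(2007, "time", seed = 1))
lad <- run_ladder(cohort, outcomes = "betacell_z")
summary(lad)
#> Fully adjusted (m3b) standardized betas:
#>    exposure    outcome     st_beta         lo          hi           p
#>  hrv_time_z betacell_z -0.07081936 -0.1192022 -0.02243653 0.004140190
#>  hrv_freq_z betacell_z -0.06695962 -0.1140477 -0.01987150 0.005341065
```

A single replicate carries Monte-Carlo noise of about ±0.022 (1 SE); the
generator's population value for the fully adjusted time-domain
coefficient is −0.055, which replicate averaging recovers (below).

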