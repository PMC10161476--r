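---
title: "Autonomic function and beta-cell response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autonomic function and beta-cell response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvbeta)
```

## Scope

`hrvbeta` implements an analysis chain linking 24-hour cardiac autonomic
function, measured as heart rate variability (HRV) from labelled beat
series, to beta-cell response during a seven-point oral glucose tolerance
test (OGTT), together with a calibrated synthetic cohort generator that
reproduces the statistical structure such an epidemiological analysis
assumes. The chain has four scientific layers: HRV metric extraction,
beta-cell response modelling, composite scoring, and a standardized-beta
covariate-adjustment ladder. Everything runs on synthetic data; no subject
data ships with the package.

## HRV extraction

The input is a beat series: beat times (seconds) with labels sinus (`N`),
ectopic (`E`) or artifact (`A`). An interbeat interval is a normal-to-normal
(NN) interval only when both delimiting beats are sinus; every interval
adjacent to a non-sinus beat is dropped, and retained intervals separated by
a dropped interval belong to different contiguous runs. Successive-difference
statistics (RMSSD, NN50, pNN50, SDSD) are computed within runs only, so they
never span an exclusion gap. Recordings with less than 18 h of retained
sinus data (inclusive boundary: exactly 18 h passes) are excluded.

Time-domain conventions, applied consistently:

* all standard deviations use the sample (n-1) denominator;
* NN50 counts successive pairs with |difference| strictly greater than
  50 ms; nanosecond rounding of intervals protects this boundary from
  floating-point dust in reconstructed beat times;
* pNN50 divides by the total NN-interval count, not the number of
  successive pairs;
* SDANN and the SDNN index use consecutive 5-minute bins of the recording
  clock; SDSD is reported equal to RMSSD.

Frequency-domain analysis resamples the NN tachogram (interval value at
interval onset) to an even 4-Hz grid, mean-centres, applies a Hann window,
and integrates a single full-record FFT periodogram over ULF (0-0.003 Hz),
VLF (0.003-0.04), LF (0.04-0.15), HF (0.15-0.4) and total power (0-0.4),
all half-open `[lo, hi)` bands in ms^2. Welch averaging is deliberately not
used because ULF requires full-record frequency resolution. The periodogram
normalization makes the integral of the one-sided density equal the
windowed variance, so a pure sinusoidal modulation of amplitude A carries
band power A^2/2 (Parseval); the test suite checks this closed form.
Resampling uses cubic-spline interpolation by default: at a 0.25-Hz
modulation sampled at a typical 1.25-Hz beat rate, linear interpolation
attenuates amplitude by the sinc^2 factor (~0.875, i.e. ~23% power loss),
which would corrupt absolute HF power; the cubic-spline transfer is ~0.995
there. Linear interpolation remains selectable (`interp = "linear"`).
Detrending, window and interpolation choices are declared defaults of this
implementation, not reconstructions of any particular proprietary pipeline.

Composites: each index is z-scored against the analysis sample; the
time-domain composite is the mean of the SDNN, RMSSD, SDANN, SDNN-index and
pNN50 z-scores, the frequency-domain composite the mean of the TP, ULF,
VLF, LF and HF z-scores. Skewed indices enter as raw z-scores (no log
transformation), matching the composite definition used for calibration.

## Beta-cell response

Two formula-based indices are computed directly from the 7-point record:
the C-peptidogenic index (CP30 - CP0)/(G30 - G0) and overall insulin
secretion CP_AUC/G_AUC (trapezoid over 0-120 min). A zero glucose
increment makes the C-peptidogenic index undefined (missing); a negative
increment is retained but flagged. The Matsuda index of insulin
sensitivity is 10000/sqrt(G0 * I0 * Gmean * Imean) with glucose in mg/dL
(x 18.016 from mmol/L) and insulin in uU/mL (/ 6.0 from pmol/L), means
taken over all seven samples.

The model-based indices come from a secretion model fitted to C-peptide
through two-compartment kinetics:

    ISR(t) = P(t) * [b0 + s * (G(t) - G_basal)] + r * max(dG/dt, 0)

with `s` the dose-response slope ("glucose sensitivity",
pmol min^-1 m^-2 mM^-1), `r` the rate sensitivity (pmol m^-2 mM^-1) acting
on rising glucose only, `b0` basal secretion, and `P(t)` a positive
time-varying potentiation factor normalized to time-average 1 over the
record, represented on a 20-minute knot grid. The potentiation excursion is
P(120)/P(0). This is a minimal faithful re-implementation of the standard
dose-response/potentiation description, not a clone of any specific
published software; only qualitative agreement with such software can be
asserted. Plasma C-peptide follows from Van Cauter-type population
kinetics: fast fraction 0.76 and fast/slow half-lives 4.95/29.2 min
(4.55/33.5 when obese, 4.52/27.3 in type 2 diabetes), rate constants
derived from the impulse-response algebra, and a distribution volume
proportional to body surface area (2.64 L/m^2, about 5 L for a typical
adult). The forward solution uses exact exponential stepping on a 1-minute
grid; the same kernel drives the regularized non-negative deconvolution of
the secretion rate (`deconvolve_isr`), which minimizes a least-squares
criterion with a curvature penalty plus a small (1%) first-difference term
so that the strong-regularization limit is a constant secretion rate.

### Identifiability and the penalty design

A single 7-point OGTT cannot identify the dose-response slope when the
potentiation curve is fully free: numerically, an alternative slope with a
compensating potentiation tilt reproduces the same C-peptide curve to
within ~0.002%. `fit_betacell` therefore penalizes the curvature and the
tilt of log-potentiation (defaults `lambda_curv = 5`, `lambda_tilt = 100`,
chosen by an L-curve sweep on synthetic records at 4% assay CV), selecting
the flattest potentiation consistent with the data. The penalty weight
scales with the declared C-peptide assay CV (`measurement_cv`, default
0.04), with a small floor for numerical regularity: declaring
`measurement_cv = 0` for noise-free data turns the penalties nearly off, and
records generated with a flat potentiation are then recovered essentially
exactly. The cost of this design is deliberate shrinkage: for subjects
whose true potentiation is strongly tilted the estimated excursion ratio
(and with it the slope) is biased toward the flat representative, while
ranking across subjects is preserved. Recovery oracles in the test suite
are therefore run in the identified regime (flat-potentiation truths); at
4% noise the median absolute relative error of the recovered slope across
50 synthetic subjects is well under 15% with no systematic sign bias.

The overall beta-cell composite z-scores the five indices (C-peptidogenic,
overall secretion, glucose sensitivity, potentiation ratio, rate
sensitivity) on the analysis sample, averages them, and re-standardizes the
mean to mean 0, SD 1. It is computed for complete cases only.

## Association ladder

Associations are standardized betas from ordinary least squares: outcome
and determinant are z-scored on the analysis sample, the determinant is
multiplied by -1 so that coefficients read per SD *lower* HRV, and
covariates enter in a cumulative ladder: crude; model 1 (age, sex,
education); model 2 (+ Matsuda index); model 3A (+ total/HDL cholesterol
ratio, lipid-modifying medication, BMI, smoking, alcohol); model 3B
(+ office systolic blood pressure, antihypertensive medication). One
complete-case row set, computed over the union of all ladder columns, is
shared by every model so the ladder is comparable; z-scoring happens within
that analysis sample. Education, smoking and alcohol are indicator-coded
factors (reference levels: low, never, none). 95% intervals and p-values
come from the usual t distribution; no multiplicity correction is applied.

Effect modification is tested in the fully adjusted model augmented with
modifier-by-determinant *and* modifier-by-covariate interactions; the
reported p is an F test of the determinant interaction (2 df jointly for
the three-level glucose-metabolism modifier). Stratified analyses re-fit
the ladder within each glucose-metabolism stratum, z-scoring on the full
analysis sample so stratum estimates share a scale. Because beta-cell rate
sensitivity is right-skewed, a logistic sensitivity analysis categorizes it
into tertiles (33.3/66.7 sample percentiles; ties that collapse a tertile
are an error) and contrasts the top tertile against the rest by default,
reporting the odds ratio per SD lower HRV. A covariate-swap helper supports
the sensitivity re-analysis that replaces the Matsuda index with total
insulin secretion (C-peptide AUC based).

## Synthetic cohorts

Two fidelity levels share one configuration.

**Score level** (fast; used for the cohort-scale calibration checks): a
standardized linear Gaussian structural-equation model. Mutually
independent standardized confounders C_i (age, Matsuda, BMI, office SBP)
feed the exposure X = sum(a_i C_i) + e_x and each outcome
Y_k = d_k X + sum(b_ki C_i) + e_k; residual SDs are solved, not free, so
every node has unit variance. Closed form: the population crude coefficient
of Y_k on X is d_k + sum(a_i b_ki) and the adjusted coefficient is d_k, so
`solve_sem_paths` calibrates both ends of the ladder exactly — the default
configuration sets every outcome's crude and fully-adjusted values to the
published cohort estimates for that exposure domain (the six-outcome column
of the corresponding results table), with outcome paths b_ki proportional
to a_i supplying each outcome's crude-adjusted gap. Confounders are kept
mutually independent and are standardized by their population moments
precisely so this calibration is exact; correlations between covariates
beyond the modelled confounding (e.g. the joint structure of a real
cohort's covariate table) are deliberately not reproduced. Categorical
covariates (sex, education, smoking, alcohol, medication flags, glucose
metabolism status) are drawn independently with the cohort's marginal
frequencies and act as null covariates in the adjusted models, which leaves
the calibration untouched. Age is a truncated normal on [40, 75] whose
parameters are moment-matched so the realized mean/SD equal 60/8 after
truncation.

**Signal level** (slow; exercises the metric code end-to-end): each
subject's exposure composite drives the amplitudes of an RR-interval
process with circadian (24-h), VLF (0.01 Hz), LF (0.1 Hz) and HF (0.25 Hz)
sinusoidal components plus white beat-to-beat noise (defaults 140/46/26/13
ms and 25 ms, near the magnitudes implied by the cohort's printed band
powers), scaled by max(0.05, 1 + 0.12 * latent); the modest gain keeps the
band powers, which are quadratic in the amplitude scale, nearly linear in
the latent score; a configurable fraction of
beats is labelled ectopic/artifact (defaults 3%/1%). Beat times solve
t[k+1] = t[k] + RR(t[k]) by a vectorized fixed point. The subject's outcome
composite drives beta-cell truth parameters through linear maps around the
cohort-typical values (glucose sensitivity 83, rate sensitivity 724, basal
secretion 100, potentiation ratio 1.63), floored to stay physiologic; the
linear (rather than log-linear) maps keep measured composites nearly linear
in the latent score, which is what makes the signal/score consistency
property (r > 0.99 between computed and drawn composites on noise-free
signals) attainable. OGTT glucose uses fixed piecewise-linear templates per
glucose-metabolism class (editable; no published curves exist for them);
C-peptide is forward-simulated from the truth parameters and multiplied by
lognormal measurement noise at the configured CV, insulin derives from
basal class levels plus a C-peptide-proportional increment with the
prediabetes class highest, and glucose is emitted noise-free as the model's
forcing input. A master seed spawns per-subject (and per-column)
substreams, so subject k is reproducible independent of cohort size.

The signal generator emulates modulation structure, non-sinus
contamination, and secretion dynamics; it does not emulate
non-stationarity, ectopy bursts, apnea-type patterns, circadian asymmetry,
or assay drift, so passing tests demonstrate internal consistency of the
pipeline, not validity on real recordings.

## Study-selection flow

`assemble_cohort` inner-joins the per-subject HRV, beta-cell and covariate
tables and applies exclusions in a declared order — (1) effective HRV
duration < 18 h, (2) OGTT ineligibility (insulin use or fasting glucose
strictly above 11.0 mmol/L), (3) missing analysis values — logging counts
that reconcile exactly (input n - excluded = analysis n). The ordering is a
convention of this implementation.

## Problem sizes and numerical choices

Cohort-scale checks use 20 replicate cohorts of n = 2,007 (the Monte-Carlo
SE of a replicate-averaged standardized beta is then ~0.005, against a
+/-0.012 acceptance band); calibration of interval coverage and interaction
type-I error uses 500 replicates at the same n. Metric-level recovery uses
50 noisy OGTT subjects and 24-h or ~20-h beat series; the signal/score
consistency check uses n = 200 subjects at 24-h recordings (a full circadian cycle, so the sample variance of the circadian component does not depend on its random phase) to keep the
default test run within a few minutes. Degenerate inputs fail loudly:
zero-variance indices in composites, collinear regression designs,
single-level modifiers, tertile-collapsing ties, empty joins and duplicate
ids are all errors, not silent results.

## Known limitations

* The secretion model's potentiation is only weakly identified from 7
  samples; excursion ratios are shrunk toward 1 at realistic noise (see
  above). Comparisons with the original modelling software can only be
  qualitative.
* The SEM cohort reproduces marginals and the calibrated
  exposure-outcome-confounder structure, not the full joint covariate
  distribution of a real cohort.
* HRV synthesis is sinusoid-plus-noise; nonlinear indices and short-term
  (5-min) protocols are out of scope.
* eGFR, blood pressure and lifestyle covariates are simulated directly as
  covariates; no raw-instrument processing is implemented.
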