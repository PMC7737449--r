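---
title: "Modelling emergency-department patient flow as a five-state Markov process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling emergency-department patient flow as a five-state Markov process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edflow)
```

## The model

A patient's passage through an emergency department (ED) is treated as a
continuous-time Markov chain on five states:

1. **triage** — from registration/triage until first physician contact;
2. **physician** — active physician management in the treatment area;
3. **observation** — the observation room, including waiting for a ward bed;
4. **discharge** — left the ED alive and not admitted (absorbing);
5. **admission** — admitted to a ward or ICU, or transferred (absorbing).

Seven transitions are allowed: 1→2, 1→4 (the rare "left without being seen"
pathway), 2→3, 2→4, 2→5, 3→4 and 3→5. The graph is acyclic — a patient never
returns to an earlier stage — which gives several quantities closed forms.

Each allowed transition `i→j` carries an intensity `q_ij`, interpreted as
movements per person-hour. All times in the package are in hours; this is
fixed, not configurable, because every rate and every descriptive summary is
conventionally reported per person-hour. Conditional on occupying a
transient state `i`, the waiting time to the next movement is exponential
with the **total exit rate** `r_i = Σ_j q_ij`, and the destination is `j`
with probability `q_ij / r_i` (the embedded jump chain). One point deserves
emphasis because the field's shorthand is ambiguous: the reciprocal `1/q_ij`
is the mean of the latent competing clock of transition `i→j`, while the
realized mean sojourn in state `i` is `1/r_i`. `sojourn_stats()` reports the
total exit rate, its reciprocal mean and the median `log(2)/r_i`, and the
documentation labels both notions explicitly.

Covariates act log-linearly on each intensity,

```
q_ij(z) = q_ij0 * exp(beta_ij' z),
```

so `exp(beta)` is a relative rate (RR) per one-unit covariate increment.
Following the source study's convention, triage level (1 = most acute to
5 = least) and age group (1 = under 20 to 5 = over 80 years) enter as
uncentered continuous scores. This is a deliberate simplification (the
reference baseline then corresponds to the extrapolated score 0); treating
the scores as categorical would be more faithful at the price of many more
parameters, and is out of scope.

To capture within-day variation, the day is partitioned into four six-hour
shifts — night [00–06), morning [06–12), afternoon [12–18), evening [18–24)
— and a shift-stratified model lets every transition have its own intensity
per shift (piecewise-constant intensities indexed by clock time).

`ed_reference_model()` ships the published rates from a large Taiwanese
tertiary-centre ED (about 150,000 visits in one year) that the package uses
as its reference parameterisation: for example q(triage→physician) = 4.224,
q(physician→discharge) = 0.235, q(observation→admission) = 0.0189 per
person-hour, with RRs such as 1.891 per triage level on
physician→discharge. Two of the published rates are printed at three
decimals in the source's table but at four decimals in its text; the package
uses the four-decimal values (0.0114, 0.0189).

## Closed-form layer

`generator_matrix()` assembles the 5×5 generator `Q` (absorbing rows zero,
rows summing to zero). From it:

* `embedded_jump_probs()` — destination distribution per state;
* `absorption_probabilities()` — first-passage probabilities into
  discharge/admission, solved exactly by back-substitution in reverse
  topological order (3, 2, 1), exploiting acyclicity;
* `transition_probability()` — `P(t) = expm(Q t)`, delegated to
  `Matrix::expm()` (scaling-and-squaring). The acyclic closed forms and an
  independent ODE solve of the Kolmogorov forward equation serve as test
  oracles, never as the implementation's own path;
* `steady_flow_counts()` — expected `i→j` movements per hour given a steady
  occupancy (`q_ij × n_i`), rounded half away from zero to match the
  convention of the published table; transitions out of states without a
  supplied occupancy are omitted rather than silently zeroed.

## Synthetic cohorts

The study's hospital records are not public, so `generate_cohort()` creates
patient-level event records with the statistical structure the analysis
assumes: covariates drawn from configurable marginals (defaults match the
published cohort: triage I–V 5.6/15.2/59.9/17.7/1.7%, age groups
29.3/21.4/22.9/19.3/7.1%, categories 17.6/59.2/23.2%, normalized to sum to
one), arrival clock times spread over days with per-shift weights, and
trajectories simulated as competing exponential clocks. The default arrival
weights (0.15/0.30/0.30/0.25 across night/morning/afternoon/evening, uniform
within shift) are an undramatic invented default — no arrival distribution is
published — and are configurable. The tiny 1→4 intensity (0.0005; "left
without being seen") is retained so that pathway is exercised.

**Shift convention.** When simulating under a shift-stratified model, a
spell's rates are those of the shift containing its *state-entry* clock
time; they are frozen for the whole sojourn rather than re-drawn when a
sojourn crosses a shift boundary. Whether the source study re-evaluated
rates at boundaries is unstated; the frozen-at-entry convention was chosen
because it matches the estimator's attribution rule exactly (next section),
making the simulate→fit loop internally consistent. The alternative — true
piecewise hazards with exposure split at boundaries — is a coherent design
too, but mixing it with entry-shift attribution would bias the recovery of
shift rates. The prediction layer, by contrast, *does* switch generators at
boundaries, because an occupancy curve is a statement about the process, not
about any one spell's estimator.

What the generator does **not** emulate: queueing and capacity interactions
between patients (the Markov model has no servers), day-of-week or seasonal
arrival structure, time-varying covariates within a visit, and the real
cohort's joint covariate distribution (marginals are independent). Passing
the recovery tests therefore demonstrates the estimator's correctness under
the model's own assumptions, not the model's adequacy for any real ED.

## Estimation

All transition times are observed administrative timestamps, so the package
maximizes the **exact-observation** likelihood (panel/interval-censored
likelihoods are out of scope). `extract_stats()` reduces records to spells:
each visited transient state contributes its sojourn to person-time `T_i`
and one event to the realized transition `N_ij`. Records with decreasing
timestamps are rejected (abort, or skip-with-log, per `on_error`); tied
timestamps — possible in minute-resolution administrative data — are
jittered to one second (1/3600 h) with a logged count.

Without covariates the MLE is closed-form, `q̂_ij = N_ij / T_i`, with Wald
95% intervals on the log scale, `exp(log q̂ ± 1.96/√N_ij)`. A transition
with zero events yields estimate 0, an undefined CI and a flag — never an
exception, since rare pathways routinely have empty cells in small shifts.
The interval type of the source study is unstated; log-scale Wald is the
frequentist default here.

With covariates, the likelihood factorizes over transitions, and each
factor is formally a Poisson likelihood for the spell-level 0/1 event
indicator with a log person-time offset. `fit_covariates()` therefore
maximizes each factor with `stats::glm(family = poisson)` — iteratively
reweighted least squares, a Newton-type method, run to a 1e-12 deviance
tolerance — and reports `RR = exp(beta)` with Wald intervals. Covariates
constant within a transition's spells (including an identically-zero one)
are dropped with `beta = 0`, which reduces that transition exactly to the
closed-form MLE; non-convergence and runaway coefficients (|beta| > 15,
complete separation) are flagged. The reported log-likelihood is always
recomputed in-package from the fitted parameters, and the test suite checks
it against an independent brute-force per-patient product of exponential
densities and jump probabilities to 1e-9.

`fit_shift_model()` partitions spells by the shift of their state-entry
clock time — the whole sojourn and its event are attributed to that shift,
exposures are never split — and fits each shift separately. This is the
exact estimator for the simulator's frozen-at-entry convention.

`fit_mcmc()` is a deliberately small Metropolis-within-Gibbs sampler on the
log rates (and betas when requested), not a probabilistic-programming
dependency: vague normal(0, 10) priors on the log scale by default,
per-transition Gamma priors on the natural scale as an option (with the
log-scale Jacobian, so the conjugate Gamma(a + N, b + T) posterior is exact
and testable), proposal scales adapted toward a 0.44 per-component
acceptance rate during burn-in only, and an acceptance-rate diagnostic
warning outside [0.1, 0.6]. Posterior medians and central 95% intervals are
reported; chains are reproducible under a fixed seed.

## Prediction

`occupancy()` produces the predictive dynamic distribution of a patient
entering triage: for homogeneous models the triage row of `expm(Q t)` on a
grid (default step 0.1 h over a 6-hour horizon, the span usually plotted);
for shift models the distribution vector is propagated through the exact
matrix exponentials of successive shift windows intersected with the grid,
so curves are continuous at boundaries to machine precision and independent
of the grid step. `in_system_probability()` folds the curve to
`1 − P(discharge) − P(admission)`. Curves are tidy `(time, state,
probability)` tables ready for plotting; plotting itself is left to the
user. Shift-model curves require the entry clock time; covariates default
to the reference (all-zero) profile rather than averaging over a cohort —
averaging is a user decision, easily done by mixing curves.

With the reference rates the six-hour in-system probability is about 0.32.
The source study's corresponding shift-specific figures (28%–38%) derive
from its full supplementary shift-rate table, which is not reproduced in the
main text; the machinery to compute them from any fitted shift model is in
scope, the specific numbers are not.

## Pipeline and reproducibility

`run_pipeline()` chains cohort acquisition (read CSV or simulate),
descriptives (`describe_cohort()`: per-segment medians and IQRs, Q3 − Q1
with linear interpolation), estimation, prediction and the steady-flow
report, writing each artifact plus a manifest (config echo, seed, versions,
timings). Runs are deterministic given the seed — the fit JSON is
byte-identical across repeats. A thin command-line wrapper with
`simulate/describe/fit/predict/report/run` subcommands ships in
`inst/cli/edflow.R`; the package functions are the primary interface.

## Numerical choices and problem sizes

* Matrix exponentials: `Matrix::expm` on the full 5×5 generator; tolerances
  in tests 1e-10 (semigroup), 1e-12 (row conservation).
* Steady-flow rounding: half away from zero, matching the published
  integers.
* Tie jitter: +1/3600 h, logged.
* Zero rates are allowed in a model (e.g. to switch off the LWBS pathway)
  as long as every transient state keeps a positive total exit rate.
* Simulation sizes in the test suite were chosen so Monte-Carlo error sits
  comfortably inside the asserted tolerances: 200,000 trajectories for
  baseline-rate recovery and median checks (relative MC error ≈ 0.2% on the
  triage rate), 100,000 for covariate-RR and shift-rate recovery, 200
  replicates of n = 2,000 for CI-coverage calibration (95% CI asserted to
  cover in 90–99% of replicates).

## Limitations

The model inherits the usual multistate assumptions: exponential sojourns
(no duration dependence within a state), no capacity constraints or
patient interactions, covariate effects constant over a visit, and — in the
shift variant — intensities constant within six-hour blocks. Covariate
scores treated as continuous force a common multiplicative step between
adjacent levels. The synthetic-data generator shares all these assumptions,
so simulation-based tests validate estimation and prediction machinery, not
clinical realism.
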