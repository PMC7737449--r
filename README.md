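# edflow

Multistate Markov modelling of emergency-department (ED) patient flow.

ED crowding analyses usually treat the department as a black box between
arrival and departure. `edflow` instead models the management process itself
as a continuous-time Markov chain on five states — **triage** (1),
**physician management** (2), **observation / waiting for admission** (3),
and the absorbing outcomes **discharge** (4) and **admission** (5) — with
seven allowed transitions (1→2, 1→4, 2→3, 2→4, 2→5, 3→4, 3→5). The package
is for biostatisticians and ED operations researchers who want to estimate
stage-specific patient movement rates from administrative timestamps,
quantify covariate effects on each stage, and turn the fitted model into
predictive occupancy curves.

## The model

Each transition `i→j` has an intensity `q_ij` (movements per person-hour).
Sojourns in a transient state are exponential with the total exit rate
`r_i = Σ_j q_ij`; the destination follows the embedded jump chain
`P(j | i) = q_ij / r_i`. Covariates `z` (triage level 1–5, age group 1–5,
treated as continuous scores) act log-linearly,

    q_ij(z) = q_ij0 · exp(β_ij' z),   RR = exp(β),

and a shift-stratified variant gives every transition its own intensity in
each six-hour block of the day (night/morning/afternoon/evening). Because
all transition times are observed, the likelihood is the exact-observation
one and the baseline MLE is closed form, `q̂_ij = N_ij / T_i` (events over
person-time at risk); covariate effects are maximized per transition as a
Poisson regression with log person-time offset, and a lightweight Metropolis
sampler provides Bayesian fits. State-occupancy forecasts come from the
matrix exponential `P(t) = exp(Qt)` (piecewise across shift windows for
shift models).

The package ships a reference parameterisation (`ed_reference_model()`)
estimated from ~150,000 visits to a tertiary-centre ED, and — because those
hospital records are not public — a synthetic-cohort generator that emulates
their structure for testing and experimentation.

## Worked example

```r
library(edflow)

m <- ed_reference_model(covariates = TRUE)

## where do patients end up?
absorption_probabilities(generator_matrix(m))
#> discharge admission
#>    0.7165    0.2835

## expected hourly movements with 60 patients in treatment, 100 in observation
movement_report(m, c(physician = 60, observation = 100))
#>                  movement   rate n_per_hour RR_triage_level RR_age_group
#>       triage -> physician 4.2240          —           0.962        1.134
#>       triage -> discharge 0.0005          —           1.481        1.174
#>  physician -> observation 0.0990          6           0.673        1.549
#>    physician -> discharge 0.2350         14           1.891        0.773
#>    physician -> admission 0.0460          3           0.757        0.830
#>  observation -> discharge 0.0114          1           1.650        0.619
#>  observation -> admission 0.0189          2           0.842        0.910

## simulate a cohort, describe it, refit the rates
coh <- generate_cohort(cohort_config(5000, seed = 2020))
describe_cohort(coh)
#> Cohort of 5000 patients
#> Disposition: admission 28%, discharge 72%
#> Time segments (hours, median / IQR):
#>                   segment    n median    iqr
#>       triage_to_physician 4999  0.161  0.266
#>  physician_to_observation 1317  1.970  3.010
#>  ...
#>      total_length_of_stay 5000  3.200  7.390

fit_mle(extract_stats(coh))
#> Five-state model fit (mle)
#>                transition  estimate               95% CI n_events person_time
#>       triage -> physician 4.2450000        (4.129-4.364)     4999    1177.711
#>  physician -> observation 0.0977700     (0.09263-0.1032)     1317   13470.599
#>    physician -> discharge 0.2300000       (0.222-0.2382)     3098   13470.599
#>  ...

## predictive occupancy: probability of still being in the ED at 6 h
oc <- occupancy(ed_reference_model(), horizon = 6)
tail(in_system_probability(oc), 1)
#>    time p_in_system
#> 61    6   0.3182826
```

Reading the output: 71.65% of patients are eventually discharged; in a
steady department the rates imply 14 physician→discharge movements per hour;
refitting a simulated cohort reproduces the generating rates within sampling
error (4.245 vs 4.224 for triage→physician at n = 5,000); and a patient
entering triage has a 32% probability of still being in the system six hours
later under the pooled rates.

A 50-patient synthetic example cohort ships at
`system.file("extdata", "cohort_synthetic_50.csv", package = "edflow")`, and
`inst/cli/edflow.R` wraps the same functionality as a command-line tool with
`simulate / describe / fit / predict / report / run` subcommands. See the
vignette (`vignettes/ed-patient-flow.Rmd`) for the model, estimation and
design details.

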