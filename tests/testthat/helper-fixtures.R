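# Large simulated cohorts are expensive; build each at most once per run and
# share across test files.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# 200,000 patients at the reference baseline rates (no covariate effects)
baseline_cohort <- function() {
  fixture("baseline_cohort",
          generate_cohort(cohort_config(200000, seed = 101)))
}
baseline_stats <- function() {
  fixture("baseline_stats", extract_stats(baseline_cohort()))
}

# 100,000 patients with the full covariate (triage level + age group) effects
covariate_stats <- function() {
  fixture("covariate_stats", {
    coh <- generate_cohort(cohort_config(
      100000, model = ed_reference_model(covariates = TRUE), seed = 202))
    extract_stats(coh)
  })
}

# 100,000 patients under the shift-stratified observation->admission rates
shift_stats <- function() {
  fixture("shift_stats", {
    coh <- generate_cohort(cohort_config(
      100000, model = ed_reference_shift_model(), seed = 303))
    extract_stats(coh, schedule = shift_schedule())
  })
}

ref_baseline <- function() ed_reference_model()$baseline

# hand-built patient record rows
manual_record <- function(id, t_dep, t_phys = NA_real_, t_obs = NA_real_,
                          dispo = "discharge", arrival_hour = 0,
                          triage = 3, age = 2) {
  data.frame(patient_id = id,
             arrival = as.POSIXct("2013-01-01", tz = "UTC") +
               round(arrival_hour * 3600),
             triage_level = triage, age_group = age,
             category = "adult_nontrauma", t_triage_h = 0,
             t_physician_h = t_phys, t_observation_h = t_obs,
             t_departure_h = t_dep, disposition = dispo,
             stringsAsFactors = FALSE)
}

# independent brute-force exact-observation log-likelihood: per patient,
# product of the exponential sojourn density (total exit rate) and the
# embedded jump probability for every visited state
brute_loglik <- function(records, rates) {
  r1 <- rates[["1->2"]] + rates[["1->4"]]
  r2 <- rates[["2->3"]] + rates[["2->4"]] + rates[["2->5"]]
  r3 <- rates[["3->4"]] + rates[["3->5"]]
  ll <- 0
  for (i in seq_len(nrow(records))) {
    tp <- records$t_physician_h[i]
    to <- records$t_observation_h[i]
    td <- records$t_departure_h[i]
    adm <- records$disposition[i] == "admission"
    if (is.na(tp)) {
      ll <- ll + log(r1) - r1 * td + log(rates[["1->4"]] / r1)
    } else {
      ll <- ll + log(r1) - r1 * tp + log(rates[["1->2"]] / r1)
      if (is.na(to)) {
        q <- if (adm) rates[["2->5"]] else rates[["2->4"]]
        ll <- ll + log(r2) - r2 * (td - tp) + log(q / r2)
      } else {
        ll <- ll + log(r2) - r2 * (to - tp) + log(rates[["2->3"]] / r2)
        q <- if (adm) rates[["3->5"]] else rates[["3->4"]]
        ll <- ll + log(r3) - r3 * (td - to) + log(q / r3)
      }
    }
  }
  ll
}

# empirical state occupied at time t since arrival, for every patient
empirical_state <- function(records, t) {
  tp <- records$t_physician_h
  to <- records$t_observation_h
  td <- records$t_departure_h
  adm <- records$disposition == "admission"
  first_exit <- ifelse(is.na(tp), td, tp)
  state <- ifelse(t < first_exit, "triage",
           ifelse(!is.na(tp) & t < ifelse(is.na(to), td, to), "physician",
           ifelse(!is.na(to) & t < td, "observation",
           ifelse(adm, "admission", "discharge"))))
  # LWBS patients departing before t are discharged
  state[is.na(tp) & t >= td] <- "discharge"
  state
}

# Wald CI coverage of q(physician->discharge) over replicated small cohorts
coverage_q24 <- function(n_reps = 200, n = 2000) {
  fixture("coverage_q24", {
    truth <- ref_baseline()[["2->4"]]
    hits <- vapply(seq_len(n_reps), function(r) {
      coh <- generate_cohort(cohort_config(n, seed = 7000 + r))
      rt <- fit_mle(extract_stats(coh))$rates
      i <- match("2->4", rt$transition)
      rt$lower[i] <= truth && truth <= rt$upper[i]
    }, TRUE)
    mean(hits)
  })
}
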