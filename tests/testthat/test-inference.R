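test_that("spell extraction does the event/person-time bookkeeping", {
  recs <- rbind(manual_record("a", t_phys = 0.2, t_dep = 1.2),
                manual_record("b", t_phys = 0.3, t_obs = 1.3, t_dep = 5.3,
                              dispo = "admission"),
                manual_record("c", t_dep = 0.5))  # LWBS
  st <- extract_stats(recs)
  expect_equal(st$n_events[["1->2"]], 2)
  expect_equal(st$n_events[["1->4"]], 1)
  expect_equal(st$n_events[["2->4"]], 1)
  expect_equal(st$n_events[["2->3"]], 1)
  expect_equal(st$n_events[["3->5"]], 1)
  expect_equal(st$n_events[["2->5"]], 0)
  expect_equal(st$person_time[["1"]], 0.2 + 0.3 + 0.5)
  expect_equal(st$person_time[["2"]], 1.0 + 1.0)
  expect_equal(st$person_time[["3"]], 4.0)
  # empty input gives all-zero statistics
  st0 <- extract_stats(recs[0, ])
  expect_true(all(st0$n_events == 0) && all(st0$person_time == 0))
})

test_that("invalid records abort or are skipped by id; ties are jittered", {
  bad <- rbind(manual_record("ok", t_phys = 0.2, t_dep = 1),
               manual_record("rev", t_phys = 2, t_dep = 1))
  expect_error(extract_stats(bad), "rev")
  expect_message(st <- extract_stats(bad, on_error = "skip"), "skipping 1")
  expect_equal(st$n_patients, 1L)
  tie <- manual_record("t", t_phys = 0.5, t_dep = 0.5)
  expect_message(st2 <- extract_stats(tie), "jittered")
  expect_equal(st2$spells$sojourn[st2$spells$state == 2], 1 / 3600)
})

test_that("spells are attributed to the shift of their state-entry clock", {
  rec <- manual_record("s", arrival_hour = 5.5, t_phys = 1.0, t_obs = 8.0,
                       t_dep = 20, dispo = "admission")
  st <- extract_stats(rec, schedule = shift_schedule())
  sp <- st$spells[order(st$spells$state), ]
  expect_equal(sp$shift, c("night", "morning", "afternoon"))
  expect_equal(sp$entry_hod, c(5.5, 6.5, 13.5))
  # whole sojourn and event land in the entry shift
  expect_equal(st$time_by_shift["2", "morning"], 7.0)
  expect_equal(st$events_by_shift["2->3", "morning"], 1)
  expect_equal(sum(st$events_by_shift), sum(st$n_events))
})

test_that("the rate MLE is events over person-time with log-scale Wald CI", {
  # 10 patients seen after 0.5 h each: N_12 = 10, T_1 = 5, q = 2
  recs <- do.call(rbind, lapply(1:10, function(i)
    manual_record(paste0("p", i), t_phys = 0.5, t_dep = 1)))
  f <- fit_mle(extract_stats(recs))
  r12 <- f$rates[f$rates$transition == "1->2", ]
  expect_equal(r12$estimate, 2)
  expect_equal(r12$lower, exp(log(2) - 1.96 / sqrt(10)))
  expect_equal(r12$upper, exp(log(2) + 1.96 / sqrt(10)))
  # zero-event transition: estimate 0, flagged, no exception
  r14 <- f$rates[f$rates$transition == "1->4", ]
  expect_equal(r14$estimate, 0)
  expect_true(r14$flagged)
  expect_true(is.na(r14$lower))
})

test_that("refitting a large simulated cohort recovers the generating rates", {
  f <- fit_mle(baseline_stats())
  q12 <- f$rates$estimate[f$rates$transition == "1->2"]
  expect_equal(q12, 4.224, tolerance = 0.01)
  # truth inside the 95% CI for the high-count transitions
  truth <- ref_baseline()
  for (k in c("1->2", "2->3", "2->4", "2->5", "3->4", "3->5")) {
    row <- f$rates[f$rates$transition == k, ]
    expect_lt(abs(log(row$estimate / truth[[k]])) * sqrt(row$n_events), 3)
  }
})

test_that("module log-likelihood equals the brute-force per-patient product", {
  coh <- generate_cohort(cohort_config(100, seed = 31))
  st <- extract_stats(coh)
  f <- fit_mle(st)
  qhat <- stats::setNames(f$rates$estimate, f$rates$transition)
  expect_equal(f$loglik, brute_loglik(coh, qhat), tolerance = 1e-9)
  # and at arbitrary (non-MLE) rates via the internal likelihood
  set.seed(32)
  q <- ref_baseline() * exp(stats::runif(7, -0.5, 0.5))
  expect_equal(edflow:::loglik_rates(st, q), brute_loglik(coh, q),
               tolerance = 1e-9)
})

test_that("the covariate model recovers built-in relative rates", {
  f <- fit_covariates(covariate_stats(), c("triage_level", "age_group"))
  rr <- f$rr
  pick <- function(k, cv) rr$rr[rr$transition == k & rr$covariate == cv]
  expect_gt(pick("2->4", "triage_level"), 1.85)
  expect_lt(pick("2->4", "triage_level"), 1.93)
  # joint recovery of both covariates on the same transition within 3%
  expect_equal(pick("2->4", "triage_level"), 1.891, tolerance = 0.03)
  expect_equal(pick("2->4", "age_group"), 0.773, tolerance = 0.03)
  expect_equal(pick("1->2", "age_group"), 1.134, tolerance = 0.03)
  expect_equal(pick("1->2", "triage_level"), 0.962, tolerance = 0.03)
  # Wald CIs bracket the estimates
  expect_true(all(rr$lower[!is.na(rr$se)] <= rr$rr[!is.na(rr$se)] &
                    rr$rr[!is.na(rr$se)] <= rr$upper[!is.na(rr$se)]))
})

test_that("an identically-zero covariate reduces to the baseline MLE", {
  coh <- generate_cohort(cohort_config(2000, seed = 41))
  st <- extract_stats(coh)
  st$spells$null_cov <- 0
  f0 <- fit_covariates(st, "null_cov")
  f <- fit_mle(st)
  expect_equal(f0$rr$beta, rep(0, nrow(f0$rr)))
  expect_equal(f0$rates$estimate, f$rates$estimate, tolerance = 1e-12)
  expect_equal(f0$loglik, f$loglik, tolerance = 1e-9)
})

test_that("shift-stratified fits recover shift-dependent rates", {
  fits <- fit_shift_model(shift_stats())
  truth <- c(night = 0.0012, morning = 0.0069,
             afternoon = 0.0390, evening = 0.0327)
  for (s in names(truth)) {
    est <- fits[[s]]$rates$estimate[fits[[s]]$rates$transition == "3->5"]
    expect_equal(est, truth[[s]], tolerance = 0.05)
  }
})

test_that("shift-homogeneous data give mutually consistent shift estimates", {
  coh <- generate_cohort(cohort_config(40000, seed = 55))
  st <- extract_stats(coh, schedule = shift_schedule())
  fits <- fit_shift_model(st)
  pooled <- fit_mle(st)
  # pooled fit is unchanged by carrying the shift attribution
  expect_equal(pooled$rates, fit_mle(extract_stats(coh))$rates)
  for (s in names(fits)) {
    row <- fits[[s]]$rates[fits[[s]]$rates$transition == "2->4", ]
    z <- log(row$estimate / 0.235) * sqrt(row$n_events)
    expect_lt(abs(z), 4)
  }
})

test_that("shifts without spells are flagged, not errors", {
  # everything happens within one morning: huge rates, morning-only arrivals
  b <- ref_baseline() * 1000
  names(b) <- names(ref_baseline())
  coh <- generate_cohort(cohort_config(
    300, model = rate_model(b),
    arrival_weights = c(night = 0, morning = 1, afternoon = 0, evening = 0),
    seed = 66))
  fits <- fit_shift_model(extract_stats(coh, schedule = shift_schedule()))
  expect_true(all(fits$night$rates$flagged))
  expect_true(all(fits$evening$rates$flagged))
  expect_false(all(fits$morning$rates$flagged))
})

test_that("CI coverage of the physician->discharge rate is nominal", {
  cov <- coverage_q24()
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.99)
})

test_that("MCMC matches the conjugate gamma posterior", {
  coh <- generate_cohort(cohort_config(300, seed = 71))
  st <- extract_stats(coh)
  f <- fit_mcmc(st, n_iter = 8000, burn_in = 2000, seed = 72,
                priors = list("2->4" = list(type = "gamma",
                                            shape = 2, rate = 1)))
  N <- st$n_events[["2->4"]]
  T2 <- st$person_time[["2"]]
  post_med <- stats::qgamma(0.5, shape = 2 + N, rate = 1 + T2)
  est <- f$rates$estimate[f$rates$transition == "2->4"]
  expect_equal(est, post_med, tolerance = 0.03)
  lo <- f$rates$lower[f$rates$transition == "2->4"]
  hi <- f$rates$upper[f$rates$transition == "2->4"]
  expect_lt(stats::qgamma(0.025, 2 + N, rate = 1 + T2), est)
  expect_lt(abs(lo / stats::qgamma(0.025, 2 + N, rate = 1 + T2) - 1), 0.15)
  expect_lt(abs(hi / stats::qgamma(0.975, 2 + N, rate = 1 + T2) - 1), 0.15)
})

test_that("MCMC posterior medians approach the MLE for large samples", {
  st <- baseline_stats()
  f <- fit_mcmc(st, n_iter = 4000, burn_in = 1500, seed = 73)
  mle <- fit_mle(st)
  for (k in c("1->2", "2->3", "2->4", "2->5")) {
    expect_equal(f$rates$estimate[f$rates$transition == k],
                 mle$rates$estimate[mle$rates$transition == k],
                 tolerance = 0.01)
  }
  acc <- f$diagnostics$acceptance
  expect_true(all(acc > 0.1 & acc < 0.6))
})

test_that("MCMC chains are reproducible under a fixed seed", {
  coh <- generate_cohort(cohort_config(500, seed = 81))
  st <- extract_stats(coh)
  f1 <- fit_mcmc(st, n_iter = 1200, burn_in = 400, seed = 99)
  f2 <- fit_mcmc(st, n_iter = 1200, burn_in = 400, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$rates, f2$rates)
})

test_that("MCMC with covariates brackets the generating relative rate", {
  m <- rate_model(ref_baseline(),
                  effects = list("2->4" = c(triage_level = log(1.891))))
  coh <- generate_cohort(cohort_config(4000, model = m, seed = 91))
  st <- extract_stats(coh)
  # the near-empty LWBS transition may trip the acceptance-rate diagnostic
  f <- suppressWarnings(fit_mcmc(st, n_iter = 3000, burn_in = 1000, seed = 92,
                                 covariates = "triage_level"))
  row <- f$rr[f$rr$transition == "2->4" & f$rr$covariate == "triage_level", ]
  expect_lt(row$lower, 1.891)
  expect_gt(row$upper, 1.891)
  mle <- fit_covariates(st, "triage_level", transitions = "2->4")
  rr_mle <- mle$rr$rr[mle$rr$transition == "2->4"]
  expect_equal(row$rr, rr_mle, tolerance = 0.05)
})
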