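test_that("generator matrix assembles intensities, diagonals and absorbing rows", {
  Q <- generator_matrix(ed_reference_model())
  expect_equal(Q["physician", "discharge"], 0.235)
  expect_equal(Q["physician", "physician"], -(0.099 + 0.235 + 0.046))
  expect_equal(unname(Q["triage", "physician"]), 4.224)
  expect_true(all(Q[c("discharge", "admission"), ] == 0))
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(Q["triage", "observation"], 0)  # disallowed transition
})

test_that("covariates scale intensities as exp(beta * z)", {
  m <- rate_model(ref_baseline(),
                  effects = list("2->4" = c(triage_level = log(1.891))))
  Q <- generator_matrix(m, covariates = c(triage_level = 1))
  expect_equal(Q["physician", "discharge"], 0.235 * 1.891)
  Q3 <- generator_matrix(m, covariates = c(triage_level = 3))
  expect_equal(Q3["physician", "discharge"], 0.235 * 1.891^3)
  # all-zero covariates reproduce the baseline
  expect_equal(generator_matrix(m, covariates = c(triage_level = 0)),
               generator_matrix(m))
  expect_error(generator_matrix(m, covariates = c(bogus = 1)),
               "unknown covariate")
  expect_error(generator_matrix(m, covariates = c(triage_level = 1, extra = 2)),
               "unknown covariate")
  m2 <- ed_reference_model(covariates = TRUE)
  expect_error(generator_matrix(m2, covariates = c(triage_level = 1)),
               "must supply")
})

test_that("rate model validation rejects malformed inputs", {
  b <- ref_baseline()
  expect_error(rate_model(b[-1]), "transition keys")
  bad <- b; bad[["2->4"]] <- -1
  expect_error(rate_model(bad), "nonnegative")
  dead <- b; dead[c("3->4", "3->5")] <- 0
  expect_error(rate_model(dead), "positive total exit")
  expect_error(rate_model(b, shifts = list(night = b)), "labels")
  sh <- list(night = b, morning = b, afternoon = b, evening = b[-1])
  expect_error(rate_model(b, shifts = sh), "every transition")
  # a single zero rate with other exits intact is allowed (e.g. no LWBS)
  no_lwbs <- b; no_lwbs[["1->4"]] <- 0
  expect_s3_class(rate_model(no_lwbs), "ed_rate_model")
})

test_that("embedded jump probabilities follow the competing exponential clocks", {
  Q <- generator_matrix(ed_reference_model())
  p2 <- embedded_jump_probs(Q, "physician")
  expect_equal(unname(p2[c("observation", "discharge", "admission")]),
               c(0.099, 0.235, 0.046) / 0.38, tolerance = 1e-12)
  expect_equal(unname(p2["discharge"]), 0.6184, tolerance = 1e-4)
  p3 <- embedded_jump_probs(Q, 3)
  expect_equal(unname(p3), c(0.0114, 0.0189) / 0.0303, tolerance = 1e-12)
  expect_equal(unname(p3["discharge"]), 0.3762, tolerance = 1e-3)
  for (s in 1:3) expect_equal(sum(embedded_jump_probs(Q, s)), 1)
  # symmetry when the two exits tie
  b <- ref_baseline(); b[["3->4"]] <- 0.02; b[["3->5"]] <- 0.02
  expect_equal(unname(embedded_jump_probs(generator_matrix(rate_model(b)), 3)),
               c(0.5, 0.5))
  expect_error(embedded_jump_probs(Q, "discharge"), "absorbing")
})

test_that("sojourn summaries use the total exit rate", {
  Q <- generator_matrix(ed_reference_model())
  s1 <- sojourn_stats(Q, "triage")
  expect_equal(s1$rate, 4.224 + 0.0005)
  expect_equal(s1$median, log(2) / 4.2245)
  expect_equal(round(s1$median, 2), 0.16)
  expect_equal(sojourn_stats(Q, "observation")$mean, 1 / 0.0303)
  # median is 1 hour exactly when the exit rate is log(2)
  b <- ref_baseline(); b[["3->4"]] <- log(2) / 2; b[["3->5"]] <- log(2) / 2
  expect_equal(sojourn_stats(generator_matrix(rate_model(b)), 3)$median, 1)
  expect_error(sojourn_stats(Q, 5), "absorbing")
})

test_that("absorption probabilities solve the acyclic first-passage problem", {
  Q <- generator_matrix(ed_reference_model())
  a <- absorption_probabilities(Q, "triage")
  # independent arithmetic on the embedded chain
  p_disch_2 <- 0.235 / 0.38 + (0.099 / 0.38) * (0.0114 / 0.0303)
  p_disch_1 <- (0.0005 + 4.224 * p_disch_2) / 4.2245
  expect_equal(unname(a["discharge"]), p_disch_1, tolerance = 1e-12)
  expect_equal(unname(a["discharge"]), 0.7165, tolerance = 1e-4)
  expect_equal(sum(a), 1)
  expect_equal(unname(absorption_probabilities(Q, "discharge")), c(1, 0))
  expect_equal(unname(absorption_probabilities(Q, 5)), c(0, 1))
  # symmetric competing exits from physician, no observation pathway
  b <- ref_baseline(); b[["2->3"]] <- 0; b[["2->4"]] <- 0.1; b[["2->5"]] <- 0.1
  a2 <- absorption_probabilities(generator_matrix(rate_model(b)), 2)
  expect_equal(unname(a2), c(0.5, 0.5))
})

test_that("transition probabilities are a stochastic semigroup", {
  Q <- generator_matrix(ed_reference_model())
  expect_equal(transition_probability(Q, 0), diag(5), ignore_attr = TRUE)
  # closed form for the triage survival probability
  for (t in c(0.1, 1, 4)) {
    P <- transition_probability(Q, t)
    expect_equal(P["triage", "triage"], exp(-4.2245 * t), tolerance = 1e-10)
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-10)
    expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
  }
  expect_error(transition_probability(Q, -1), "nonnegative")
})

test_that("Chapman-Kolmogorov holds for random generators", {
  set.seed(11)
  for (rep in 1:5) {
    b <- ref_baseline() * exp(stats::runif(7, -1, 1))
    names(b) <- names(ref_baseline())
    Q <- generator_matrix(rate_model(b))
    s <- stats::runif(1, 0.1, 5); t <- stats::runif(1, 0.1, 5)
    expect_equal(transition_probability(Q, s + t),
                 transition_probability(Q, s) %*% transition_probability(Q, t),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("long-run transition probabilities reach the absorption probabilities", {
  Q <- generator_matrix(ed_reference_model())
  # far beyond the longest chain of mean sojourns (observation: 33 h)
  P <- transition_probability(Q, 600)
  a <- absorption_probabilities(Q, "triage")
  expect_equal(P["triage", c("discharge", "admission")], a, tolerance = 1e-6)
  expect_lt(sum(P["triage", 1:3]), 1e-6)
})

test_that("transition probabilities agree with an independent ODE solve", {
  Q <- generator_matrix(ed_reference_model())
  # Kolmogorov forward equation dp/dt = p Q from the triage row
  ode <- deSolve::lsoda(
    y = c(1, 0, 0, 0, 0), times = c(0, 2, 6),
    func = function(t, y, parms) list(drop(y %*% parms)), parms = Q,
    rtol = 1e-10, atol = 1e-12)
  for (r in 2:3) {
    expect_equal(unname(ode[r, -1]),
                 unname(transition_probability(Q, ode[r, 1])["triage", ]),
                 tolerance = 1e-7)
  }
})

test_that("raising one intensity raises its downstream absorption probability", {
  b <- ref_baseline()
  Q <- generator_matrix(rate_model(b))
  for (scale in c(1.5, 3, 10)) {
    b2 <- b; b2[["3->5"]] <- b[["3->5"]] * scale
    Q2 <- generator_matrix(rate_model(b2))
    expect_gt(absorption_probabilities(Q2, "triage")["admission"],
              absorption_probabilities(Q, "triage")["admission"])
  }
})

test_that("steady-flow counts reproduce the published integers", {
  m <- ed_reference_model()
  counts <- steady_flow_counts(m, c(physician = 60, observation = 100))
  expect_identical(counts, c("2->3" = 6L, "2->4" = 14L, "2->5" = 3L,
                             "3->4" = 1L, "3->5" = 2L))
  # triage outflows only reported when a triage occupancy is supplied
  expect_false(any(grepl("^1", names(counts))))
  with_triage <- steady_flow_counts(m, c(triage = 10, physician = 60,
                                         observation = 100))
  expect_equal(with_triage[["1->2"]], 42L)
  expect_identical(steady_flow_counts(m, c(physician = 0, observation = 0)),
                   c("2->3" = 0L, "2->4" = 0L, "2->5" = 0L,
                     "3->4" = 0L, "3->5" = 0L))
  expect_equal(steady_flow_counts(m, c(physician = 1))[["2->4"]], 0L)
  # rounding is half away from zero
  b <- ref_baseline(); b[["2->4"]] <- 0.05
  expect_equal(steady_flow_counts(rate_model(b), c(physician = 10))[["2->4"]],
               1L)
})

test_that("rate models round-trip through JSON", {
  m <- ed_reference_model(covariates = TRUE)
  p <- withr::local_tempfile(fileext = ".json")
  write_rate_model(m, p)
  m2 <- read_rate_model(p)
  expect_equal(m2$baseline, m$baseline)
  expect_equal(m2$effects, m$effects)
  sm <- ed_reference_shift_model()
  p2 <- withr::local_tempfile(fileext = ".json")
  write_rate_model(sm, p2)
  expect_equal(read_rate_model(p2)$shifts, sm$shifts)
})

test_that("shift schedule partitions the day into four six-hour intervals", {
  expect_equal(shift_of_clock(c(0, 5.999, 6, 11.5, 12, 17.9, 18, 23.99)),
               c("night", "night", "morning", "morning",
                 "afternoon", "afternoon", "evening", "evening"))
  expect_equal(shift_of_clock(24 + 3), "night")  # wraps modulo 24
  m <- ed_reference_shift_model()
  Qa <- generator_matrix(m, shift = "afternoon")
  expect_equal(Qa["observation", "admission"], 0.0390)
  expect_equal(generator_matrix(m, shift = 1)["observation", "admission"],
               0.0012)
})
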