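#' Configuration for a synthetic ED cohort
#'
#' Describes how to generate patient-level event records with the structure
#' the five-state analysis assumes: covariates drawn from configurable
#' marginals, arrival clock times spread over days with per-shift weights,
#' and trajectories simulated from a [rate_model()] as competing-risks
#' exponential sojourns.
#'
#' Default covariate marginals mirror a large tertiary-centre ED cohort:
#' triage levels I-V 5.6/15.2/59.9/17.7/1.7%, age groups (<20, 20-40, 40-60,
#' 60-80, >80 years) 29.3/21.4/22.9/19.3/7.1%, categories (trauma, adult
#' non-trauma, pediatric non-trauma) 17.6/59.2/23.2%. Marginals are
#' normalized to sum to one. The default arrival weights
#' (night/morning/afternoon/evening 0.15/0.30/0.30/0.25, uniform within
#' shift) are a plain configurable default, not an estimate.
#'
#' @param n_patients number of patients to generate (> 0).
#' @param model an [rate_model()] driving the trajectories.
#' @param triage_probs,age_probs length-5 marginal probabilities for triage
#'   level 1-5 and age group 1-5.
#' @param category_probs named length-3 marginals for the patient category.
#' @param arrival_weights named length-4 per-shift arrival weights
#'   (night, morning, afternoon, evening); need not sum to 1.
#' @param n_days arrivals are spread uniformly over this many days.
#' @param start_date calendar date of day 1 (arrival timestamps are UTC).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class `ed_cohort_config`.
#' @seealso [generate_cohort()], [sample_covariates()]
#' @export
cohort_config <- function(n_patients,
                          model = ed_reference_model(),
                          triage_probs = c(0.056, 0.152, 0.599, 0.177, 0.017),
                          age_probs = c(0.293, 0.214, 0.229, 0.193, 0.071),
                          category_probs = c(trauma = 0.176,
                                             adult_nontrauma = 0.592,
                                             pediatric_nontrauma = 0.232),
                          arrival_weights = c(night = 0.15, morning = 0.30,
                                              afternoon = 0.30, evening = 0.25),
                          n_days = 30,
                          start_date = as.Date("2013-01-01"),
                          seed = 1L) {
  stopifnot(n_patients > 0, length(triage_probs) == 5, length(age_probs) == 5,
            length(category_probs) == 3, length(arrival_weights) == 4,
            n_days >= 1, inherits(model, "ed_rate_model"))
  if (any(triage_probs < 0) || any(age_probs < 0) ||
      any(category_probs < 0) || any(arrival_weights < 0)) {
    stop("probabilities and weights must be nonnegative", call. = FALSE)
  }
  if (sum(arrival_weights) <= 0) stop("arrival weights sum to zero")
  sched <- shift_schedule()
  if (is.null(names(arrival_weights))) names(arrival_weights) <- sched$labels
  arrival_weights <- arrival_weights[sched$labels]
  structure(list(n_patients = as.integer(n_patients), model = model,
                 triage_probs = triage_probs / sum(triage_probs),
                 age_probs = age_probs / sum(age_probs),
                 category_probs = category_probs / sum(category_probs),
                 arrival_weights = arrival_weights,
                 n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "ed_cohort_config")
}

#' Draw patient covariates from the configured marginals
#'
#' Draws are taken from the current RNG stream; callers wanting
#' reproducibility set the seed (as [generate_cohort()] does from
#' `config$seed`) or pass `seed`.
#'
#' @param config an [cohort_config()].
#' @param n number of patients (defaults to `config$n_patients`).
#' @param seed optional integer seed set before drawing.
#' @return data.frame with numeric columns `triage_level`, `age_group`
#'   (scores 1-5) and character `category`.
#' @export
sample_covariates <- function(config, n = config$n_patients, seed = NULL) {
  stopifnot(inherits(config, "ed_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    triage_level = sample(1:5, n, replace = TRUE, prob = config$triage_probs),
    age_group = sample(1:5, n, replace = TRUE, prob = config$age_probs),
    category = sample(names(config$category_probs), n, replace = TRUE,
                      prob = config$category_probs),
    stringsAsFactors = FALSE
  )
}

# per-patient intensity of one transition: shift-specific baseline (by the
# clock time of state entry) times the covariate relative rates
patient_rates <- function(model, key, covs, entry_clock) {
  if (is.null(model$shifts)) {
    base <- rep(model$baseline[[key]], length(entry_clock))
  } else {
    per_shift <- vapply(model$shifts, `[[`, 0, key)
    base <- unname(per_shift[shift_of_clock(entry_clock)])
  }
  b <- model$effects[[key]]
  if (!is.null(b)) {
    miss <- setdiff(names(b), names(covs))
    if (length(miss)) stop("records lack covariate(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    z <- as.matrix(covs[names(b)])
    base <- base * exp(drop(z %*% b))
  }
  base
}

# vectorized competing-risks trajectory simulation; sojourns in each state are
# drawn from the rates of the shift containing the state-entry clock time
# (rates frozen at entry, not re-drawn at shift boundaries)
simulate_paths <- function(model, covs, arrival_clock) {
  n <- nrow(covs)
  t_phys <- t_obs <- t_dep <- rep(NA_real_, n)
  dispo <- character(n)

  # state 1: triage
  q12 <- patient_rates(model, "1->2", covs, arrival_clock)
  q14 <- patient_rates(model, "1->4", covs, arrival_clock)
  r1 <- q12 + q14
  s1 <- stats::rexp(n, r1)
  to_phys <- stats::runif(n) < q12 / r1
  t_dep[!to_phys] <- s1[!to_phys]
  dispo[!to_phys] <- "discharge"
  t_phys[to_phys] <- s1[to_phys]

  # state 2: physician management
  i2 <- which(to_phys)
  if (length(i2)) {
    entry2 <- arrival_clock[i2] + s1[i2]
    c2 <- covs[i2, , drop = FALSE]
    q23 <- patient_rates(model, "2->3", c2, entry2)
    q24 <- patient_rates(model, "2->4", c2, entry2)
    q25 <- patient_rates(model, "2->5", c2, entry2)
    r2 <- q23 + q24 + q25
    s2 <- stats::rexp(length(i2), r2)
    u <- stats::runif(length(i2))
    dest2 <- ifelse(u < q23 / r2, 3L, ifelse(u < (q23 + q24) / r2, 4L, 5L))
    done2 <- dest2 != 3L
    t_dep[i2[done2]] <- s1[i2[done2]] + s2[done2]
    dispo[i2[done2]] <- ifelse(dest2[done2] == 4L, "discharge", "admission")
    t_obs[i2[!done2]] <- s1[i2[!done2]] + s2[!done2]

    # state 3: observation / waiting for admission
    i3 <- i2[!done2]
    if (length(i3)) {
      entry3 <- arrival_clock[i3] + t_obs[i3]
      c3 <- covs[i3, , drop = FALSE]
      q34 <- patient_rates(model, "3->4", c3, entry3)
      q35 <- patient_rates(model, "3->5", c3, entry3)
      r3 <- q34 + q35
      s3 <- stats::rexp(length(i3), r3)
      t_dep[i3] <- t_obs[i3] + s3
      dispo[i3] <- ifelse(stats::runif(length(i3)) < q34 / r3,
                          "discharge", "admission")
    }
  }
  data.frame(t_physician_h = t_phys, t_observation_h = t_obs,
             t_departure_h = t_dep, disposition = dispo,
             stringsAsFactors = FALSE)
}

#' Simulate a single patient trajectory
#'
#' Draws one trajectory through the five-state process: from each transient
#' state the sojourn is exponential with the state's total exit rate and the
#' destination follows the embedded jump probabilities (equivalently,
#' competing exponential clocks). For shift-stratified models the rates are
#' those of the shift containing the clock time of state entry.
#'
#' @param model an [rate_model()].
#' @param covariates named numeric vector (e.g.
#'   `c(triage_level = 3, age_group = 2)`) covering the model's effect
#'   covariates; extra entries such as a category label may be present.
#' @param start_clock arrival clock time in decimal hours (may exceed 24;
#'   reduced modulo 24 for shift lookup).
#' @param patient_id id string for the returned record.
#' @return one-row data.frame in the cohort record schema (see
#'   [generate_cohort()]).
#' @examples
#' set.seed(1)
#' simulate_path(ed_reference_model(), c(triage_level = 3, age_group = 1), 8.5)
#' @export
simulate_path <- function(model, covariates = NULL, start_clock = 0,
                          patient_id = "p000001") {
  stopifnot(inherits(model, "ed_rate_model"))
  covs <- as.data.frame(as.list(covariates %||% numeric()))
  if (!nrow(covs)) covs <- data.frame(row.names = 1)
  path <- simulate_paths(model, covs, start_clock)
  rec <- data.frame(
    patient_id = patient_id,
    arrival = as.POSIXct(round(start_clock * 3600),
                         origin = "2013-01-01", tz = "UTC"),
    triage_level = covariates[["triage_level"]] %||% NA_real_,
    age_group = covariates[["age_group"]] %||% NA_real_,
    category = NA_character_,
    t_triage_h = 0,
    stringsAsFactors = FALSE
  )
  cbind(rec, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic patient cohort
#'
#' Draws covariates from the configured marginals, arrival times per the
#' per-shift arrival weights (uniform within shift, uniform across
#' `n_days`), and a trajectory per patient from the rate model. Optionally
#' writes the cohort to CSV (see [write_cohort()] for the schema) and always
#' returns the records in memory.
#'
#' @param config an [cohort_config()].
#' @param path optional CSV output path.
#' @return data.frame of patient records, one row per patient, with columns
#'   `patient_id`, `arrival` (POSIXct UTC), `triage_level`, `age_group`,
#'   `category`, `t_triage_h` (always 0), `t_physician_h`,
#'   `t_observation_h` (NA if the observation room was skipped),
#'   `t_departure_h` and `disposition` (`"discharge"`/`"admission"`); the
#'   `t_*` columns are decimal hours since arrival.
#' @examples
#' coh <- generate_cohort(cohort_config(100, seed = 42))
#' table(coh$disposition)
#' @export
generate_cohort <- function(config, path = NULL) {
  stopifnot(inherits(config, "ed_cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  covs <- sample_covariates(config, n)
  sched <- shift_schedule()
  day <- sample.int(config$n_days, n, replace = TRUE)
  sh <- sample.int(4L, n, replace = TRUE, prob = config$arrival_weights)
  within <- stats::runif(n, 0, 6)
  arrival_clock <- (day - 1) * 24 + sched$boundaries[sh] + within
  arrival_clock <- round(arrival_clock * 3600) / 3600  # whole seconds
  paths <- simulate_paths(config$model, covs, arrival_clock)
  records <- data.frame(
    patient_id = sprintf("p%06d", seq_len(n)),
    arrival = as.POSIXct(config$start_date, tz = "UTC") +
      round(arrival_clock * 3600),
    triage_level = covs$triage_level,
    age_group = covs$age_group,
    category = covs$category,
    t_triage_h = 0,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, paths)
  if (!is.null(path)) write_cohort(records, path, seed = config$seed)
  records
}

#' Read / write a cohort CSV
#'
#' One row per patient: `patient_id, arrival_iso8601, triage_level,
#' age_group, category, t_triage_h, t_physician_h, t_observation_h,
#' t_departure_h, disposition`. Times are decimal hours since arrival
#' (empty where a state was skipped); the ISO-8601 arrival carries the
#' clock/shift information. A `#` comment header records the generating seed.
#'
#' @param records cohort data.frame as returned by [generate_cohort()].
#' @param path CSV path.
#' @param seed optional seed recorded in the header comment.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the records data.frame.
#' @export
write_cohort <- function(records, path, seed = NULL) {
  out <- data.frame(
    patient_id = records$patient_id,
    arrival_iso8601 = format(records$arrival, "%Y-%m-%dT%H:%M:%S",
                             tz = "UTC"),
    triage_level = records$triage_level,
    age_group = records$age_group,
    category = records$category,
    t_triage_h = num_or_blank(records$t_triage_h),
    t_physician_h = num_or_blank(records$t_physician_h),
    t_observation_h = num_or_blank(records$t_observation_h),
    t_departure_h = num_or_blank(records$t_departure_h),
    disposition = records$disposition,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# edflow synthetic cohort",
                    if (!is.null(seed)) paste0("; seed=", seed)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

num_or_blank <- function(x) ifelse(is.na(x), "", sprintf("%.9f", x))

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#", na.strings = "",
                         stringsAsFactors = FALSE)
  need <- c("patient_id", "arrival_iso8601", "triage_level", "age_group",
            "category", "t_triage_h", "t_physician_h", "t_observation_h",
            "t_departure_h", "disposition")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("cohort CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(
    patient_id = as.character(raw$patient_id),
    arrival = as.POSIXct(raw$arrival_iso8601, format = "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
    triage_level = as.numeric(raw$triage_level),
    age_group = as.numeric(raw$age_group),
    category = as.character(raw$category),
    t_triage_h = as.numeric(raw$t_triage_h),
    t_physician_h = as.numeric(raw$t_physician_h),
    t_observation_h = as.numeric(raw$t_observation_h),
    t_departure_h = as.numeric(raw$t_departure_h),
    disposition = as.character(raw$disposition),
    stringsAsFactors = FALSE
  )
}

# clock hour-of-day (decimal hours) of a POSIXct arrival
arrival_hod <- function(arrival) {
  lt <- as.POSIXlt(arrival, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}
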