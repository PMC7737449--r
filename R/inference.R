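#' Sufficient statistics for the exact-observation likelihood
#'
#' Converts patient-level event records into the sufficient statistics of
#' the five-state exponential model: for every patient and every transient
#' state visited, a spell contributing its sojourn to the state's person-time
#' at risk and one event to the realized transition. All transition times are
#' observed (administrative timestamps), so this is the exact-observation —
#' not panel-observed — likelihood.
#'
#' With a shift schedule, a spell is attributed wholly to the shift
#' containing its state-entry clock time (sojourns are not split at shift
#' boundaries), matching the simulator's convention of freezing rates at
#' state entry.
#'
#' Records with decreasing timestamps are rejected: `on_error = "abort"`
#' stops naming the offending patient ids, `"skip"` drops them with a
#' message. Tied timestamps (zero sojourns) are jittered to one second
#' (1/3600 h) and counted in a message.
#'
#' @param records cohort data.frame in the [generate_cohort()] schema.
#' @param schedule optional [shift_schedule()]; when supplied, spells carry a
#'   shift label and per-shift aggregates are computed.
#' @param on_error `"abort"` or `"skip"` for invalid records.
#' @return An object of class `ed_suffstats`: list with `spells` (one row per
#'   patient-state spell: `patient_id`, `state`, `dest`, `transition`,
#'   `sojourn`, `entry_hod`, `shift`, plus covariate columns), `n_events`
#'   (named count per transition), `person_time` (named hours per transient
#'   state), per-shift matrices `events_by_shift` / `time_by_shift` when a
#'   schedule is given, `n_patients` and `schedule`.
#' @export
extract_stats <- function(records, schedule = NULL,
                          on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  need <- c("patient_id", "arrival", "t_physician_h", "t_observation_h",
            "t_departure_h", "disposition")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  tp <- records$t_physician_h
  to <- records$t_observation_h
  td <- records$t_departure_h
  bad <- is.na(td) | td < 0 |
    (!is.na(tp) & tp < 0) |
    (!is.na(tp) & !is.na(to) & to < tp) |
    (!is.na(tp) & is.na(to) & td < tp) |
    (!is.na(to) & td < to) |
    (!is.na(to) & is.na(tp)) |                      # observation needs physician
    !records$disposition %in% c("discharge", "admission") |
    (is.na(tp) & records$disposition != "discharge") # LWBS departs from triage
  if (any(bad)) {
    ids <- records$patient_id[bad]
    msg <- paste0(sum(bad), " invalid record(s): ",
                  paste(utils::head(ids, 10), collapse = ", "),
                  if (sum(bad) > 10) ", ...")
    if (on_error == "abort") stop(msg, call. = FALSE)
    message("skipping ", msg)
    records <- records[!bad, , drop = FALSE]
    tp <- tp[!bad]; to <- to[!bad]; td <- td[!bad]
  }
  n <- nrow(records)
  if (n == 0) {
    spells <- data.frame(patient_id = character(), state = integer(),
                         dest = integer(), sojourn = numeric(),
                         entry_hod = numeric())
  } else {
    hod <- arrival_hod(records$arrival)
    has_phys <- !is.na(tp)
    has_obs <- !is.na(to)
    adm <- records$disposition == "admission"

    s1 <- data.frame(patient_id = records$patient_id, state = 1L,
                     dest = ifelse(has_phys, 2L, 4L),
                     sojourn = ifelse(has_phys, tp, td),
                     entry_hod = hod, stringsAsFactors = FALSE)
    i2 <- which(has_phys)
    s2 <- if (length(i2))
      data.frame(patient_id = records$patient_id[i2], state = 2L,
                 dest = ifelse(has_obs[i2], 3L, ifelse(adm[i2], 5L, 4L)),
                 sojourn = ifelse(has_obs[i2], to[i2], td[i2]) - tp[i2],
                 entry_hod = (hod[i2] + tp[i2]) %% 24,
                 stringsAsFactors = FALSE)
    i3 <- which(has_obs)
    s3 <- if (length(i3))
      data.frame(patient_id = records$patient_id[i3], state = 3L,
                 dest = ifelse(adm[i3], 5L, 4L),
                 sojourn = td[i3] - to[i3],
                 entry_hod = (hod[i3] + to[i3]) %% 24,
                 stringsAsFactors = FALSE)
    spells <- rbind(s1, s2, s3)
    ties <- spells$sojourn == 0
    if (any(ties)) {
      message(sum(ties), " zero sojourn(s) jittered to 1 second")
      spells$sojourn[ties] <- 1 / 3600
    }
    for (cv in intersect(c("triage_level", "age_group"), names(records))) {
      spells[[cv]] <- records[[cv]][match(spells$patient_id,
                                          records$patient_id)]
    }
  }
  spells$transition <- if (nrow(spells))
    paste0(spells$state, "->", spells$dest) else character()
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "ed_shift_schedule"))
    spells$shift <- shift_of_clock(spells$entry_hod, schedule)
  }
  out <- list(spells = spells,
              n_events = spell_events(spells),
              person_time = spell_time(spells),
              n_patients = n,
              schedule = schedule)
  if (!is.null(schedule)) {
    out$events_by_shift <- vapply(schedule$labels, function(s)
      spell_events(spells[spells$shift == s, , drop = FALSE]), numeric(7))
    out$time_by_shift <- vapply(schedule$labels, function(s)
      spell_time(spells[spells$shift == s, , drop = FALSE]), numeric(3))
  }
  class(out) <- "ed_suffstats"
  out
}

spell_events <- function(spells) {
  keys <- ed_state_space()$transitions
  n <- vapply(keys, function(k) sum(spells$transition == k), 0)
  stats::setNames(n, keys)
}

spell_time <- function(spells) {
  tr <- ed_state_space()$transient
  t <- vapply(tr, function(i) sum(spells$sojourn[spells$state == i]), 0)
  stats::setNames(t, as.character(tr))
}

#' @export
print.ed_suffstats <- function(x, ...) {
  cat("ED sufficient statistics:", x$n_patients, "patients,",
      nrow(x$spells), "spells\n")
  cat("events: ", paste0(names(x$n_events), "=", x$n_events,
                         collapse = ", "), "\n")
  cat("person-time (h) in states 1-3: ",
      paste(signif(x$person_time, 5), collapse = ", "), "\n")
  if (!is.null(x$schedule)) cat("shift-attributed (state-entry clock)\n")
  invisible(x)
}

# restrict sufficient statistics to one shift
subset_stats <- function(stats, shift) {
  if (is.null(stats$schedule)) {
    stop("stats carry no shift attribution; pass a schedule to extract_stats",
         call. = FALSE)
  }
  shift <- resolve_shift(shift)
  sp <- stats$spells[stats$spells$shift == shift, , drop = FALSE]
  out <- list(spells = sp, n_events = spell_events(sp),
              person_time = spell_time(sp),
              n_patients = length(unique(sp$patient_id)),
              schedule = stats$schedule)
  class(out) <- "ed_suffstats"
  out
}

#' Closed-form maximum-likelihood estimates of the transition intensities
#'
#' Under the exact-observation exponential likelihood the MLE is
#' `q_ij = N_ij / T_i` (events over person-time at risk), with Wald 95%
#' intervals on the log scale, `exp(log q +- 1.96 / sqrt(N_ij))`. Transitions
#' with zero events get estimate 0 with undefined CI and are flagged rather
#' than raising an error. The reported log-likelihood is
#' `sum_ij N_ij log q_ij - q_ij T_i` (constants dropped).
#'
#' @param stats an [extract_stats()] result.
#' @param shift optional shift label/index: fit on that shift's spells only
#'   (requires shift-attributed stats).
#' @return An object of class `ed_fit` with elements `rates` (data.frame:
#'   `transition`, `estimate`, `lower`, `upper`, `n_events`, `person_time`,
#'   `flagged`), `rr` (NULL), `loglik`, `method = "mle"`, `shift`,
#'   `diagnostics`.
#' @export
fit_mle <- function(stats, shift = NULL) {
  stopifnot(inherits(stats, "ed_suffstats"))
  if (!is.null(shift)) stats <- subset_stats(stats, shift)
  keys <- ed_state_space()$transitions
  pairs <- transition_pairs(keys)
  N <- stats$n_events
  T_i <- stats$person_time[as.character(pairs[, "from"])]
  est <- ifelse(T_i > 0, N / T_i, NA_real_)
  se_log <- ifelse(N > 0, 1 / sqrt(N), NA_real_)
  rates <- data.frame(
    transition = keys,
    estimate = ifelse(N > 0, est, ifelse(T_i > 0, 0, NA_real_)),
    lower = exp(log(est) - 1.96 * se_log),
    upper = exp(log(est) + 1.96 * se_log),
    n_events = unname(N),
    person_time = unname(T_i),
    flagged = unname(N == 0),
    stringsAsFactors = FALSE
  )
  rates$lower[N == 0] <- NA_real_
  rates$upper[N == 0] <- NA_real_
  ll <- sum(ifelse(N > 0, N * log(est) - est * T_i, 0))
  structure(list(rates = rates, rr = NULL, loglik = ll, method = "mle",
                 shift = if (!is.null(shift)) resolve_shift(shift),
                 diagnostics = list(n_patients = stats$n_patients)),
            class = "ed_fit")
}

#' Log-linear covariate model for the transition intensities
#'
#' Fits `q_ij(z) = q_ij0 * exp(beta_ij . z)` by maximizing the
#' exact-observation likelihood. The likelihood factorizes over transitions:
#' each transition's factor is a Poisson likelihood for the 0/1 event
#' indicator of its spells with a log person-time offset, so each transition
#' is maximized by an iteratively reweighted least-squares (Newton-type)
#' Poisson regression. `RR = exp(beta)` with Wald 95% CI
#' `exp(beta +- 1.96 SE)`.
#'
#' Covariates that are constant within a transition's spells (including the
#' all-zero covariate) are dropped from that transition's design with
#' `beta = 0`, which reduces the baseline to the closed-form [fit_mle()]
#' estimate. Non-convergence and runaway coefficients (|beta| > 15,
#' complete separation) are flagged in the result, not raised.
#'
#' @param stats an [extract_stats()] result whose spells carry the covariate
#'   columns.
#' @param covariates character vector of covariate names (columns of
#'   `stats$spells`), e.g. `c("triage_level", "age_group")`.
#' @param transitions transitions to model with covariates (default: all
#'   seven); the others get baseline-only MLEs.
#' @param shift optional shift restriction, as in [fit_mle()].
#' @return An `ed_fit`; `rr` is a data.frame with columns `transition`,
#'   `covariate`, `rr`, `lower`, `upper`, `beta`, `se`, `flagged`.
#' @export
fit_covariates <- function(stats, covariates,
                           transitions = NULL, shift = NULL) {
  stopifnot(inherits(stats, "ed_suffstats"), length(covariates) >= 1)
  if (!is.null(shift)) stats <- subset_stats(stats, shift)
  miss <- setdiff(covariates, names(stats$spells))
  if (length(miss)) stop("spells lack covariate column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  keys <- ed_state_space()$transitions
  transitions <- transitions %||% keys
  stopifnot(all(transitions %in% keys))
  pairs <- transition_pairs(keys)
  base_fit <- fit_mle(stats)
  rates <- base_fit$rates
  rr_rows <- list()
  ll <- 0
  for (k in keys) {
    from <- pairs[k, "from"]; to <- pairs[k, "to"]
    sub <- stats$spells[stats$spells$state == from, , drop = FALSE]
    y <- as.integer(sub$dest == to)
    tt <- sub$sojourn
    if (!k %in% transitions || nrow(sub) == 0 || sum(y) == 0) {
      # baseline-only: contribution at the closed-form MLE
      q <- rates$estimate[rates$transition == k]
      if (isTRUE(q > 0)) ll <- ll + sum(y) * log(q) - q * sum(tt)
      next
    }
    Z <- as.matrix(sub[covariates])
    keep <- apply(Z, 2, function(col) stats::sd(col) > 0)
    flagged <- FALSE
    if (any(keep)) {
      df <- data.frame(y = y, Z[, keep, drop = FALSE])
      fit <- stats::glm(y ~ ., data = df, family = stats::poisson(),
                        offset = log(tt),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
      cf <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
      flagged <- !fit$converged || any(abs(cf[-1]) > 15)
      beta <- stats::setNames(numeric(length(covariates)), covariates)
      beta_se <- stats::setNames(rep(NA_real_, length(covariates)),
                                 covariates)
      beta[colnames(Z)[keep]] <- cf[-1]
      beta_se[colnames(Z)[keep]] <- se[-1]
      q0 <- exp(cf[[1]])
      q0_ci <- exp(cf[[1]] + c(-1.96, 1.96) * se[[1]])
    } else {
      beta <- stats::setNames(numeric(length(covariates)), covariates)
      beta_se <- stats::setNames(rep(NA_real_, length(covariates)),
                                 covariates)
      q0 <- sum(y) / sum(tt)
      q0_ci <- exp(log(q0) + c(-1.96, 1.96) / sqrt(sum(y)))
    }
    i <- match(k, rates$transition)
    rates$estimate[i] <- q0
    rates$lower[i] <- q0_ci[1]
    rates$upper[i] <- q0_ci[2]
    rates$flagged[i] <- flagged
    rr_rows[[k]] <- data.frame(
      transition = k, covariate = covariates,
      rr = exp(unname(beta)),
      lower = exp(unname(beta) - 1.96 * unname(beta_se)),
      upper = exp(unname(beta) + 1.96 * unname(beta_se)),
      beta = unname(beta), se = unname(beta_se),
      flagged = flagged, stringsAsFactors = FALSE
    )
    rate_z <- q0 * exp(drop(Z %*% beta))
    ll <- ll + sum(y * log(rate_z) - rate_z * tt)
  }
  structure(list(rates = rates, rr = do.call(rbind, rr_rows),
                 loglik = ll, method = "mle",
                 shift = if (!is.null(shift)) resolve_shift(shift),
                 diagnostics = list(n_patients = stats$n_patients,
                                    covariates = covariates)),
            class = "ed_fit")
}

#' Shift-stratified estimation
#'
#' Partitions the spells by the shift of their state-entry clock time and
#' fits each shift separately ([fit_mle()], or [fit_covariates()] when
#' covariate names are given). Shifts in which some transition has no events
#' carry the usual zero-event flags.
#'
#' @inheritParams fit_covariates
#' @param covariates optional covariate names; `NULL` for baseline-only fits.
#' @return named list of `ed_fit` (one per shift label), class
#'   `ed_shift_fit`.
#' @export
fit_shift_model <- function(stats, covariates = NULL) {
  stopifnot(inherits(stats, "ed_suffstats"))
  if (is.null(stats$schedule)) {
    stop("extract_stats must be run with a shift schedule first",
         call. = FALSE)
  }
  fits <- lapply(stats$schedule$labels, function(s) {
    if (is.null(covariates)) fit_mle(stats, shift = s)
    else fit_covariates(stats, covariates, shift = s)
  })
  names(fits) <- stats$schedule$labels
  class(fits) <- "ed_shift_fit"
  fits
}

#' @export
print.ed_shift_fit <- function(x, digits = 4, ...) {
  for (s in names(x)) {
    cat("==", s, "==\n")
    print(x[[s]], digits = digits)
  }
  invisible(x)
}

#' @export
print.ed_fit <- function(x, digits = 4, ...) {
  cat("Five-state model fit (", x$method,
      if (!is.null(x$shift)) paste0(", shift: ", x$shift), ")\n", sep = "")
  tab <- x$rates
  tab$transition <- pretty_transition(tab$transition)
  tab$estimate <- signif(tab$estimate, digits)
  tab$`95% CI` <- sprintf("(%s-%s)", signif(tab$lower, digits),
                          signif(tab$upper, digits))
  print(tab[c("transition", "estimate", "95% CI", "n_events",
              "person_time")], row.names = FALSE)
  if (!is.null(x$rr)) {
    cat("Relative rates (per one-unit covariate increment):\n")
    rr <- x$rr
    rr$transition <- pretty_transition(rr$transition)
    rr$rr <- signif(rr$rr, digits)
    rr$`95% CI` <- sprintf("(%s-%s)", signif(rr$lower, digits),
                           signif(rr$upper, digits))
    print(rr[c("transition", "covariate", "rr", "95% CI")],
          row.names = FALSE)
  }
  cat("loglik:", format(x$loglik), "\n")
  invisible(x)
}

# exact-observation log-likelihood of given rates for given stats
# (baseline-only); used by the MCMC sampler and available for checks
loglik_rates <- function(stats, rates) {
  keys <- ed_state_space()$transitions
  pairs <- transition_pairs(keys)
  N <- stats$n_events[keys]
  T_i <- stats$person_time[as.character(pairs[, "from"])]
  sum(ifelse(N > 0, N * log(rates[keys]), 0) - rates[keys] * T_i)
}
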