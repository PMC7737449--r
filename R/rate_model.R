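#' Transition-intensity model for the five-state ED process
#'
#' A rate model bundles baseline transition intensities `q_ij` (per
#' person-hour), optional log-linear covariate effects, and optional
#' shift-specific baseline intensities (piecewise-constant over the four
#' six-hour shifts of [shift_schedule()]).
#'
#' Covariates act multiplicatively on an intensity:
#' `q_ij(z) = q_ij * exp(sum_c beta_ijc * z_c)`, so `exp(beta)` is the
#' relative rate (RR) per one-unit covariate increment. Covariates are
#' numeric, uncentered scores; the conventional coding is triage level 1-5
#' (most to least acute) and age group 1-5 (<20, 20-40, 40-60, 60-80, >80
#' years), both treated as continuous.
#'
#' @param baseline named numeric vector of intensities over the transition
#'   keys `"1->2"`, `"1->4"`, `"2->3"`, `"2->4"`, `"2->5"`, `"3->4"`,
#'   `"3->5"`. All seven keys must be present; values must be finite and
#'   nonnegative, and every transient state must have a strictly positive
#'   total exit rate.
#' @param effects optional named list, one element per transition key, each a
#'   named numeric vector of log-coefficients (`beta`, so RR = `exp(beta)`)
#'   by covariate name.
#' @param shifts optional named list with one element per shift label
#'   (`night`, `morning`, `afternoon`, `evening`), each a full baseline
#'   vector overriding `baseline` during that shift.
#' @return An object of class `ed_rate_model`.
#' @seealso [ed_reference_model()], [generator_matrix()]
#' @examples
#' m <- rate_model(c("1->2" = 4.2, "1->4" = 0.0005, "2->3" = 0.1,
#'                   "2->4" = 0.24, "2->5" = 0.05, "3->4" = 0.011,
#'                   "3->5" = 0.019))
#' generator_matrix(m)
#' @export
rate_model <- function(baseline, effects = NULL, shifts = NULL) {
  ss <- ed_state_space()
  keys <- ss$transitions
  if (is.null(names(baseline)) || !setequal(names(baseline), keys)) {
    stop("`baseline` must be named with exactly the transition keys: ",
         paste(keys, collapse = ", "), call. = FALSE)
  }
  baseline <- baseline[keys]
  check_rates(baseline, ss)
  if (!is.null(effects)) {
    bad <- setdiff(names(effects), keys)
    if (length(bad)) stop("effects given for unknown transitions: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(effects)) {
      b <- effects[[k]]
      if (!is.numeric(b) || is.null(names(b)) || any(!is.finite(b))) {
        stop("effects[['", k, "']] must be a named finite numeric vector ",
             "of log-coefficients", call. = FALSE)
      }
    }
  }
  if (!is.null(shifts)) {
    sched <- shift_schedule()
    if (!setequal(names(shifts), sched$labels)) {
      stop("`shifts` must have exactly the labels: ",
           paste(sched$labels, collapse = ", "), call. = FALSE)
    }
    shifts <- lapply(shifts[sched$labels], function(b) {
      if (is.null(names(b)) || !setequal(names(b), keys)) {
        stop("every shift must define a rate for every transition",
             call. = FALSE)
      }
      b <- b[keys]
      check_rates(b, ss)
      b
    })
  }
  structure(list(baseline = baseline, effects = effects, shifts = shifts,
                 state_space = ss),
            class = "ed_rate_model")
}

check_rates <- function(rates, ss) {
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("transition intensities must be finite and nonnegative",
         call. = FALSE)
  }
  pairs <- transition_pairs(ss$transitions)
  exit <- vapply(ss$transient,
                 function(i) sum(rates[pairs[, "from"] == i]), 0)
  if (any(exit <= 0)) {
    stop("every transient state needs a strictly positive total exit rate",
         call. = FALSE)
  }
  invisible(rates)
}

# covariate names used anywhere in the model's effects
effect_covariates <- function(model) {
  unique(unlist(lapply(model$effects, names), use.names = FALSE))
}

#' @export
print.ed_rate_model <- function(x, digits = 4, ...) {
  cat("ED five-state rate model (intensities per person-hour)\n")
  tab <- data.frame(transition = pretty_transition(names(x$baseline)),
                    rate = signif(unname(x$baseline), digits))
  if (!is.null(x$effects)) {
    for (cv in effect_covariates(x)) {
      rr <- vapply(names(x$baseline), function(k) {
        b <- x$effects[[k]][cv]
        if (is.null(x$effects[[k]]) || is.na(b)) NA_real_ else exp(unname(b))
      }, 0)
      tab[[paste0("RR_", cv)]] <- signif(rr, digits)
    }
  }
  print(tab, row.names = FALSE)
  if (!is.null(x$shifts)) {
    cat("Shift-specific baselines defined for:",
        paste(names(x$shifts), collapse = ", "), "\n")
  }
  invisible(x)
}

pretty_transition <- function(keys) {
  ss <- ed_state_space()
  pairs <- transition_pairs(keys)
  lab <- names(ss$states)
  paste(lab[pairs[, "from"]], "->", lab[pairs[, "to"]])
}

#' Published reference rate model for a tertiary-centre ED
#'
#' Baseline transition intensities (per person-hour) and covariate relative
#' rates estimated from roughly 150,000 visits to a large Taiwanese
#' tertiary-care emergency department, used throughout the package as the
#' reference parameterisation for simulation and worked examples:
#' q(triage->physician) = 4.224, q(triage->departure) = 0.0005 (patients who
#' leave without being seen), q(physician->observation) = 0.099,
#' q(physician->discharge) = 0.235, q(physician->admission) = 0.046,
#' q(observation->discharge) = 0.0114, q(observation->admission) = 0.0189.
#'
#' With `covariates = TRUE` the model carries the published relative rates
#' per one-level increment of triage level (1.891 on physician->discharge,
#' 0.962 on triage->physician, ...) and of age group (1.134 on
#' triage->physician, 0.773 on physician->discharge, ...), stored as
#' log-coefficients.
#'
#' @param covariates logical; attach the triage-level and age-group effects?
#' @return An `ed_rate_model`.
#' @examples
#' ed_reference_model()
#' @export
ed_reference_model <- function(covariates = FALSE) {
  baseline <- c("1->2" = 4.224, "1->4" = 0.0005,
                "2->3" = 0.099, "2->4" = 0.235, "2->5" = 0.046,
                "3->4" = 0.0114, "3->5" = 0.0189)
  effects <- NULL
  if (covariates) {
    rr_triage <- c("1->2" = 0.962, "1->4" = 1.481, "2->3" = 0.673,
                   "2->4" = 1.891, "2->5" = 0.757, "3->4" = 1.650,
                   "3->5" = 0.842)
    rr_age <- c("1->2" = 1.134, "1->4" = 1.174, "2->3" = 1.549,
                "2->4" = 0.773, "2->5" = 0.830, "3->4" = 0.619,
                "3->5" = 0.910)
    effects <- lapply(names(baseline), function(k) {
      c(triage_level = log(rr_triage[[k]]), age_group = log(rr_age[[k]]))
    })
    names(effects) <- names(baseline)
  }
  rate_model(baseline, effects = effects)
}

#' Reference shift-stratified rate model
#'
#' The reference model of [ed_reference_model()] with the published
#' shift-specific observation-to-admission intensities: 0.0012 at night,
#' 0.0069 in the morning, 0.0390 in the afternoon and 0.0327 in the evening
#' (per person-hour), reflecting ward beds becoming available mostly in the
#' afternoon. All other intensities are held at their pooled baselines.
#' (The same study also reports a slower evening triage-to-physician rate,
#' 3.8872; it is not part of this default so that the shift contrast is
#' isolated on one transition.)
#'
#' @return An `ed_rate_model` with a `shifts` component.
#' @export
ed_reference_shift_model <- function() {
  base <- ed_reference_model()$baseline
  q35 <- c(night = 0.0012, morning = 0.0069,
           afternoon = 0.0390, evening = 0.0327)
  shifts <- lapply(q35, function(q) {
    b <- base
    b[["3->5"]] <- q
    b
  })
  rate_model(base, shifts = shifts)
}

#' Read / write a rate model as JSON
#'
#' Serialization stores baseline intensities under `"baseline"`,
#' log-coefficients under `"effects"` (keyed transition, then covariate)
#' and shift overrides under `"shifts"`.
#'
#' @param model an `ed_rate_model`.
#' @param path file path.
#' @return `read_rate_model()` returns an `ed_rate_model`;
#'   `write_rate_model()` returns `path` invisibly.
#' @export
write_rate_model <- function(model, path) {
  stopifnot(inherits(model, "ed_rate_model"))
  obj <- list(baseline = as.list(model$baseline))
  if (!is.null(model$effects)) obj$effects <- lapply(model$effects, as.list)
  if (!is.null(model$shifts)) obj$shifts <- lapply(model$shifts, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rate_model
#' @export
read_rate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  baseline <- unlist(obj$baseline)
  effects <- if (!is.null(obj$effects)) lapply(obj$effects, unlist)
  shifts <- if (!is.null(obj$shifts)) lapply(obj$shifts, unlist)
  rate_model(baseline, effects = effects, shifts = shifts)
}
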