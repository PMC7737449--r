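#' Predictive dynamic state-occupancy curve
#'
#' Probability of being in each of the five states as a function of time
#' since ED entry (start concentrated in triage). For a homogeneous model
#' this is the triage row of `expm(Q t)` on the grid; for shift-stratified
#' models the occupancy vector is propagated by left-multiplying the
#' piecewise matrix exponentials of the successive six-hour shift windows
#' intersected with the grid, so the curve is exact and continuous across
#' shift boundaries.
#'
#' @param model an [rate_model()].
#' @param horizon curve length in hours (> 0).
#' @param step grid step in hours (default 0.1).
#' @param covariates optional covariate vector, as in [generator_matrix()];
#'   `NULL` means reference (all-zero) covariates.
#' @param entry_clock clock time of entry in decimal hours (or a POSIXct);
#'   required for shift-stratified models, ignored otherwise.
#' @return An object of class `ed_occupancy`: tidy data.frame with columns
#'   `time` (hours since entry), `state` (label) and `probability`, with the
#'   entry clock and covariates as attributes.
#' @examples
#' oc <- occupancy(ed_reference_model(), horizon = 6)
#' subset(oc, time == 6)
#' @export
occupancy <- function(model, horizon = 6, step = 0.1, covariates = NULL,
                      entry_clock = NULL) {
  stopifnot(inherits(model, "ed_rate_model"), horizon > 0, step > 0)
  ss <- model$state_space
  grid <- seq(0, horizon, by = step)
  if (grid[length(grid)] < horizon) grid <- c(grid, horizon)
  p <- c(1, 0, 0, 0, 0)
  out <- matrix(NA_real_, length(grid), 5,
                dimnames = list(NULL, names(ss$states)))
  out[1, ] <- p
  if (is.null(model$shifts)) {
    Q <- generator_matrix(model, covariates = covariates)
    for (g in seq_along(grid)[-1]) {
      P <- transition_probability(Q, grid[g] - grid[g - 1])
      p <- drop(p %*% P)
      out[g, ] <- p
    }
  } else {
    if (is.null(entry_clock)) {
      stop("shift-stratified model: `entry_clock` is required", call. = FALSE)
    }
    if (inherits(entry_clock, "POSIXct")) entry_clock <- arrival_hod(entry_clock)
    sched <- shift_schedule()
    Qs <- lapply(sched$labels, function(s)
      generator_matrix(model, covariates = covariates, shift = s))
    names(Qs) <- sched$labels
    for (g in seq_along(grid)[-1]) {
      # propagate across every shift boundary inside (t_{g-1}, t_g]
      t0 <- grid[g - 1]; t1 <- grid[g]
      while (t0 < t1 - 1e-12) {
        clock <- (entry_clock + t0) %% 24
        next_bound <- 6 * floor(clock / 6 + 1)   # next multiple of 6 h
        dt <- min(t1 - t0, next_bound - clock)
        p <- drop(p %*% transition_probability(Qs[[shift_of_clock(clock)]], dt))
        t0 <- t0 + dt
      }
      out[g, ] <- p
    }
  }
  curve <- data.frame(time = rep(grid, each = 5),
                      state = rep(names(ss$states), length(grid)),
                      probability = as.vector(t(out)),
                      stringsAsFactors = FALSE)
  structure(curve, class = c("ed_occupancy", "data.frame"),
            entry_clock = entry_clock, covariates = covariates)
}

#' Probability of still being in the ED system
#'
#' `1 - P(discharge) - P(admission)` along an occupancy curve: the
#' probability of not yet having been absorbed, a nonincreasing function of
#' time since entry.
#'
#' @param curve an [occupancy()] result.
#' @return data.frame with columns `time` and `p_in_system`.
#' @examples
#' tail(in_system_probability(occupancy(ed_reference_model(), horizon = 6)))
#' @export
in_system_probability <- function(curve) {
  stopifnot(inherits(curve, "ed_occupancy"))
  absorbed <- curve$state %in% c("discharge", "admission")
  p_abs <- tapply(curve$probability[absorbed], curve$time[absorbed], sum)
  data.frame(time = as.numeric(names(p_abs)),
             p_in_system = 1 - unname(p_abs))
}

#' Steady-state hourly movement table
#'
#' Combines the baseline intensities, relative rates and expected hourly
#' movement counts of [steady_flow_counts()] into one table (the usual
#' reporting layout: movement, rate, count, RR per covariate). Transitions
#' out of states without a supplied occupancy show a `NA` count (printed as
#' an em dash).
#'
#' @param model an [rate_model()].
#' @param occupancy_counts named patient counts by state, e.g.
#'   `c(physician = 60, observation = 100)`.
#' @return data.frame of class `ed_movement_report`.
#' @examples
#' movement_report(ed_reference_model(covariates = TRUE),
#'                 c(physician = 60, observation = 100))
#' @export
movement_report <- function(model,
                            occupancy_counts = c(physician = 60,
                                                 observation = 100)) {
  stopifnot(inherits(model, "ed_rate_model"))
  keys <- names(model$baseline)
  counts <- steady_flow_counts(model, occupancy_counts)
  tab <- data.frame(
    movement = pretty_transition(keys),
    rate = unname(model$baseline),
    n_per_hour = counts[match(keys, names(counts))],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  if (!is.null(model$effects)) {
    for (cv in effect_covariates(model)) {
      tab[[paste0("RR_", cv)]] <- vapply(keys, function(k) {
        b <- model$effects[[k]][cv]
        if (is.null(model$effects[[k]]) || is.na(b)) NA_real_
        else exp(unname(b))
      }, 0)
    }
  }
  class(tab) <- c("ed_movement_report", "data.frame")
  tab
}

#' @export
print.ed_movement_report <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$n_per_hour <- ifelse(is.na(y$n_per_hour), "—",
                         as.character(y$n_per_hour))
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Render a table as GitHub-style markdown
#'
#' @param tab a data.frame (e.g. a [movement_report()] or a fit's `rates`).
#' @param digits significant digits for numeric columns.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(tab, digits = 4) {
  y <- as.data.frame(tab)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) ifelse(is.na(v), "—",
                                              format(signif(v, digits))))
  y[] <- lapply(y, function(v) ifelse(is.na(v) | v == "NA", "—",
                                      as.character(v)))
  header <- paste0("| ", paste(names(y), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(y)), collapse = "|"), "|")
  rows <- apply(y, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                         " |"))
  c(header, sep, unname(rows))
}
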