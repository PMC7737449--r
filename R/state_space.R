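#' The five-state ED state space
#'
#' The patient management process is modelled on five states: `triage` (1),
#' `physician` (2, physician management), `observation` (3, observation room /
#' waiting for admission), `discharge` (4) and `admission` (5). States 4 and 5
#' are absorbing. Seven transitions are allowed: 1->2 (seen by physician),
#' 1->4 (left from triage without being seen), 2->3, 2->4, 2->5, 3->4 and
#' 3->5. The transition graph is acyclic.
#'
#' @return An object of class `ed_state_space`: a list with elements
#'   `states` (named integer vector), `transitions` (character vector of
#'   `"i->j"` keys), `absorbing` (integer indices) and `transient`
#'   (integer indices).
#' @examples
#' ed_state_space()
#' @export
ed_state_space <- function() {
  ss <- list(
    states = c(triage = 1L, physician = 2L, observation = 3L,
               discharge = 4L, admission = 5L),
    transitions = c("1->2", "1->4", "2->3", "2->4", "2->5", "3->4", "3->5"),
    absorbing = c(4L, 5L),
    transient = c(1L, 2L, 3L)
  )
  class(ss) <- "ed_state_space"
  ss
}

#' @export
print.ed_state_space <- function(x, ...) {
  cat("ED state space: 5 states, 7 transitions\n")
  cat("  states:    ", paste0(x$states, "=", names(x$states), collapse = ", "), "\n")
  cat("  absorbing: ", paste(names(x$states)[x$absorbing], collapse = ", "), "\n")
  cat("  transitions:", paste(x$transitions, collapse = ", "), "\n")
  invisible(x)
}

# split "i->j" keys into a 2-column integer matrix
transition_pairs <- function(keys = ed_state_space()$transitions) {
  m <- do.call(rbind, strsplit(keys, "->", fixed = TRUE))
  matrix(as.integer(m), ncol = 2L, dimnames = list(keys, c("from", "to")))
}

# resolve a state given as index or label to an integer index
resolve_state <- function(state, ss = ed_state_space()) {
  if (is.character(state)) {
    num <- grepl("^[0-9]+$", state)
    idx <- integer(length(state))
    idx[num] <- as.integer(state[num])
    idx[!num] <- unname(ss$states[state[!num]])
    if (anyNA(idx) || any(idx < 1L) || any(idx > 5L)) {
      stop("unknown state: ", paste(state, collapse = ", "), call. = FALSE)
    }
    return(idx)
  }
  state <- as.integer(state)
  if (anyNA(state) || any(state < 1L) || any(state > 5L)) {
    stop("state index must be in 1..5", call. = FALSE)
  }
  state
}

#' Six-hour shift schedule
#'
#' The 24-hour day is partitioned into four six-hour shifts used for
#' piecewise-constant (shift-stratified) transition intensities:
#' night \[0, 6), morning \[6, 12), afternoon \[12, 18) and evening \[18, 24).
#'
#' @return An object of class `ed_shift_schedule` with elements `boundaries`
#'   (`c(0, 6, 12, 18, 24)`) and `labels`
#'   (`c("night", "morning", "afternoon", "evening")`).
#' @seealso [shift_of_clock()]
#' @export
shift_schedule <- function() {
  sched <- list(boundaries = c(0, 6, 12, 18, 24),
                labels = c("night", "morning", "afternoon", "evening"))
  class(sched) <- "ed_shift_schedule"
  sched
}

#' @export
print.ed_shift_schedule <- function(x, ...) {
  iv <- paste0("[", x$boundaries[-5], ",", x$boundaries[-1], ")")
  cat("Shift schedule:", paste(x$labels, iv, collapse = ", "), "\n")
  invisible(x)
}

#' Shift containing a clock time
#'
#' @param clock numeric vector of clock times in decimal hours; values are
#'   reduced modulo 24, so cumulative hours since an epoch are accepted.
#' @param schedule a [shift_schedule()].
#' @return character vector of shift labels.
#' @examples
#' shift_of_clock(c(0, 5.99, 6, 13.5, 23.9, 26))
#' @export
shift_of_clock <- function(clock, schedule = shift_schedule()) {
  h <- clock %% 24
  schedule$labels[findInterval(h, schedule$boundaries,
                               rightmost.closed = FALSE)]
}

# normalize a shift argument (index 1..4 or label) to a label
resolve_shift <- function(shift, schedule = shift_schedule()) {
  if (is.numeric(shift)) {
    if (!shift %in% seq_along(schedule$labels)) {
      stop("shift index must be in 1..", length(schedule$labels), call. = FALSE)
    }
    return(schedule$labels[shift])
  }
  shift <- match.arg(shift, schedule$labels)
  shift
}
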