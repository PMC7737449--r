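#' Generator (intensity) matrix of the five-state process
#'
#' Builds the 5x5 generator `Q` for a given covariate vector and, for
#' shift-stratified models, a given shift. Off-diagonal entries are
#' `Q[i, j] = q_ij * exp(sum_c beta_ijc * z_c)` for allowed transitions and 0
#' otherwise; diagonals make rows sum to zero; rows of the absorbing states
#' (discharge, admission) are identically zero.
#'
#' @param model an [rate_model()].
#' @param covariates named numeric vector supplying a value for every
#'   covariate named in the model's effects (e.g.
#'   `c(triage_level = 3, age_group = 1)`). `NULL` means all covariates at 0,
#'   i.e. the baseline intensities.
#' @param shift shift label or index (1 = night .. 4 = evening); required
#'   meaningfully only for models with shift-specific baselines. `NULL` uses
#'   the pooled baseline.
#' @return 5x5 numeric matrix with state-name dimnames.
#' @examples
#' Q <- generator_matrix(ed_reference_model())
#' rowSums(Q)   # all zero
#' @export
generator_matrix <- function(model, covariates = NULL, shift = NULL) {
  stopifnot(inherits(model, "ed_rate_model"))
  ss <- model$state_space
  base <- model$baseline
  if (!is.null(shift)) {
    if (is.null(model$shifts)) {
      warning("model has no shift-specific rates; using pooled baseline")
    } else {
      base <- model$shifts[[resolve_shift(shift)]]
    }
  }
  needed <- effect_covariates(model)
  if (is.null(covariates)) {
    z <- stats::setNames(numeric(length(needed)), needed)
  } else {
    if (is.null(names(covariates))) stop("`covariates` must be named")
    unknown <- setdiff(names(covariates), needed)
    if (length(unknown)) {
      stop("unknown covariate name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(needed, names(covariates))
    if (length(missing)) {
      stop("covariates must supply a value for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    z <- covariates
  }
  rates <- vapply(names(base), function(k) {
    b <- model$effects[[k]]
    r <- base[[k]]
    if (!is.null(b)) r <- r * exp(sum(b * z[names(b)]))
    r
  }, 0)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("corrupted model: nonpositive or non-finite resulting rate")
  }
  n <- length(ss$states)
  Q <- matrix(0, n, n, dimnames = list(names(ss$states), names(ss$states)))
  pairs <- transition_pairs(ss$transitions)
  Q[pairs] <- rates[rownames(pairs)]
  diag(Q) <- -rowSums(Q)
  Q[ss$absorbing, ] <- 0
  Q
}

#' Embedded jump-chain probabilities from a state
#'
#' Conditional on leaving state `i`, the destination is `j` with probability
#' `Q[i, j] / (-Q[i, i])` (the competing exponential clocks of the allowed
#' transitions).
#'
#' @param Q generator matrix from [generator_matrix()].
#' @param state transient state index or label.
#' @return named numeric vector of destination probabilities (over
#'   destinations with positive intensity); sums to 1.
#' @examples
#' embedded_jump_probs(generator_matrix(ed_reference_model()), "physician")
#' @export
embedded_jump_probs <- function(Q, state) {
  i <- resolve_state(state)
  if (i %in% ed_state_space()$absorbing) {
    stop("state ", state, " is absorbing: no jump distribution",
         call. = FALSE)
  }
  out <- Q[i, -i]
  r <- -Q[i, i]
  if (r <= 0) stop("state has zero exit rate", call. = FALSE)
  p <- out[out > 0] / r
  p
}

#' Sojourn-time summaries for a transient state
#'
#' The waiting time in a transient state is exponential with rate equal to
#' the state's total exit rate `r = -Q[i, i]` (the sum of the competing
#' transition intensities). Returns that rate together with the mean `1/r`
#' and the median `log(2)/r`, in hours. Note the distinction from the
#' per-transition reciprocal `1/q_ij`, which is the mean waiting time a
#' single transition would have in isolation; for competing risks the
#' realized sojourn is governed by the total exit rate.
#'
#' @inheritParams embedded_jump_probs
#' @return list with elements `rate`, `mean`, `median` (hours).
#' @examples
#' sojourn_stats(generator_matrix(ed_reference_model()), "triage")
#' @export
sojourn_stats <- function(Q, state) {
  i <- resolve_state(state)
  if (i %in% ed_state_space()$absorbing) {
    stop("state ", state, " is absorbing: infinite sojourn", call. = FALSE)
  }
  r <- -Q[i, i]
  list(rate = r, mean = 1 / r, median = log(2) / r)
}

#' First-passage (absorption) probabilities
#'
#' Probability that the process started in `start` is eventually absorbed in
#' discharge vs admission. The transition graph is acyclic, so the first
#' passage probabilities are solved exactly by back-substitution over the
#' embedded jump chain, visiting transient states in reverse topological
#' order (observation, physician, triage).
#'
#' @inheritParams embedded_jump_probs
#' @param start starting state index or label (any state).
#' @return named numeric vector `c(discharge = , admission = )`; sums to 1.
#' @examples
#' absorption_probabilities(generator_matrix(ed_reference_model()), "triage")
#' @export
absorption_probabilities <- function(Q, start = "triage") {
  ss <- ed_state_space()
  s0 <- resolve_state(start)
  n <- length(ss$states)
  A <- matrix(0, n, 2, dimnames = list(names(ss$states),
                                       names(ss$states)[ss$absorbing]))
  A[ss$absorbing, ] <- diag(2)
  for (i in rev(ss$transient)) {      # 3, 2, 1: reverse topological order
    p <- embedded_jump_probs(Q, i)
    dest <- resolve_state(names(p))
    A[i, ] <- colSums(p * A[dest, , drop = FALSE])
  }
  A[s0, ]
}

#' Transition probability matrix P(t)
#'
#' `P(t) = expm(Q t)`, computed by scaling-and-squaring on the full 5x5
#' generator. Rows sum to 1; `P[i, j](t)` is the probability of occupying
#' state `j` a time `t` (hours) after entering state `i`.
#'
#' @inheritParams embedded_jump_probs
#' @param t nonnegative time in hours.
#' @return 5x5 stochastic matrix.
#' @examples
#' transition_probability(generator_matrix(ed_reference_model()), 6)["triage", ]
#' @export
transition_probability <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("`t` must be a single nonnegative number of hours", call. = FALSE)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  P
}

#' Expected hourly movement counts in a steady ED
#'
#' With `n_i` patients held in state `i` of a steady system, the expected
#' number of `i -> j` movements per hour is `q_ij * n_i`, reported rounded to
#' integer (half away from zero). Transitions out of states not present in
#' `occupancy` are omitted, e.g. triage outflows are not reported unless a
#' triage occupancy is supplied.
#'
#' @param model an [rate_model()]; baseline (covariate-reference) intensities
#'   are used.
#' @param occupancy named nonnegative vector of patient counts by state label
#'   or index, e.g. `c(physician = 60, observation = 100)`.
#' @return named integer vector keyed by `"i->j"`.
#' @examples
#' steady_flow_counts(ed_reference_model(),
#'                    c(physician = 60, observation = 100))
#' @export
steady_flow_counts <- function(model, occupancy) {
  stopifnot(inherits(model, "ed_rate_model"))
  if (length(occupancy) && (is.null(names(occupancy)) || any(occupancy < 0))) {
    stop("`occupancy` must be a named, nonnegative vector", call. = FALSE)
  }
  occ_idx <- resolve_state(names(occupancy))
  pairs <- transition_pairs(names(model$baseline))
  keep <- pairs[, "from"] %in% occ_idx
  keys <- rownames(pairs)[keep]
  counts <- vapply(keys, function(k) {
    n_i <- occupancy[[match(pairs[k, "from"], occ_idx)]]
    round_half_away(model$baseline[[k]] * n_i)
  }, 0)
  stats::setNames(as.integer(counts), keys)
}

round_half_away <- function(x) trunc(x + 0.5 * sign(x))
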