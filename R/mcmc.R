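#' Bayesian estimation by random-walk Metropolis
#'
#' Samples the posterior of the transition intensities (and covariate
#' log-coefficients, when requested) under the exact-observation likelihood,
#' with Metropolis-within-Gibbs random-walk updates on the log-rate scale.
#' Proposal scales are adapted towards a ~0.44 per-component acceptance rate
#' during burn-in only, so the retained chain is a valid Markov chain.
#'
#' Priors default to vague normals on the log rates (mean 0, sd 10). A
#' per-transition override `priors[["3->5"]] = list(type = "gamma",
#' shape = a, rate = b)` places a Gamma(a, b) prior on the natural rate
#' scale (the log-scale Jacobian is included), for which the posterior given
#' `N` events and person-time `T` is the conjugate Gamma(a + N, b + T).
#' Normal overrides use `list(type = "normal", mean =, sd =)`.
#'
#' @param stats an [extract_stats()] result.
#' @param n_iter total iterations (must exceed `burn_in`).
#' @param burn_in iterations discarded (and used for adaptation).
#' @param seed integer seed; fixed seed gives identical chains.
#' @param priors optional named list of per-transition prior overrides.
#' @param covariates optional covariate names: adds `beta` parameters with
#'   normal(0, 10) priors for every modelled transition.
#' @param shift optional shift restriction, as in [fit_mle()].
#' @return An `ed_fit` with `method = "mcmc"`: `estimate` is the posterior
#'   median, `lower`/`upper` the central 95% credible interval;
#'   `diagnostics` carries per-parameter acceptance rates (a warning is
#'   issued if any falls outside [0.1, 0.6] after adaptation) and the chain
#'   dimensions; element `draws` holds the retained posterior draws
#'   (rates and RRs on their natural scales).
#' @export
fit_mcmc <- function(stats, n_iter = 6000, burn_in = 2000, seed = NULL,
                     priors = NULL, covariates = NULL, shift = NULL) {
  stopifnot(inherits(stats, "ed_suffstats"), n_iter > burn_in, burn_in >= 1)
  if (!is.null(shift)) stats <- subset_stats(stats, shift)
  if (!is.null(seed)) set.seed(seed)
  keys <- ed_state_space()$transitions
  pairs <- transition_pairs(keys)
  N <- stats$n_events[keys]
  T_i <- stats::setNames(stats$person_time[as.character(pairs[, "from"])],
                         keys)

  # per-transition data for the covariate likelihood
  cov_data <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(stats$spells))
    if (length(miss)) stop("spells lack covariate column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    cov_data <- lapply(keys, function(k) {
      sub <- stats$spells[stats$spells$state == pairs[k, "from"], ,
                          drop = FALSE]
      list(y = as.integer(sub$dest == pairs[k, "to"]), t = sub$sojourn,
           Z = as.matrix(sub[covariates]))
    })
    names(cov_data) <- keys
  }

  log_prior <- function(k, logq) {
    pr <- priors[[k]]
    if (is.null(pr) || identical(pr$type, "normal")) {
      m <- pr$mean %||% 0; s <- pr$sd %||% 10
      stats::dnorm(logq, m, s, log = TRUE)
    } else if (identical(pr$type, "gamma")) {
      # Gamma(shape, rate) on q, plus the dq/dlogq = q Jacobian
      pr$shape * logq - pr$rate * exp(logq)
    } else stop("unknown prior type: ", pr$type, call. = FALSE)
  }

  # parameter vector: log q per transition, then betas per transition
  par_names <- keys
  if (!is.null(covariates)) {
    par_names <- c(par_names, as.vector(outer(covariates, keys,
                                              function(cv, k) paste0(k, ":", cv))))
  }
  npar <- length(par_names)
  theta <- numeric(npar)
  names(theta) <- par_names
  theta[keys] <- log((N + 0.5) / pmax(T_i, 1e-12))

  # log target contribution of one transition given the current theta
  comp_loglik <- function(k, th) {
    if (is.null(cov_data)) {
      q <- exp(th[[k]])
      N[[k]] * th[[k]] - q * T_i[[k]]
    } else {
      d <- cov_data[[k]]
      beta <- th[paste0(k, ":", covariates)]
      lin <- th[[k]] + drop(d$Z %*% beta)
      sum(d$y * lin) - sum(d$t * exp(lin))
    }
  }
  comp_target <- function(k, th) {
    lp <- comp_loglik(k, th) + log_prior(k, th[[k]])
    if (!is.null(covariates)) {
      lp <- lp + sum(stats::dnorm(th[paste0(k, ":", covariates)], 0, 10,
                                  log = TRUE))
    }
    lp
  }
  # transition whose likelihood a parameter touches
  par_key <- sub(":.*$", "", par_names)

  prop_sd <- rep(0.5, npar)
  acc <- integer(npar)
  acc_window <- integer(npar)
  n_keep <- n_iter - burn_in
  draws <- matrix(NA_real_, n_keep, npar,
                  dimnames = list(NULL, par_names))
  cur_target <- vapply(keys, comp_target, 0, th = theta)

  for (it in seq_len(n_iter)) {
    for (p in seq_len(npar)) {
      k <- par_key[p]
      cand <- theta
      cand[p] <- cand[p] + stats::rnorm(1, 0, prop_sd[p])
      new_t <- comp_target(k, cand)
      if (log(stats::runif(1)) < new_t - cur_target[[k]]) {
        theta <- cand
        cur_target[[k]] <- new_t
        acc[p] <- acc[p] + 1L
        acc_window[p] <- acc_window[p] + 1L
      }
    }
    if (it <= burn_in && it %% 50 == 0) {
      rate <- acc_window / 50
      prop_sd <- pmin(pmax(prop_sd * exp(rate - 0.44), 1e-3), 10)
      acc_window[] <- 0L
    }
    if (it > burn_in) draws[it - burn_in, ] <- theta
  }

  acc_rate <- acc / n_iter
  names(acc_rate) <- par_names
  if (any(acc_rate < 0.1 | acc_rate > 0.6)) {
    warning("MCMC acceptance rate outside [0.1, 0.6] for: ",
            paste(par_names[acc_rate < 0.1 | acc_rate > 0.6],
                  collapse = ", "))
  }

  qs <- apply(exp(draws[, keys, drop = FALSE]), 2, stats::quantile,
              probs = c(0.5, 0.025, 0.975), names = FALSE)
  rates <- data.frame(
    transition = keys,
    estimate = qs[1, ], lower = qs[2, ], upper = qs[3, ],
    n_events = unname(N), person_time = unname(T_i),
    flagged = unname(N == 0), stringsAsFactors = FALSE
  )
  rr <- NULL
  if (!is.null(covariates)) {
    bcols <- setdiff(par_names, keys)
    bq <- apply(exp(draws[, bcols, drop = FALSE]), 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975), names = FALSE)
    rr <- data.frame(
      transition = sub(":.*$", "", bcols),
      covariate = sub("^.*:", "", bcols),
      rr = bq[1, ], lower = bq[2, ], upper = bq[3, ],
      beta = log(bq[1, ]), se = NA_real_, flagged = FALSE,
      stringsAsFactors = FALSE
    )
  }
  med <- theta
  med[] <- apply(draws, 2, stats::median)
  ll <- sum(vapply(keys, comp_loglik, 0, th = med))
  structure(list(rates = rates, rr = rr, loglik = ll, method = "mcmc",
                 shift = if (!is.null(shift)) resolve_shift(shift),
                 diagnostics = list(n_iter = n_iter, burn_in = burn_in,
                                    acceptance = acc_rate,
                                    n_patients = stats$n_patients),
                 draws = exp(draws)),
            class = "ed_fit")
}
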