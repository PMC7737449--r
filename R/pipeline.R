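#' Descriptive statistics of a cohort
#'
#' Median and interquartile range (Q3 - Q1, linear interpolation) of the
#' between-state time segments — triage to physician, physician to
#' observation, physician directly to discharge/admission, observation to
#' discharge/admission, triage directly to departure, and total length of
#' stay — plus covariate frequency tables and the disposition split.
#'
#' @param records cohort data.frame in the [generate_cohort()] schema.
#' @return list of class `ed_describe` with elements `time_table`
#'   (data.frame: `segment`, `n`, `median`, `iqr`, hours), `covariates`
#'   (named list of frequency data.frames) and `disposition` (named
#'   proportions).
#' @export
describe_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("empty cohort", call. = FALSE)
  }
  tp <- records$t_physician_h
  to <- records$t_observation_h
  td <- records$t_departure_h
  adm <- records$disposition == "admission"
  seg <- list(
    triage_to_physician = tp,
    physician_to_observation = (to - tp),
    triage_to_departure = td[is.na(tp)],
    physician_to_discharge = (td - tp)[!is.na(tp) & is.na(to) & !adm],
    observation_to_discharge = (td - to)[!is.na(to) & !adm],
    physician_to_admission = (td - tp)[!is.na(tp) & is.na(to) & adm],
    observation_to_admission = (td - to)[!is.na(to) & adm],
    total_length_of_stay = td
  )
  time_table <- do.call(rbind, lapply(names(seg), function(nm) {
    x <- seg[[nm]][!is.na(seg[[nm]])]
    data.frame(segment = nm, n = length(x),
               median = if (length(x)) stats::median(x) else NA_real_,
               iqr = if (length(x)) unname(diff(stats::quantile(x, c(.25, .75))))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  covs <- list()
  for (cv in intersect(c("triage_level", "age_group", "category"),
                       names(records))) {
    tb <- table(records[[cv]])
    covs[[cv]] <- data.frame(level = names(tb), n = as.integer(tb),
                             proportion = as.numeric(tb) / nrow(records),
                             stringsAsFactors = FALSE)
  }
  dispo <- table(records$disposition) / nrow(records)
  structure(list(time_table = time_table, covariates = covs,
                 disposition = c(dispo), n_patients = nrow(records)),
            class = "ed_describe")
}

#' @export
print.ed_describe <- function(x, digits = 3, ...) {
  cat("Cohort of", x$n_patients, "patients\n")
  cat("Disposition:", paste0(names(x$disposition), " ",
                             signif(100 * x$disposition, digits), "%",
                             collapse = ", "), "\n")
  tab <- x$time_table
  tab$median <- signif(tab$median, digits)
  tab$iqr <- signif(tab$iqr, digits)
  cat("Time segments (hours, median / IQR):\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: where to read or simulate the
#' cohort, which estimator to use, whether to stratify by shift, which
#' covariates to model, and the seed making the run reproducible.
#'
#' @param output_dir directory for the artifact bundle (created if absent).
#' @param input optional cohort CSV; `NULL` simulates `n_patients` from
#'   `model` instead.
#' @param n_patients cohort size when simulating.
#' @param model an [rate_model()], a model-JSON path, or `NULL` for
#'   [ed_reference_model()].
#' @param estimator `"mle"` or `"mcmc"`.
#' @param covariates optional covariate names for [fit_covariates()].
#' @param shifts logical: shift-stratified estimation and prediction?
#' @param horizon prediction horizon in hours.
#' @param seed integer seed for the whole run.
#' @param mcmc list of MCMC settings (`n_iter`, `burn_in`).
#' @param log_level `"DEBUG"`, `"INFO"` or `"WARNING"`.
#' @return list of class `ed_pipeline_config`.
#' @export
pipeline_config <- function(output_dir, input = NULL, n_patients = 1000,
                            model = NULL, estimator = c("mle", "mcmc"),
                            covariates = NULL, shifts = FALSE, horizon = 6,
                            seed = 1L, mcmc = list(n_iter = 6000,
                                                   burn_in = 2000),
                            log_level = c("INFO", "DEBUG", "WARNING")) {
  estimator <- match.arg(estimator)
  log_level <- match.arg(log_level)
  if (is.null(model)) model <- ed_reference_model()
  if (is.character(model)) model <- read_rate_model(model)
  stopifnot(inherits(model, "ed_rate_model"), is.numeric(seed),
            seed == round(seed), horizon > 0, n_patients > 0)
  structure(list(output_dir = output_dir, input = input,
                 n_patients = as.integer(n_patients), model = model,
                 estimator = estimator, covariates = covariates,
                 shifts = isTRUE(shifts), horizon = horizon,
                 seed = as.integer(seed), mcmc = mcmc,
                 log_level = log_level),
            class = "ed_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; `model` may
#' be a path to a model JSON.
#'
#' @param path YAML file.
#' @return an `ed_pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, y)
}

pipeline_log <- function(level, msg, config, logfile = NULL) {
  levels <- c(DEBUG = 1, INFO = 2, WARNING = 3)
  line <- sprintf("[%s] %s", level, msg)
  if (levels[level] >= levels[config$log_level]) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full simulate/describe/fit/predict pipeline
#'
#' Executes the stages in order — obtain the cohort (read `input` or
#' simulate), descriptive statistics, intensity estimation (MLE or MCMC,
#' optionally shift-stratified and/or with covariates), predictive occupancy
#' curve from the fitted rates, movement report — writing each artifact to
#' `output_dir` plus a run manifest (config echo, seed, package and R
#' versions, stage timings). A failing stage aborts with the stage named.
#' Runs are idempotent given the same seed: the fit JSON is byte-identical
#' across repeats.
#'
#' @param config an [pipeline_config()] (or a YAML path).
#' @return invisibly, a list with the artifact `paths` and the in-memory
#'   `cohort`, `describe`, `fit`, `curve` and `report` objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "ed_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$output_dir, "run.log")
  cat("", file = logfile)
  paths <- list()
  timings <- list()
  stage <- function(name, expr) {
    pipeline_log("INFO", paste("stage:", name), config, logfile)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      pipeline_log("WARNING", conditionMessage(e), config, logfile)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- stage("cohort", {
    if (!is.null(config$input)) {
      read_cohort(config$input)
    } else {
      p <- file.path(config$output_dir, "cohort.csv")
      coh <- generate_cohort(cohort_config(config$n_patients,
                                           model = config$model,
                                           seed = config$seed), path = p)
      paths$cohort <- p
      coh
    }
  })

  desc <- stage("describe", describe_cohort(cohort))
  paths$describe <- file.path(config$output_dir, "describe.md")
  writeLines(c("## Time segments (hours)",
               report_markdown(desc$time_table),
               "", "## Disposition",
               report_markdown(data.frame(disposition = names(desc$disposition),
                                          proportion = as.numeric(desc$disposition)))),
             paths$describe)

  fit <- stage("fit", {
    sched <- if (config$shifts) shift_schedule()
    st <- extract_stats(cohort, schedule = sched)
    if (config$shifts) {
      fit_shift_model(st, covariates = config$covariates)
    } else if (config$estimator == "mcmc") {
      fit_mcmc(st, n_iter = config$mcmc$n_iter %||% 6000,
               burn_in = config$mcmc$burn_in %||% 2000,
               seed = config$seed, covariates = config$covariates)
    } else if (!is.null(config$covariates)) {
      fit_covariates(st, config$covariates)
    } else {
      fit_mle(st)
    }
  })
  paths$fit <- file.path(config$output_dir, "fit.json")
  write_fit_json(fit, paths$fit, seed = config$seed)

  curve <- stage("predict", {
    fitted_model <- fit_to_model(fit, config$model)
    occupancy(fitted_model, horizon = config$horizon,
              entry_clock = if (config$shifts) 0)
  })
  paths$occupancy <- file.path(config$output_dir, "occupancy.csv")
  utils::write.csv(as.data.frame(curve), paths$occupancy, row.names = FALSE)

  report <- stage("report", {
    movement_report(fit_to_model(fit, config$model))
  })
  paths$report <- file.path(config$output_dir, "report.md")
  writeLines(c("## Movement rates and expected hourly counts (steady ED)",
               report_markdown(report)), paths$report)

  paths$manifest <- file.path(config$output_dir, "manifest.json")
  manifest <- list(
    seed = config$seed,
    estimator = config$estimator,
    shifts = config$shifts,
    covariates = config$covariates,
    n_patients = nrow(cohort),
    horizon = config$horizon,
    input = config$input,
    versions = list(edflow = as.character(utils::packageVersion("edflow")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timings_s = timings
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  pipeline_log("INFO", paste("done:", length(paths), "artifacts in",
                             config$output_dir), config, logfile)
  invisible(list(paths = paths, cohort = cohort, describe = desc, fit = fit,
                 curve = curve, report = report))
}

# rebuild a rate model from fitted estimates (per shift when shift-fit),
# keeping zero-event transitions at a tiny positive floor so the generator
# stays valid
fit_to_model <- function(fit, template) {
  rates_of <- function(f) {
    q <- stats::setNames(f$rates$estimate, f$rates$transition)
    q[!is.finite(q) | q <= 0] <- 1e-8
    q
  }
  if (inherits(fit, "ed_shift_fit")) {
    rate_model(rates_of(fit[[1]]),
               shifts = lapply(unclass(fit), rates_of))
  } else {
    rate_model(rates_of(fit))
  }
}

#' Write a fit result as JSON
#'
#' @param fit an `ed_fit` or `ed_shift_fit`.
#' @param path output path.
#' @param seed optional seed echoed into the JSON.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  as_obj <- function(f) {
    list(method = f$method, shift = f$shift, rates = f$rates, rr = f$rr,
         loglik = f$loglik,
         diagnostics = f$diagnostics[setdiff(names(f$diagnostics),
                                             "acceptance")],
         acceptance = if (!is.null(f$diagnostics$acceptance))
           as.list(f$diagnostics$acceptance))
  }
  obj <- if (inherits(fit, "ed_shift_fit")) {
    list(kind = "shift_fit", shifts = lapply(unclass(fit), as_obj),
         seed = seed)
  } else {
    c(as_obj(fit), list(seed = seed))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
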