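#' Read concentration-time data from CSV
#'
#' Expects columns `subject_id`, `time_h`, `conc_mg_L` and optionally
#' `dose_number`. Returns one [observed_series()] per subject, in file
#' order. Malformed input raises an error naming the offending column or
#' line.
#'
#' @param path CSV file path.
#' @param loq Optional LOQ to record on every series.
#' @return Named list of [observed_series()].
#' @export
read_conc_csv <- function(path, loq = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "time_h", "conc_mg_L")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("no data rows in ", path)
  bad <- which(!is.finite(d$time_h) | !is.finite(d$conc_mg_L))
  if (length(bad))
    stop("non-numeric time/concentration at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- lapply(split(d, factor(d$subject_id, unique(d$subject_id))),
                function(s) {
    s <- s[order(s$time_h), ]
    observed_series(s$time_h, s$conc_mg_L, subject_id = s$subject_id[1],
                    dose_number = if ("dose_number" %in% names(s))
                      s$dose_number else NULL,
                    loq = loq)
  })
  out
}

#' Write an observed series (or list of them) to CSV
#'
#' Emits the same dialect [read_conc_csv()] reads: `subject_id`, `time_h`,
#' `conc_mg_L` and, when present, `dose_number`.
#'
#' @param x An [observed_series()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conc_csv <- function(x, path) {
  if (inherits(x, "observed_series")) x <- list(x)
  d <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a fit as JSON
#'
#' `write_fit_json()` stores the fitted parameters, model kind, metrics,
#' convergence diagnostics and the data the fit used; `read_fit_json()`
#' restores a `pk_fit` object usable by [predict_multidose()] and
#' [predict.pk_fit()].
#'
#' @param fit A `pk_fit`.
#' @param path JSON path.
#' @return `write_fit_json` returns `path` invisibly; `read_fit_json`
#'   returns a `pk_fit`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pk_fit"))
  obj <- list(
    model = fit$model,
    params = as.list(unclass(fit$params)),
    wrss = fit$wrss, fitting_degree = fit$fitting_degree,
    converged = fit$converged, n_irls_rounds = fit$n_irls_rounds,
    start_points_tried = fit$start_points_tried,
    n_below_loq = fit$n_below_loq,
    weighting = unclass(fit$weighting),
    subject_id = fit$data$subject_id,
    times = fit$times, observed = fit$observed, fitted = fit$fitted)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (o$model == "dual_elimination")
    dual_elim_params(o$params$k1, o$params$c_a, o$params$k0_over_v)
  else one_compartment_params(o$params$c0, o$params$k_el)
  w <- weight_config(o$weighting$scheme, o$weighting$floor,
                     o$weighting$max_irls_iterations,
                     o$weighting$irls_tolerance)
  obs <- observed_series(o$times, o$observed, subject_id = o$subject_id)
  structure(list(params = params, model = o$model, wrss = o$wrss,
                 fitting_degree = o$fitting_degree, converged = o$converged,
                 n_irls_rounds = o$n_irls_rounds,
                 start_points_tried = o$start_points_tried,
                 fitted = o$fitted, weights = NULL, residuals = NULL,
                 times = o$times, observed = o$observed,
                 n_below_loq = o$n_below_loq, data = obs, weighting = w,
                 irls_trace = NULL, call = NULL), class = "pk_fit")
}

# --- run configuration ------------------------------------------------------

.config_schema <- list(
  fit = c("weighting", "loq"),
  simulate = c("seed", "proportional_cv", "additive_sd", "truths",
               "regimen", "schedule"),
  predict = c("tau", "n_doses", "c0", "c0_strategy"),
  weighting = c("scheme", "floor", "max_irls_iterations", "irls_tolerance"),
  regimen = c("tau", "n_doses", "c0_increment", "first_dose_start"))

#' Validate a run configuration
#'
#' Checks a configuration list (typically parsed from JSON) against the
#' schema of the given command; unknown keys are rejected so that typos
#' cannot silently change a run.
#'
#' @param config A named list (or path to a JSON file).
#' @param command One of `"fit"`, `"simulate"`, `"predict"`.
#' @return The validated config list, with class `run_config`.
#' @export
run_config <- function(config, command = c("fit", "simulate", "predict")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  allowed <- .config_schema[[command]]
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s) for '", command, "': ",
         paste(unknown, collapse = ", "))
  for (block in intersect(names(config), c("weighting", "regimen"))) {
    bad <- setdiff(names(config[[block]]), .config_schema[[block]])
    if (length(bad))
      stop("unknown config key(s) in '", block, "': ",
           paste(bad, collapse = ", "))
  }
  structure(c(config, list(command = command)), class = "run_config")
}

# write the resolved configuration next to a run's outputs
.write_resolved_config <- function(config, out_dir, name = "config") {
  path <- file.path(out_dir, paste0(name, "_resolved.json"))
  cfg <- config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
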