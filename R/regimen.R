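#' Estimate the per-dose concentration increment C0
#'
#' In a repeated-dose regimen each administration raises the plasma
#' concentration by an increment `c0` that, after the first dose, no longer
#' pays the pre-existing-target binding toll and therefore generally exceeds
#' the first dose's post-binding level `c_a`. Three strategies are offered:
#' \describe{
#'   \item{`from_observed_jumps`}{mean, over doses 2..n, of the 5-min
#'     post-dose concentration minus the immediately preceding pre-dose
#'     trough. Requires multiple-dose observations with dose bookkeeping.}
#'   \item{`equal_to_ca`}{uses the single-dose fit's `c_a` (with a warning:
#'     this ignores the binding loss asymmetry and tends to underpredict).}
#'   \item{`user_supplied`}{passes `value` through.}
#' }
#'
#' @param obs An [observed_series()] with `dose_number` bookkeeping
#'   (required for `from_observed_jumps`).
#' @param regimen A [dose_regimen()] giving the dosing interval.
#' @param strategy Estimation strategy; see Details.
#' @param fit A `pk_fit` (dual-elimination), required for `equal_to_ca`.
#' @param value User-supplied increment, mg/L, for `user_supplied`.
#' @return A list with `c0_increment` (mg/L), `c0_source` (provenance
#'   label), and `n_pairs` (number of trough/peak pairs used, or `NA`).
#' @examples
#' # two jump pairs (10 -> 22) and (12 -> 25) average to 12.5 mg/L
#' obs <- observed_series(times = c(167.9, 168.083, 335.9, 336.083),
#'                        concentrations = c(10, 22, 12, 25),
#'                        dose_number = c(1, 2, 2, 3))
#' estimate_c0(obs, dose_regimen(tau = 168, n_doses = 3))
#' @export
estimate_c0 <- function(obs = NULL, regimen = NULL,
                        strategy = c("from_observed_jumps", "equal_to_ca",
                                     "user_supplied"),
                        fit = NULL, value = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "user_supplied") {
    stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
    return(list(c0_increment = value, c0_source = "user_supplied",
                n_pairs = NA_integer_))
  }
  if (strategy == "equal_to_ca") {
    stopifnot(inherits(fit, "pk_fit"))
    if (fit$model != "dual_elimination")
      stop("equal_to_ca requires a dual-elimination fit")
    warning("using the first-dose post-binding level c_a as the per-dose ",
            "increment; later doses do not pay the pre-existing-target ",
            "binding loss, so this tends to underpredict accumulation")
    return(list(c0_increment = fit$params$c_a, c0_source = "equal_to_ca",
                n_pairs = NA_integer_))
  }
  stopifnot(inherits(obs, "observed_series"),
            inherits(regimen, "dose_regimen"))
  if (is.null(obs$dose_number))
    stop("from_observed_jumps requires dose_number bookkeeping on the series")
  jumps <- c()
  for (k in 2:regimen$n_doses) {
    tk <- (k - 1) * regimen$tau
    pre_i <- which(obs$dose_number == k - 1 & obs$times <= tk + 1e-9)
    post_i <- which(obs$dose_number == k & obs$times >= tk - 1e-9 &
                      obs$times <= tk + 1)
    if (length(pre_i) && length(post_i)) {
      pre <- obs$concentrations[pre_i[which.max(obs$times[pre_i])]]
      post <- obs$concentrations[post_i[which.min(obs$times[post_i])]]
      jumps <- c(jumps, post - pre)
    }
  }
  if (length(jumps) == 0L)
    stop("no paired pre-/post-dose samples found for any dose >= 2")
  list(c0_increment = mean(jumps), c0_source = "from_observed_jumps",
       n_pairs = length(jumps))
}

#' Predict a multiple-dose profile from a single-dose fit
#'
#' Carries the parameters estimated from a subject's single-dose profile
#' into the multiple-dose expression: dose 1 starts at the fitted `c_a`
#' (post-binding), later doses add `c0_increment`, and the steady-state
#' peak/trough follow from the fixed point of the dose-to-dose map. When
#' observations are supplied, per-point relative errors, the weighted
#' residual sum of squares and the goodness of fit of prediction against
#' observation are reported, along with observed steady-state extrema
#' extracted from the sampling design (peak: 5-min post-dose sample of the
#' last dose; trough: last pre-dose sample).
#'
#' @param fit A converged `pk_fit`.
#' @param regimen A [dose_regimen()]; its `c0_increment` is the increment
#'   used (see [estimate_c0()] for ways to choose it).
#' @param obs Optional [observed_series()] of multiple-dose observations
#'   (with `dose_number` bookkeeping for exact trough placement).
#' @param times Prediction times when `obs` is `NULL`; defaults to a dense
#'   grid over the regimen span.
#' @param c0_source Provenance label for the regimen's increment, recorded
#'   in the report.
#' @return An object of class `pk_prediction`: `profile` (data frame of
#'   time, dose_number, predicted, observed, re_pct), `steady_state` (data
#'   frame of predicted/observed peak and trough with RE%), `wrss`,
#'   `fitting_degree`, `c0_source`, `regimen`, `model`.
#' @export
predict_multidose <- function(fit, regimen, obs = NULL, times = NULL,
                              c0_source = "regimen") {
  stopifnot(inherits(fit, "pk_fit"), inherits(regimen, "dose_regimen"))
  if (!fit$converged)
    stop("refusing to predict from an unconverged fit (converged = FALSE); ",
         "refit or inspect irls_trace")
  dual <- fit$model == "dual_elimination"

  if (!is.null(obs)) {
    stopifnot(inherits(obs, "observed_series"))
    times <- obs$times
    dose_number <- obs$dose_number
  } else if (is.null(times)) {
    times <- seq(0, regimen$n_doses * regimen$tau, length.out = 400)
    dose_number <- NULL
  } else dose_number <- NULL

  pred <- if (is.null(dose_number)) {
    predict(fit, times = times, regimen = regimen)
  } else if (dual) {
    # honour bookkeeping: troughs at dose instants belong to the old interval
    starts <- multidose_start_levels(fit$params, regimen)
    local_t <- times - (dose_number - 1) * regimen$tau
    vapply(seq_along(times), function(i)
      interval_solution(starts[dose_number[i]], fit$params, local_t[i]),
      numeric(1))
  } else {
    # classic superposition over the doses given so far per the bookkeeping
    vapply(seq_along(times), function(i) {
      js <- seq_len(min(dose_number[i], regimen$n_doses))
      sum(fit$params$c0 *
            exp(-fit$params$k_el * (times[i] - (js - 1) * regimen$tau)))
    }, numeric(1))
  }

  profile <- data.frame(time_h = times, predicted = pred)
  if (!is.null(dose_number)) profile$dose_number <- dose_number
  w <- NULL
  if (!is.null(obs)) {
    profile$observed <- obs$concentrations
    # RE is undefined at an observed zero (possible late in the last
    # interval when the zero-order sink empties the plasma)
    pos <- obs$concentrations > 0
    profile$re_pct <- NA_real_
    profile$re_pct[pos] <- relative_error(obs$concentrations[pos], pred[pos])
    w <- pk_weights(obs$concentrations, pred, fit$weighting)
  }

  # steady-state extrema: fixed point for the dual model, textbook
  # accumulation for the classic comparator
  if (dual) {
    ss <- steady_state_extrema(fit$params, regimen)
  } else {
    q <- exp(-fit$params$k_el * regimen$tau)
    cmax <- fit$params$c0 / (1 - q)
    ss <- list(c_max_ss = cmax, c_min_ss = cmax - fit$params$c0,
               degenerate = FALSE)
  }
  sstab <- data.frame(metric = c("cmin_ss", "cmax_ss"),
                      predicted = c(ss$c_min_ss, ss$c_max_ss),
                      stringsAsFactors = FALSE)
  if (!is.null(obs) && !is.null(obs$dose_number)) {
    n <- regimen$n_doses
    tn <- (n - 1) * regimen$tau
    peak_i <- which(obs$dose_number == n & obs$times >= tn &
                      obs$times <= tn + 1)
    trough_i <- which(obs$dose_number == n - 1 & obs$times <= tn + 1e-9)
    sstab$observed <- c(
      if (length(trough_i)) obs$concentrations[trough_i[which.max(obs$times[trough_i])]]
      else NA_real_,
      if (length(peak_i)) obs$concentrations[peak_i[which.min(obs$times[peak_i])]]
      else NA_real_)
    sstab$re_pct <- ifelse(is.na(sstab$observed), NA_real_,
                           relative_error(sstab$observed, sstab$predicted))
  }

  structure(list(
    profile = profile, steady_state = sstab,
    wrss = if (is.null(obs)) NA_real_
           else wrss(obs$concentrations, pred, w),
    fitting_degree = if (is.null(obs)) NA_real_
                     else fitting_degree(obs$concentrations, pred, w),
    degenerate_steady_state = ss$degenerate,
    c0_source = c0_source, regimen = regimen, model = fit$model,
    params = fit$params), class = "pk_prediction")
}

#' @export
print.pk_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("Multiple-dose prediction (%s model), c0 source: %s\n",
              gsub("_", "-", x$model), x$c0_source))
  print(x$regimen)
  cat("Steady state:\n")
  print(x$steady_state, digits = digits, row.names = FALSE)
  if (x$degenerate_steady_state)
    cat("  NOTE: degenerate steady state (trough <= 0)\n")
  if (!is.na(x$wrss))
    cat(sprintf("Against observations: WRSS = %s, fitting degree = %s\n",
                format(x$wrss, digits = digits),
                format(x$fitting_degree, digits = digits)))
  invisible(x)
}

#' Flag steady-state prediction errors against a tolerance
#'
#' Checks whether the predicted steady-state trough and peak fall within a
#' relative-error tolerance of their observations (inclusive at the
#' boundary: RE exactly equal to the tolerance passes).
#'
#' @param report A `pk_prediction` with observed steady-state values.
#' @param tolerance_percent Acceptance tolerance for RE, percent
#'   (default 20).
#' @return A data frame with `metric`, `re_pct`, `pass`.
#' @export
within_tolerance_summary <- function(report, tolerance_percent = 20) {
  stopifnot(inherits(report, "pk_prediction"))
  ss <- report$steady_state
  if (is.null(ss$re_pct) || all(is.na(ss$re_pct)))
    stop("report has no observed steady-state values")
  data.frame(metric = ss$metric, re_pct = ss$re_pct,
             pass = ss$re_pct <= tolerance_percent,
             stringsAsFactors = FALSE)
}

#' Write a prediction report to disk
#'
#' Writes the full profile as CSV, the steady-state table as a compact CSV
#' (observed, predicted, RE% with one decimal), and the whole report as
#' JSON. Parameter-like values are rounded to 4 significant figures in the
#' CSVs; the JSON keeps full precision.
#'
#' @param report A `pk_prediction`.
#' @param path_prefix Path prefix; files `<prefix>_profile.csv`,
#'   `<prefix>_steady_state.csv`, `<prefix>.json` are written.
#' @return Invisibly, the vector of paths written.
#' @export
write_prediction_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "pk_prediction"))
  p1 <- paste0(path_prefix, "_profile.csv")
  p2 <- paste0(path_prefix, "_steady_state.csv")
  p3 <- paste0(path_prefix, ".json")
  prof <- report$profile
  prof$predicted <- signif(prof$predicted, 4)
  if (!is.null(prof$re_pct)) prof$re_pct <- round(prof$re_pct, 1)
  utils::write.csv(prof, p1, row.names = FALSE)
  ss <- report$steady_state
  ss$predicted <- signif(ss$predicted, 4)
  if (!is.null(ss$re_pct)) ss$re_pct <- round(ss$re_pct, 1)
  utils::write.csv(ss, p2, row.names = FALSE)
  rep_json <- report
  class(rep_json) <- NULL
  rep_json$regimen <- unclass(rep_json$regimen)
  rep_json$params <- as.list(unclass(rep_json$params))
  jsonlite::write_json(rep_json, p3, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(profile = p1, steady_state = p2, json = p3))
}
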