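#' Fit a pharmacokinetic elimination model to single-dose data
#'
#' Estimates either the dual-elimination model (first-order plus zero-order
#' elimination after an initial target-binding loss) or the classic
#' one-compartment comparator from a subject's single-dose concentration-time
#' profile, by weighted nonlinear least squares. The default weighting uses
#' the reciprocal of the model-predicted concentration; because those weights
#' depend on the fit, the estimation is iteratively reweighted: round 0 is
#' seeded with reciprocal-of-observed weights and each subsequent round
#' refits with weights taken from the previous round's predictions, until the
#' relative parameter change drops below `weighting$irls_tolerance`.
#'
#' Within each round the weighted objective is minimised by bounded
#' Levenberg-Marquardt steps from a deterministic multi-start grid spanning
#' decade ranges of the rate parameters; the best start wins (ties broken by
#' lower `k0_over_v`). The whole procedure is deterministic: identical inputs
#' give an identical fit.
#'
#' @param formula Either a formula such as `conc_mg_L ~ time_h` naming the
#'   concentration and time columns of `data`, or directly a data frame /
#'   [observed_series()] (in which case `data` is ignored and standard column
#'   names `time_h`/`time` and `conc_mg_L`/`conc` are expected).
#' @param data A data frame, when `formula` is a formula.
#' @param model `"dual_elimination"` (default) or `"one_compartment"`.
#' @param weighting A [weight_config()].
#' @param loq Optional lower limit of quantification, mg/L; observations at
#'   or below it (and zeros) are excluded from the objective and counted.
#' @param subject_id Optional subject label override.
#' @return An object of class `pk_fit` with components `params` (a
#'   [dual_elim_params()] or [one_compartment_params()]), `wrss`,
#'   `fitting_degree`, `converged`, `n_irls_rounds`, `start_points_tried`,
#'   `residuals` (weighted), `weights`, `fitted`, `n_below_loq`, `irls_trace`
#'   and the data used. Supports `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot` and `simulate` methods.
#' @examples
#' dog2 <- dual_elim_params(0.0030, 8.45, 0.0032)
#' d <- data.frame(time_h = beagle_schedule_single(),
#'                 conc_mg_L = conc_single_dose(dog2, beagle_schedule_single()))
#' fit <- fit_pk(conc_mg_L ~ time_h, d)
#' coef(fit)
#' @export
fit_pk <- function(formula, data = NULL,
                   model = c("dual_elimination", "one_compartment"),
                   weighting = weight_config(), loq = NULL,
                   subject_id = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(weighting, "weight_config"))
  cl <- match.call()

  obs <- if (inherits(formula, "formula")) {
    stopifnot(is.data.frame(data))
    v <- all.vars(formula)
    if (length(v) != 2) stop("formula must be of the form conc ~ time")
    df <- data.frame(time_h = data[[v[2]]], conc_mg_L = data[[v[1]]])
    if ("subject_id" %in% names(data)) df$subject_id <- data$subject_id
    as_observed_series(df, subject_id = subject_id, loq = loq)
  } else {
    as_observed_series(formula, subject_id = subject_id, loq = loq)
  }
  if (!is.null(loq)) obs$loq <- loq

  # points entering the weighted objective must be positive and above LOQ
  keep <- obs$concentrations > 0
  if (!is.null(obs$loq)) keep <- keep & obs$concentrations >= obs$loq
  n_below_loq <- sum(!keep)
  tt <- obs$times[keep]
  cc <- obs$concentrations[keep]

  min_pts <- if (model == "dual_elimination") 4L else 2L
  if (length(tt) < min_pts)
    stop(sprintf("need at least %d quantifiable points to fit the %s model",
                 min_pts, model))

  eng <- if (model == "dual_elimination") .fit_engine_dual
         else .fit_engine_classic
  res <- .irls(tt, cc, weighting, eng)

  params <- if (model == "dual_elimination")
    dual_elim_params(res$par[["k1"]], res$par[["c_a"]], res$par[["k0_over_v"]])
  else one_compartment_params(res$par[["c0"]], res$par[["k_el"]])

  pred <- .predict_curve(params, tt)
  w <- pk_weights(cc, pred, weighting)
  structure(list(
    params = params, model = model,
    wrss = wrss(cc, pred, w),
    fitting_degree = fitting_degree(cc, pred, w),
    converged = res$converged, n_irls_rounds = res$n_rounds,
    start_points_tried = res$starts_tried,
    fitted = pred, weights = w,
    residuals = sqrt(w) * (cc - pred),
    times = tt, observed = cc,
    n_below_loq = n_below_loq,
    data = obs, weighting = weighting,
    irls_trace = res$trace, call = cl), class = "pk_fit")
}

.predict_curve <- function(params, t) {
  if (inherits(params, "dual_elim_params")) conc_single_dose(params, t)
  else conc_classic(params, t)
}

# IRLS outer loop; `engine(t, c, w, init)` does one weighted fit and returns
# list(par, wrss, starts_tried). `init = NULL` requests the multi-start grid.
.irls <- function(tt, cc, cfg, engine) {
  single_round <- cfg$scheme != "reciprocal_predicted"
  w <- pk_weights(cc, cc, cfg)  # round 0 seed: reciprocal of observed
  fit <- engine(tt, cc, w, init = NULL)
  trace <- data.frame(round = 0L, wrss = fit$wrss)
  converged <- single_round
  n_rounds <- 1L
  if (!single_round) {
    par_old <- fit$par
    for (r in seq_len(cfg$max_irls_iterations)) {
      pred <- fit$predict(fit$par)
      w <- pk_weights(cc, pred, cfg)
      fit <- engine(tt, cc, w, init = fit$par)
      trace <- rbind(trace, data.frame(round = r, wrss = fit$wrss))
      n_rounds <- r + 1L
      rel <- abs(fit$par - par_old) / pmax(abs(par_old), 1e-12)
      if (max(rel) < cfg$irls_tolerance) { converged <- TRUE; break }
      par_old <- fit$par
    }
  }
  list(par = fit$par, converged = converged, n_rounds = n_rounds,
       starts_tried = fit$starts_tried, trace = trace)
}

# one weighted fit of the dual-elimination model by bounded LM,
# multi-start over decades of k1 and k0_over_v when init is NULL
.fit_engine_dual <- function(tt, cc, w, init = NULL) {
  cmax <- max(cc)
  tspan <- max(max(tt), 1)
  lower <- c(k1 = 1e-6, c_a = 1e-9, k0_over_v = 0)
  upper <- c(k1 = 1, c_a = 10 * cmax, k0_over_v = 10 * cmax / tspan)
  predict <- function(p) {
    b <- p[["k0_over_v"]] / p[["k1"]]
    e <- exp(-p[["k1"]] * tt)
    pmax(p[["c_a"]] * e - b * (1 - e), 0)
  }
  resid_fn <- function(p) sqrt(w) * (cc - predict(p))
  starts <- if (is.null(init)) {
    k1s <- 10^seq(-4, -1)
    k0s <- c(1e-8, 0.01, 0.2) * cmax / tspan
    g <- expand.grid(k1 = k1s, k0_over_v = k0s)
    lapply(seq_len(nrow(g)), function(i)
      c(k1 = g$k1[i], c_a = cmax, k0_over_v = g$k0_over_v[i]))
  } else list(init)
  .best_lm(resid_fn, starts, lower, upper, predict,
           tie_on = "k0_over_v")
}

# one weighted fit of the one-compartment model; init grid seeded by
# log-linear regression of log(conc) on time
.fit_engine_classic <- function(tt, cc, w, init = NULL) {
  cmax <- max(cc)
  lower <- c(c0 = 1e-9, k_el = 1e-6)
  upper <- c(c0 = 10 * cmax, k_el = 1)
  predict <- function(p) p[["c0"]] * exp(-p[["k_el"]] * tt)
  resid_fn <- function(p) sqrt(w) * (cc - predict(p))
  starts <- if (is.null(init)) {
    ll <- stats::lm(log(cc) ~ tt)
    k0 <- max(min(-stats::coef(ll)[[2]], 0.5), 1e-5)
    c0 <- exp(stats::coef(ll)[[1]])
    lapply(c(0.25, 1, 4), function(f)
      c(c0 = min(max(c0, 1e-6), 10 * cmax),
        k_el = min(max(k0 * f, 1e-6), 1)))
  } else list(init)
  .best_lm(resid_fn, starts, lower, upper, predict, tie_on = "k_el")
}

.best_lm <- function(resid_fn, starts, lower, upper, predict, tie_on) {
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || ss < best$wrss * (1 - 1e-12) ||
        (abs(ss - best$wrss) <= 1e-12 * max(best$wrss, 1) &&
         fit$par[[tie_on]] < best$par[[tie_on]])) {
      best <- list(par = unlist(fit$par), wrss = ss)
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best$starts_tried <- length(starts)
  best$predict <- predict
  best
}

#' @export
print.pk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("PK fit: %s model, subject '%s'\n",
              gsub("_", "-", x$model), x$data$subject_id))
  print(x$params, digits = digits)
  cat(sprintf("  WRSS = %s, fitting degree = %s (%s weights)\n",
              format(x$wrss, digits = digits),
              format(x$fitting_degree, digits = digits),
              x$weighting$scheme))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' @export
summary.pk_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pk_fit")
}

#' @export
print.summary.pk_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  %d observations (%d excluded below LOQ/zero)\n",
              length(f$observed), f$n_below_loq))
  cat(sprintf("  IRLS rounds: %d (converged: %s); starts tried: %d\n",
              f$n_irls_rounds, f$converged, f$start_points_tried))
  cat("  Weighted residuals:\n")
  print(summary(f$residuals), digits = digits)
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) as.vector(object$params)

#' @export
fitted.pk_fit <- function(object, ...) object$fitted

#' @export
residuals.pk_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  if (type == "weighted") object$residuals
  else object$observed - object$fitted
}

#' Predict concentrations from a fitted PK model
#'
#' @param object A `pk_fit`.
#' @param times Times (h from first dose) at which to predict; defaults to
#'   the fitted data's times.
#' @param regimen Optional [dose_regimen()] for a multiple-dose prediction;
#'   `NULL` predicts the single-dose curve.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations, mg/L.
#' @export
predict.pk_fit <- function(object, times = NULL, regimen = NULL, ...) {
  if (is.null(times)) times <- object$times
  if (is.null(regimen)) return(.predict_curve(object$params, times))
  if (object$model == "dual_elimination")
    conc_multidose(object$params, regimen, times)
  else conc_classic(object$params, times, regimen = regimen)
}

#' Plot observed data with the fitted curve
#'
#' Observed concentrations (points) with the fitted model curve on a
#' logarithmic concentration axis, the usual display for elimination-phase
#' diagnostics.
#'
#' @param x A `pk_fit`.
#' @param log Axis log spec passed to [graphics::plot()]; default `"y"`.
#' @param ... Further graphical parameters.
#' @export
plot.pk_fit <- function(x, log = "y", ...) {
  tgrid <- seq(min(x$times), max(x$times), length.out = 400)
  pred <- .predict_curve(x$params, tgrid)
  ylim <- range(c(x$observed, pred[pred > 0]))
  graphics::plot(x$times, x$observed, log = log, xlab = "Time (h)",
                 ylab = "Concentration (mg/L)", ylim = ylim,
                 main = sprintf("%s fit: %s", gsub("_", "-", x$model),
                                x$data$subject_id), ...)
  ok <- if (grepl("y", log)) pred > 0 else rep(TRUE, length(pred))
  graphics::lines(tgrid[ok], pred[ok], col = "purple", lwd = 2)
  invisible(x)
}

#' Simulate concentration series from a fitted model
#'
#' Draws noisy replicates of the fitted curve at the original (or given)
#' sampling times using the package's measurement-error model.
#'
#' @param object A `pk_fit`.
#' @param nsim Number of replicate series.
#' @param seed RNG seed (integer) for reproducibility.
#' @param schedule Sampling times, h; defaults to the fitted data's times.
#' @param error An [error_model()].
#' @param ... Unused.
#' @return A list of [observed_series()] of length `nsim`.
#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = NULL,
                            schedule = NULL, error = error_model(), ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- object$times
  truth <- object$params
  if (object$model == "one_compartment")
    truth <- dual_elim_params(k1 = object$params$k_el,
                              c_a = object$params$c0, k0_over_v = 0)
  lapply(seq_len(nsim), function(i)
    generate_single_dose(truth, schedule,
                         error_model(error$proportional_cv,
                                     error$additive_sd, seed = NULL),
                         subject_id = sprintf("%s_sim%d",
                                              object$data$subject_id, i)))
}

#' Compare two fits of the same data
#'
#' Side-by-side weighted residual sum of squares, goodness of fit and
#' parameter values for two models fitted to the same observations; the
#' model with the lower WRSS is flagged as the winner.
#'
#' @param fit_a,fit_b `pk_fit` objects fitted to the same series under the
#'   same weighting scheme.
#' @return An object of class `pk_model_comparison` wrapping a data frame
#'   (one row per model) with columns `model`, `wrss`, `fitting_degree`,
#'   `n_params`, `winner`.
#' @export
compare_pk_fits <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "pk_fit"), inherits(fit_b, "pk_fit"))
  if (!isTRUE(all.equal(fit_a$times, fit_b$times)) ||
      !isTRUE(all.equal(fit_a$observed, fit_b$observed)))
    stop("fits were not produced from the same observations")
  if (fit_a$weighting$scheme != fit_b$weighting$scheme)
    stop("fits use different weighting schemes")
  tab <- data.frame(
    model = c(fit_a$model, fit_b$model),
    wrss = c(fit_a$wrss, fit_b$wrss),
    fitting_degree = c(fit_a$fitting_degree, fit_b$fitting_degree),
    n_params = c(length(as.vector(fit_a$params)),
                 length(as.vector(fit_b$params))),
    stringsAsFactors = FALSE)
  tab$winner <- tab$wrss == min(tab$wrss)
  structure(list(table = tab, subject_id = fit_a$data$subject_id,
                 scheme = fit_a$weighting$scheme),
            class = "pk_model_comparison")
}

#' @export
print.pk_model_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Model comparison, subject '%s' (%s weights)\n",
              x$subject_id, x$scheme))
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write / read a model-comparison table as CSV
#'
#' Numbers are serialised at full double precision so that the table
#' round-trips losslessly.
#'
#' @param x A `pk_model_comparison`.
#' @param path Output CSV path.
#' @return `write_comparison_csv` returns `path` invisibly;
#'   `read_comparison_csv` returns the comparison table as a data frame.
#' @export
write_comparison_csv <- function(x, path) {
  stopifnot(inherits(x, "pk_model_comparison"))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(col) sprintf("%.17g", col))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
read_comparison_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
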