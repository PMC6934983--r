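#' Measurement-error model for simulated concentrations
#'
#' Multiplicative lognormal noise with coefficient of variation
#' `proportional_cv` (the lognormal is parameterised to have mean 1, so
#' noisy values are unbiased around the model curve) plus additive Gaussian
#' noise of standard deviation `additive_sd`; results are truncated at 0.
#' The defaults (5% proportional, no additive term) mimic the repeatability
#' of a duplicate-measured ELISA.
#'
#' @param proportional_cv Proportional CV as a fraction (>= 0).
#' @param additive_sd Additive noise SD, mg/L (>= 0).
#' @param seed Optional integer seed applied before drawing.
#' @return An object of class `error_model`.
#' @export
error_model <- function(proportional_cv = 0.05, additive_sd = 0,
                        seed = NULL) {
  stopifnot(proportional_cv >= 0, additive_sd >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd, seed = seed),
            class = "error_model")
}

.apply_noise <- function(conc, error) {
  if (!is.null(error$seed)) set.seed(error$seed)
  out <- conc
  if (error$proportional_cv > 0) {
    sdlog <- sqrt(log(1 + error$proportional_cv^2))
    out <- out * stats::rlnorm(length(out), meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
  }
  if (error$additive_sd > 0)
    out <- out + stats::rnorm(length(out), 0, error$additive_sd)
  pmax(out, 0)
}

#' Simulate a single-dose concentration series
#'
#' Evaluates the dual-elimination curve at the sampling schedule and
#' perturbs it with the measurement-error model.
#'
#' @param truth A [dual_elim_params()] object (the generating parameters).
#' @param schedule Sampling times, h; defaults to the reference 19-point
#'   beagle schedule ([beagle_schedule_single()]).
#' @param error An [error_model()].
#' @param subject_id Subject label.
#' @param loq Optional LOQ recorded on the series (default 0.025 mg/L, a
#'   typical ELISA quantification limit; censoring is left to the fitter).
#' @return An [observed_series()].
#' @export
generate_single_dose <- function(truth, schedule = beagle_schedule_single(),
                                 error = error_model(),
                                 subject_id = "sim", loq = 0.025) {
  stopifnot(inherits(truth, "dual_elim_params"),
            inherits(error, "error_model"), length(schedule) >= 1)
  conc <- conc_single_dose(truth, schedule)
  observed_series(schedule, .apply_noise(conc, error),
                  subject_id = subject_id, loq = loq)
}

#' Simulate a multiple-dose concentration series
#'
#' Evaluates the multiple-dose profile at a trough/peak sampling design
#' (default: the reference beagle design, [beagle_schedule_multidose()])
#' and perturbs it with the measurement-error model. Pre-dose troughs are
#' evaluated as the left limit at the dose instant via their dose
#' bookkeeping.
#'
#' @inheritParams generate_single_dose
#' @param regimen A [dose_regimen()].
#' @param schedule Data frame with `time_h` and `dose_number` columns;
#'   defaults to [beagle_schedule_multidose()] for the regimen.
#' @return An [observed_series()] with `dose_number` bookkeeping.
#' @export
generate_multidose <- function(truth, regimen,
                               schedule = beagle_schedule_multidose(regimen),
                               error = error_model(),
                               subject_id = "sim", loq = 0.025) {
  stopifnot(inherits(truth, "dual_elim_params"),
            inherits(regimen, "dose_regimen"),
            is.data.frame(schedule),
            all(c("time_h", "dose_number") %in% names(schedule)))
  starts <- multidose_start_levels(truth, regimen)
  dn <- pmin(pmax(as.integer(schedule$dose_number), 1L), regimen$n_doses)
  local_t <- schedule$time_h - (dn - 1) * regimen$tau
  conc <- vapply(seq_along(dn), function(i)
    interval_solution(starts[dn[i]], truth, local_t[i]), numeric(1))
  observed_series(schedule$time_h, .apply_noise(conc, error),
                  subject_id = subject_id, dose_number = dn, loq = loq)
}

#' Generate a reproducible synthetic multi-subject study
#'
#' Builds a complete synthetic study — one single-dose series per subject,
#' and optionally a multiple-dose series under a regimen — from known
#' ground-truth parameters. The default truths are the five reference
#' beagle parameter sets, so a default study structurally mirrors the
#' reference design. A manifest (seed, error model, schedule, version)
#' makes every study bit-reproducible: [regenerate_study()] on the manifest
#' returns an identical object.
#'
#' @param truths Data frame with columns `subject_id`, `k1`, `c_a`,
#'   `k0_over_v` (default [beagle_reference_params()]).
#' @param regimen Optional [dose_regimen()]; when supplied, a multiple-dose
#'   series is generated per subject (increment defaulting to each
#'   subject's `c_a` unless the regimen sets one).
#' @param error An [error_model()] (its `seed` field is ignored; use `seed`).
#' @param seed Master integer seed.
#' @param schedule Single-dose sampling times.
#' @return An object of class `pk_study`: `truths`, `regimen`,
#'   `single_dose` (list of series), `multidose` (list or NULL), `manifest`.
#' @export
synthetic_study <- function(truths = beagle_reference_params(),
                            regimen = NULL, error = error_model(),
                            seed = 1L,
                            schedule = beagle_schedule_single()) {
  stopifnot(is.data.frame(truths),
            all(c("subject_id", "k1", "c_a", "k0_over_v") %in% names(truths)))
  manifest <- list(
    generator = "mabpk_synthetic_study", version = "1",
    seed = as.integer(seed),
    proportional_cv = error$proportional_cv,
    additive_sd = error$additive_sd,
    schedule = schedule,
    truths = truths,
    regimen = if (is.null(regimen)) NULL else unclass(regimen))
  set.seed(as.integer(seed))
  err <- error_model(error$proportional_cv, error$additive_sd, seed = NULL)
  single <- lapply(seq_len(nrow(truths)), function(i) {
    p <- dual_elim_params(truths$k1[i], truths$c_a[i], truths$k0_over_v[i])
    generate_single_dose(p, schedule, err, subject_id = truths$subject_id[i])
  })
  names(single) <- truths$subject_id
  multi <- NULL
  if (!is.null(regimen)) {
    multi <- lapply(seq_len(nrow(truths)), function(i) {
      p <- dual_elim_params(truths$k1[i], truths$c_a[i], truths$k0_over_v[i])
      reg_i <- dose_regimen(regimen$tau, regimen$n_doses,
                            c0_increment = if (regimen$c0_increment > 0)
                              regimen$c0_increment else truths$c_a[i],
                            first_dose_start = regimen$first_dose_start)
      generate_multidose(p, reg_i, error = err,
                         subject_id = truths$subject_id[i])
    })
    names(multi) <- truths$subject_id
  }
  structure(list(truths = truths, regimen = regimen, single_dose = single,
                 multidose = multi, manifest = manifest),
            class = "pk_study")
}

#' @rdname synthetic_study
#' @param manifest A study manifest (the `manifest` component of a
#'   `pk_study`, possibly round-tripped through JSON).
#' @export
regenerate_study <- function(manifest) {
  stopifnot(identical(manifest$generator, "mabpk_synthetic_study"))
  regimen <- if (is.null(manifest$regimen)) NULL else
    dose_regimen(manifest$regimen$tau, manifest$regimen$n_doses,
                 manifest$regimen$c0_increment,
                 manifest$regimen$first_dose_start)
  synthetic_study(truths = as.data.frame(manifest$truths),
                  regimen = regimen,
                  error = error_model(manifest$proportional_cv,
                                      manifest$additive_sd),
                  seed = manifest$seed,
                  schedule = as.numeric(manifest$schedule))
}

#' @export
print.pk_study <- function(x, ...) {
  cat(sprintf("Synthetic PK study: %d subjects, seed %d, CV %.1f%%%s\n",
              nrow(x$truths), x$manifest$seed,
              100 * x$manifest$proportional_cv,
              if (is.null(x$multidose)) "" else ", with multiple-dose arm"))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` noisy single-dose studies per ground-truth
#' parameter set, refits the dual-elimination model to each, and summarises
#' how well the parameters are recovered: per-parameter relative bias,
#' relative RMSE and median absolute relative error, plus the number of fit
#' failures (counted, not raised). Deterministic under a fixed seed.
#'
#' @param truth_sets Data frame of ground-truth parameters (columns
#'   `subject_id`, `k1`, `c_a`, `k0_over_v`); defaults to the reference
#'   beagle sets.
#' @param n_replicates Replicates per truth set.
#' @param error An [error_model()].
#' @param seed Master seed.
#' @param schedule Sampling schedule, h.
#' @param weighting A [weight_config()] for the refits.
#' @return A list with `summary` (data frame: one row per truth set and
#'   parameter, with relative bias, relative RMSE, median absolute relative
#'   error), `estimates` (data frame of all fitted triples with replicate
#'   indices), `n_failures`.
#' @export
recovery_experiment <- function(truth_sets = beagle_reference_params(),
                                n_replicates = 20, error = error_model(),
                                seed = 1L,
                                schedule = beagle_schedule_single(),
                                weighting = weight_config()) {
  stopifnot(n_replicates >= 1)
  set.seed(as.integer(seed))
  err <- error_model(error$proportional_cv, error$additive_sd, seed = NULL)
  est <- NULL
  n_fail <- 0L
  for (i in seq_len(nrow(truth_sets))) {
    p <- dual_elim_params(truth_sets$k1[i], truth_sets$c_a[i],
                          truth_sets$k0_over_v[i])
    for (r in seq_len(n_replicates)) {
      obs <- generate_single_dose(p, schedule, err,
                                  subject_id = truth_sets$subject_id[i])
      fit <- tryCatch(fit_pk(obs, model = "dual_elimination",
                             weighting = weighting),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { n_fail <- n_fail + 1L; next }
      est <- rbind(est, data.frame(
        subject_id = truth_sets$subject_id[i], replicate = r,
        k1 = fit$params$k1, c_a = fit$params$c_a,
        k0_over_v = fit$params$k0_over_v,
        k1_true = p$k1, c_a_true = p$c_a, k0_over_v_true = p$k0_over_v,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(est)) stop("all fits failed")
  summ <- do.call(rbind, lapply(split(est, est$subject_id), function(d) {
    do.call(rbind, lapply(c("k1", "c_a", "k0_over_v"), function(par) {
      rel <- (d[[par]] - d[[paste0(par, "_true")]]) /
        d[[paste0(par, "_true")]]
      data.frame(subject_id = d$subject_id[1], parameter = par,
                 rel_bias = mean(rel), rel_rmse = sqrt(mean(rel^2)),
                 median_abs_rel_err = stats::median(abs(rel)),
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  list(summary = summ, estimates = est, n_failures = n_fail)
}
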