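#' Reference beagle study: fitted parameters, design, steady-state table
#'
#' Reference values from a published single- and multiple-dose study of
#' bevacizumab (2.5 mg/kg IV) in five beagle dogs, used throughout the
#' package as realistic parameter sets for examples, synthetic studies and
#' validation. `beagle_reference_params()` returns the dual-elimination
#' parameters fitted to each dog's single-dose profile;
#' `beagle_steady_state()` returns the observed and model-predicted
#' steady-state trough/peak concentrations (with the reported relative
#' errors, in percent) under the once-weekly 6-dose regimen;
#' `beagle_schedule_single()` is the 19-point single-dose sampling schedule
#' and `beagle_schedule_multidose()` the three-part multiple-dose schedule.
#'
#' @return `beagle_reference_params()`: a data frame with columns
#'   `subject_id`, `k1` (1/h), `c_a` (mg/L), `k0_over_v` (mg/(L*h)).
#' @examples
#' p <- beagle_reference_params()
#' dog2 <- dual_elim_params(p$k1[2], p$c_a[2], p$k0_over_v[2])
#' conc_single_dose(dog2, 0)
#' @export
beagle_reference_params <- function() {
  data.frame(
    subject_id = as.character(1:5),
    k1 = c(0.0048, 0.0030, 0.0028, 0.0030, 0.0039),
    c_a = c(22.55, 8.45, 6.65, 9.84, 9.72),
    k0_over_v = c(0.0058, 0.0032, 0.0045, 0.0039, 0.0072),
    stringsAsFactors = FALSE)
}

#' @rdname beagle_reference_params
#' @return `beagle_steady_state()`: a data frame with one row per dog and
#'   per steady-state metric (`cmin_ss`, `cmax_ss`): observed value,
#'   predicted value, reported relative error in percent, and
#'   `re_consistent` flagging the two cells whose reported RE does not
#'   round-trip from the printed observed/predicted pair (recomputation
#'   gives 24.4 vs reported 24.3 for dog 1's peak and 1.5 vs 1.6 for dog 5's
#'   trough — rounding drift in the source table).
#' @export
beagle_steady_state <- function() {
  d <- rbind(
    data.frame(subject_id = as.character(1:5), metric = "cmin_ss",
               observed = c(19.75, 15.20, 42.17, 32.44, 31.15),
               predicted = c(21.37, 17.38, 44.63, 41.39, 30.67),
               re_reported = c(8.2, 14.3, 5.8, 27.6, 1.6),
               stringsAsFactors = FALSE),
    data.frame(subject_id = as.character(1:5), metric = "cmax_ss",
               observed = c(64.74, 32.48, 79.56, 84.49, 70.73),
               predicted = c(48.95, 30.37, 74.61, 71.37, 60.64),
               re_reported = c(24.3, 6.5, 6.2, 15.5, 14.3),
               stringsAsFactors = FALSE))
  d$re_consistent <- !(d$subject_id == "1" & d$metric == "cmax_ss") &
    !(d$subject_id == "5" & d$metric == "cmin_ss")
  d[order(d$subject_id, d$metric), ]
}

#' @rdname beagle_reference_params
#' @return `beagle_schedule_single()`: the 19 post-dose sampling times, h.
#' @export
beagle_schedule_single <- function() {
  c(0.083, 2, 6, 12, 24, 48, 72, 120, 168, 216, 264, 336, 408, 480, 504,
    600, 624, 648, 672)
}

#' @rdname beagle_reference_params
#' @param regimen A [dose_regimen()]; the schedule adapts to its interval
#'   and number of doses (the reference design is 6 once-weekly doses).
#' @return `beagle_schedule_multidose()`: a data frame with columns `time_h`
#'   (from first dose) and `dose_number` (the governing interval; a pre-dose
#'   trough drawn at a dose instant belongs to the preceding interval).
#'   Design: rich sampling after dose 1; trough + 5-min peak around each
#'   intermediate dose; rich sampling after the last dose.
#' @export
beagle_schedule_multidose <- function(regimen = dose_regimen(tau = 168,
                                                             n_doses = 6)) {
  stopifnot(inherits(regimen, "dose_regimen"))
  tau <- regimen$tau
  n <- regimen$n_doses
  first <- data.frame(time_h = c(0.083, 6, 24, 48, 72, 120),
                      dose_number = 1L)
  first <- first[first$time_h < tau, , drop = FALSE]
  mids <- NULL
  if (n > 2) {
    for (k in 2:(n - 1)) {
      t0 <- (k - 1) * tau
      mids <- rbind(mids,
                    data.frame(time_h = t0, dose_number = k - 1L),   # trough
                    data.frame(time_h = t0 + 0.083, dose_number = k)) # peak
    }
  }
  last <- NULL
  if (n > 1) {
    t0 <- (n - 1) * tau
    post <- c(0.083, 2, 6, 12, 24, 48, 72, 120, 168, 216, 264, 336, 408,
              504, 600, 696, 792)
    last <- rbind(data.frame(time_h = t0, dose_number = n - 1L),
                  data.frame(time_h = t0 + post, dose_number = as.integer(n)))
  }
  out <- rbind(first, mids, last)
  out <- out[order(out$time_h, out$dose_number), ]
  rownames(out) <- NULL
  out
}
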