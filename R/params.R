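#' Dual-elimination model parameters
#'
#' Constructs the parameter set of the dual-elimination model for an
#' intravenously dosed monoclonal antibody: elimination is the superposition
#' of a first-order (proteolytic catabolism) process with rate constant `k1`
#' and a zero-order (target-mediated) process with rate `K0`. Only the ratio
#' `K0/V` (zero-order rate scaled by the distribution volume) is identifiable
#' from concentration data, so it is carried as a single parameter. `c_a` is
#' the plasma concentration remaining immediately after the first dose once
#' the pre-existing target pool has been neutralised.
#'
#' @param k1 First-order elimination rate constant, 1/h. Must be positive.
#' @param c_a Post-binding initial concentration at the first dose, mg/L.
#'   Must be positive.
#' @param k0_over_v Zero-order elimination rate divided by the distribution
#'   volume, mg/(L*h). Must be nonnegative; 0 reduces the model to the
#'   classic one-compartment form.
#' @return An object of class `dual_elim_params`.
#' @seealso [one_compartment_params()], [conc_single_dose()]
#' @examples
#' p <- dual_elim_params(k1 = 0.0030, c_a = 8.45, k0_over_v = 0.0032)
#' conc_single_dose(p, c(0, 168, 672))
#' @export
dual_elim_params <- function(k1, c_a, k0_over_v) {
  stopifnot(is.numeric(k1), length(k1) == 1L, is.finite(k1),
            is.numeric(c_a), length(c_a) == 1L, is.finite(c_a),
            is.numeric(k0_over_v), length(k0_over_v) == 1L,
            is.finite(k0_over_v))
  if (k1 <= 0) stop("`k1` must be > 0")
  if (c_a <= 0) stop("`c_a` must be > 0")
  if (k0_over_v < 0) stop("`k0_over_v` must be >= 0")
  structure(list(k1 = k1, c_a = c_a, k0_over_v = k0_over_v),
            class = c("dual_elim_params", "pk_params"))
}

#' One-compartment comparator parameters
#'
#' The classic one-compartment IV bolus model `C(t) = c0 * exp(-k_el * t)`,
#' used as the comparator against the dual-elimination model.
#'
#' @param c0 Initial concentration, mg/L (> 0).
#' @param k_el First-order elimination rate constant, 1/h (> 0).
#' @return An object of class `one_compartment_params`.
#' @export
one_compartment_params <- function(c0, k_el) {
  stopifnot(is.numeric(c0), length(c0) == 1L, is.finite(c0),
            is.numeric(k_el), length(k_el) == 1L, is.finite(k_el))
  if (c0 <= 0) stop("`c0` must be > 0")
  if (k_el <= 0) stop("`k_el` must be > 0")
  structure(list(c0 = c0, k_el = k_el),
            class = c("one_compartment_params", "pk_params"))
}

#' @export
print.dual_elim_params <- function(x, digits = 4, ...) {
  cat("Dual-elimination model parameters\n")
  cat(sprintf("  k1        = %s 1/h      (first-order elimination)\n",
              format(x$k1, digits = digits)))
  cat(sprintf("  c_a       = %s mg/L     (post-binding initial concentration)\n",
              format(x$c_a, digits = digits)))
  cat(sprintf("  K0/V      = %s mg/(L*h) (zero-order elimination / volume)\n",
              format(x$k0_over_v, digits = digits)))
  invisible(x)
}

#' @export
print.one_compartment_params <- function(x, digits = 4, ...) {
  cat("One-compartment model parameters\n")
  cat(sprintf("  c0   = %s mg/L\n", format(x$c0, digits = digits)))
  cat(sprintf("  k_el = %s 1/h\n", format(x$k_el, digits = digits)))
  invisible(x)
}

#' @export
as.vector.dual_elim_params <- function(x, mode = "any") {
  c(k1 = x$k1, c_a = x$c_a, k0_over_v = x$k0_over_v)
}

#' @export
as.vector.one_compartment_params <- function(x, mode = "any") {
  c(c0 = x$c0, k_el = x$k_el)
}

#' Dosing regimen for repeated intravenous administration
#'
#' Describes a fixed-interval IV regimen. The first dose starts the profile
#' at `first_dose_start` (by default the model's post-binding concentration
#' `c_a`, because the pre-existing target pool soaks up part of the first
#' dose); every later dose raises the concentration instantaneously by
#' `c0_increment`, the binding loss not being incurred again once the
#' pre-existing target has been neutralised.
#'
#' @param tau Dosing interval, h (> 0). The once-weekly design uses 168 h.
#' @param n_doses Number of administrations (integer >= 1).
#' @param c0_increment Concentration jump at each dose from the second
#'   onward, mg/L (>= 0).
#' @param first_dose_start Start concentration at dose 1, mg/L. `NULL`
#'   (default) means "use the model's `c_a` at evaluation time".
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(tau = 168, n_doses = 1L, c0_increment = 0,
                         first_dose_start = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(n_doses), length(n_doses) == 1L,
            is.numeric(c0_increment), length(c0_increment) == 1L,
            is.finite(c0_increment))
  if (tau <= 0) stop("`tau` must be > 0")
  if (n_doses < 1 || n_doses != round(n_doses))
    stop("`n_doses` must be a positive integer")
  if (c0_increment < 0) stop("`c0_increment` must be >= 0")
  if (!is.null(first_dose_start)) {
    stopifnot(is.numeric(first_dose_start), length(first_dose_start) == 1L)
    if (first_dose_start <= 0) stop("`first_dose_start` must be > 0")
  }
  structure(list(tau = tau, n_doses = as.integer(n_doses),
                 c0_increment = c0_increment,
                 first_dose_start = first_dose_start),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("Dose regimen: %d dose(s) every %g h, increment %g mg/L%s\n",
              x$n_doses, x$tau, x$c0_increment,
              if (is.null(x$first_dose_start)) " (dose 1 starts at c_a)"
              else sprintf(" (dose 1 starts at %g mg/L)", x$first_dose_start)))
  invisible(x)
}

#' Observed concentration-time series
#'
#' A single subject's plasma concentration measurements. Times are hours
#' from the first administration; `dose_number` (optional) assigns each
#' sample to the dosing interval that governs it, so that a trough drawn
#' immediately before dose k carries `dose_number = k - 1` even though its
#' clock time coincides with the dose instant.
#'
#' @param times Sampling times, h; strictly increasing and >= 0.
#' @param concentrations Measured concentrations, mg/L; same length as
#'   `times`, nonnegative.
#' @param subject_id Subject label.
#' @param dose_number Optional integer vector assigning samples to dosing
#'   intervals.
#' @param loq Optional lower limit of quantification, mg/L; samples below it
#'   are flagged and excluded from fitting objectives.
#' @return An object of class `observed_series`.
#' @export
observed_series <- function(times, concentrations, subject_id = "subject",
                            dose_number = NULL, loq = NULL) {
  stopifnot(is.numeric(times), is.numeric(concentrations),
            length(times) == length(concentrations))
  if (length(times) == 0L) stop("empty series")
  if (any(times < 0)) stop("times must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (!is.null(dose_number)) {
    stopifnot(length(dose_number) == length(times))
    dose_number <- as.integer(dose_number)
  }
  if (!is.null(loq)) stopifnot(is.numeric(loq), length(loq) == 1L, loq > 0)
  structure(list(subject_id = as.character(subject_id),
                 times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 dose_number = dose_number, loq = loq),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("Observed series '%s': %d samples, %g-%g h, %g-%g mg/L%s\n",
              x$subject_id, length(x$times), min(x$times), max(x$times),
              min(x$concentrations), max(x$concentrations),
              if (is.null(x$loq)) "" else sprintf(", LOQ %g mg/L", x$loq)))
  invisible(x)
}

#' @export
as.data.frame.observed_series <- function(x, ...) {
  d <- data.frame(subject_id = x$subject_id, time_h = x$times,
                  conc_mg_L = x$concentrations, stringsAsFactors = FALSE)
  if (!is.null(x$dose_number)) d$dose_number <- x$dose_number
  d
}

# coerce a data.frame (subject_id/time_h/conc_mg_L or time/conc) to one series
as_observed_series <- function(data, subject_id = NULL, loq = NULL) {
  if (inherits(data, "observed_series")) return(data)
  stopifnot(is.data.frame(data))
  nm <- names(data)
  tcol <- intersect(c("time_h", "time", "times"), nm)[1]
  ccol <- intersect(c("conc_mg_L", "conc", "concentration", "concentrations"),
                    nm)[1]
  if (is.na(tcol) || is.na(ccol))
    stop("data must have time ('time_h' or 'time') and concentration ",
         "('conc_mg_L' or 'conc') columns")
  sid <- subject_id
  if (is.null(sid)) {
    sid <- if ("subject_id" %in% nm) as.character(data$subject_id[1]) else "subject"
  }
  dn <- if ("dose_number" %in% nm) data$dose_number else NULL
  observed_series(data[[tcol]], data[[ccol]], subject_id = sid,
                  dose_number = dn, loq = loq)
}
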