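#' Weighting configuration for nonlinear least squares
#'
#' The fitting objective weights each squared residual. The default scheme
#' uses the reciprocal of the model-predicted concentration, which is
#' circular (weights depend on the fit) and is therefore resolved by
#' iteratively reweighted least squares: round 0 is seeded with reciprocal
#' observed weights, later rounds reuse the previous round's predictions.
#'
#' @param scheme One of `"reciprocal_predicted"` (default),
#'   `"reciprocal_observed"`, `"unweighted"`.
#' @param floor Minimum value used in a weight denominator, mg/L; prevents
#'   exploding weights near the zero-crossing of the dual-elimination curve.
#' @param max_irls_iterations Maximum IRLS rounds.
#' @param irls_tolerance Relative parameter-change threshold declaring IRLS
#'   convergence.
#' @return An object of class `weight_config`.
#' @export
weight_config <- function(scheme = c("reciprocal_predicted",
                                     "reciprocal_observed", "unweighted"),
                          floor = 0.01, max_irls_iterations = 20L,
                          irls_tolerance = 1e-6) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(floor), floor > 0,
            max_irls_iterations >= 1, irls_tolerance > 0)
  structure(list(scheme = scheme, floor = floor,
                 max_irls_iterations = as.integer(max_irls_iterations),
                 irls_tolerance = irls_tolerance),
            class = "weight_config")
}

# weights for a given scheme; `predicted` only needed for reciprocal_predicted
pk_weights <- function(observed, predicted, cfg) {
  switch(cfg$scheme,
    reciprocal_predicted = 1 / pmax(predicted, cfg$floor),
    reciprocal_observed  = 1 / pmax(observed, cfg$floor),
    unweighted           = rep(1, length(observed)))
}

#' Weighted residual sum of squares
#'
#' `sum(w_i * (obs_i - pred_i)^2)`, the fitting objective. With the
#' reciprocal-predicted scheme `w_i = 1/max(pred_i, floor)`.
#'
#' @param observed Observed concentrations, mg/L.
#' @param predicted Model-predicted concentrations, mg/L; same length.
#' @param weights Per-point positive weights; same length.
#' @return The weighted residual sum of squares (scalar, >= 0).
#' @export
wrss <- function(observed, predicted, weights) {
  if (length(observed) != length(predicted) ||
      length(observed) != length(weights))
    stop("observed, predicted and weights must have equal length")
  if (any(weights <= 0)) stop("weights must be > 0")
  sum(weights * (observed - predicted)^2)
}

#' Weighted goodness-of-fit score
#'
#' A weighted coefficient of determination,
#' `1 - sum(w*(obs-pred)^2) / sum(w*(obs - obs_bar_w)^2)` with `obs_bar_w`
#' the weighted mean of the observations. Equals 1 for a perfect fit, 0 when
#' the model does no better than the weighted mean, and can be negative.
#' `method = "pearson"` instead returns the squared Pearson correlation
#' between observed and predicted values.
#'
#' @inheritParams wrss
#' @param method `"weighted_r2"` (default) or `"pearson"`.
#' @return Dimensionless score in (-Inf, 1].
#' @export
fitting_degree <- function(observed, predicted, weights,
                           method = c("weighted_r2", "pearson")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted) ||
      length(observed) != length(weights))
    stop("observed, predicted and weights must have equal length")
  if (length(observed) < 2) stop("need at least 2 points")
  if (method == "pearson") return(stats::cor(observed, predicted)^2)
  obar <- sum(weights * observed) / sum(weights)
  denom <- sum(weights * (observed - obar)^2)
  if (denom <= 0) stop("zero weighted variance of observations")
  1 - sum(weights * (observed - predicted)^2) / denom
}

#' Relative prediction error, percent
#'
#' `|predicted - observed| / observed * 100`, the magnitude of the relative
#' deviation of a prediction from its observation.
#'
#' @param observed Observed value(s), mg/L; must be > 0.
#' @param predicted Predicted value(s), mg/L.
#' @return Absolute relative error(s) in percent.
#' @examples
#' relative_error(15.20, 17.38)  # 14.3
#' @export
relative_error <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (any(observed <= 0)) stop("observed must be > 0")
  abs(predicted - observed) / observed * 100
}
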