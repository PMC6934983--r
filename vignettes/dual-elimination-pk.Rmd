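---
title: "Dual-elimination pharmacokinetics of monoclonal antibodies: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-elimination pharmacokinetics of monoclonal antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabpk)
```

## Why a dual-elimination model

Classic compartment models assume elimination is first order: the
log-concentration profile is a straight line (one compartment) or a sum of
exponentials. Therapeutic monoclonal antibodies often violate this. Besides
nonspecific proteolytic catabolism — genuinely first order — a mAb is
removed by binding its target, after which effector mechanisms (ADCC,
complement) destroy the complex. When the soluble target is produced at a
roughly constant rate and the antibody is present in excess, this second
route consumes drug at a roughly constant *rate*, i.e. zero order in
antibody concentration. At high concentrations the first-order route
dominates and the profile looks mono-exponential; as concentration falls
the fixed zero-order drain becomes relatively more important and the
log-profile bends downward — the hallmark this model captures.

A third feature matters only at the first dose: the pre-existing pool of
target soaks up a fixed amount of antibody essentially instantly, so the
observable profile starts at a *post-binding* concentration `c_a`, below
dose/V.

### Single dose

Solving `dC/dt = -k1*C - K0/V` from `C(0) = c_a` gives

$$C(t) = c_A e^{-k_1 t} - B\,(1 - e^{-k_1 t}), \qquad B = \frac{K_0}{k_1 V}.$$

Only the ratio `K0/V` is identifiable from concentration data; the package
never attempts to separate `K0` from `V`. The curve reaches zero at the
finite time `t* = log(1 + c_a/B)/k1` (`zero_crossing_time()`). Physical
concentrations cannot be negative, so model output is clamped at zero —
and, within a dosing interval, zero is absorbing: once the plasma is empty
the zero-order sink has nothing to act on until the next dose. The
un-clamped value remains available (`clamp = FALSE`) because fitting
diagnostics and root-finding need it.

### Multiple doses

The repeated-dose expression follows from two rules: the within-interval
trajectory obeys the same ODE, giving the affine propagator
`C(t) = (start + B) e^{-k1 t} - B` (`interval_solution()`), and the
first-dose binding loss is *not* paid again at later doses — the
pre-existing target is already neutralised — so dose 1 starts at `c_a`
while each later dose adds a fixed increment `c0`. The start levels obey

`start_n = propagate(start_{n-1}, tau) + c0`,

implemented as a recursion (`multidose_start_levels()`), which away from
the zero clamp telescopes to the geometric closed form with fixed point
`x* = c0/(1-q) - B`, `q = exp(-k1*tau)`. The steady-state peak equals that
fixed point and the trough is `x* - c0` (`steady_state_extrema()`). A
regimen whose trough is nonpositive cannot sustain a steady state; it is
flagged `degenerate` rather than raised, since a user exploring dosing
intervals will hit this region legitimately. Times are measured from the
first administration, dose *n* is given at `(n-1)*tau`, and a time falling
exactly on a dose instant takes the post-dose (right-limit) value; sampling
designs represent a pre-dose trough drawn at the dose instant through dose
bookkeeping (`dose_number` one less than the arriving dose).

The study used a short IV infusion, but the model is bolus-form: `t = 0` is
taken as the end of infusion and the 5-minute (0.083 h) sample is the first
post-dose point.

## Estimation

`fit_pk()` minimises the weighted residual sum of squares
`sum(w_i (obs_i - pred_i)^2)`. The weighting of record uses the reciprocal
of the *model-predicted* concentration, which keeps the late, low,
mechanistically informative tail from being drowned out by the early peak.
Those weights depend on the fit, a circularity resolved by iteratively
reweighted least squares: round 0 is seeded with reciprocal-of-observed
weights, each later round refits with weights from the previous round's
predictions, stopping when the largest relative parameter change drops
below `irls_tolerance` (default 1e-6, max 20 rounds). On data that the
model describes well, predictions approach observations and the scheme
converges in two or three rounds.

Within a round, the bounded objective is minimised by Levenberg–Marquardt
(`minpack.lm::nls.lm`) from a deterministic 12-point multi-start grid
spanning decade ranges of `k1` (1e-4–0.1 1/h) and of the zero-order rate
(from effectively zero to 0.2·Cmax per hour of span), with `c_a` seeded at
the observed maximum. Bounds: `k1` in (1e-6, 1], `c_a` in (0, 10·Cmax],
`k0_over_v` in [0, 10·Cmax/tspan]. The best start by WRSS wins; exact ties
go to the smaller `k0_over_v` (the more parsimonious explanation). No
randomness enters the optimiser, so identical inputs give bit-identical
fits. The one-compartment comparator is fitted by the same machinery,
initialised by log-linear regression of log-concentration on time.

Tunable numerical settings, all in `weight_config()`: weight scheme
(`reciprocal_predicted` default, `reciprocal_observed`, `unweighted`), the
weight floor (0.01 mg/L — weights are computed on `max(pred, floor)` so
they cannot explode near the zero crossing), IRLS round cap and tolerance.
Observations at zero, or below a declared limit of quantification, are
excluded from the objective and counted (`n_below_loq`); the default LOQ
recorded by the generator, 0.025 mg/L, is a typical ELISA quantification
limit.

### Goodness of fit

The "fitting degree" reported alongside WRSS is a weighted coefficient of
determination, `1 - sum(w (obs-pred)^2) / sum(w (obs - obar_w)^2)` with
`obar_w` the weighted mean of the observations. This is this package's own
definition, chosen because it is the natural weighted analogue of R² and
shares the objective's weights; commercial PK software computes a
proprietary variant, so fitting-degree values are comparable within this
package but not necessarily across tools. A squared Pearson correlation is
available via `fitting_degree(..., method = "pearson")`.

### Relative error

Prediction accuracy against observations is the absolute relative error
`|pred - obs|/obs * 100` (percent). It is undefined at an observed zero and
reported as `NA` there, which can occur late in the last interval when the
zero-order sink empties the plasma.

## Choosing the per-dose increment C0

The multiple-dose prediction needs the increment `c0` each dose adds. It is
*not* equal to `c_a`: later doses do not pay the first dose's binding toll,
so `c0 > c_a` in general, and `c0` is not identifiable from single-dose
data alone. The package therefore makes the choice explicit and records its
provenance in every report (`c0_source`):

* `from_observed_jumps` (default when multiple-dose data exist): mean over
  doses 2..n of the 5-minute post-dose sample minus the immediately
  preceding trough. Because the post-dose sample decays for five minutes
  before being drawn, this recovers the true increment to about 0.1% on
  noiseless data — exact to well within any assay's precision.
* `equal_to_ca`: uses the fitted `c_a`, with a warning, as a fallback when
  no multiple-dose observations exist; it systematically underpredicts
  accumulation.
* `user_supplied`: passes a value through, e.g. one obtained from the
  dose amount and an independent volume estimate.

Observed steady-state extrema are extracted from the sampling design: the
peak is the 5-minute post-dose sample of the last dose, the trough the last
pre-dose sample. `within_tolerance_summary()` applies an inclusive
relative-error band (default 20%): an RE exactly at the tolerance passes,
the convention being that the band states the acceptable error.

## The synthetic-study generator

`synthetic_study()` emulates the reference beagle design: five subjects
whose ground-truth parameters default to the shipped reference sets
(`beagle_reference_params()`), a single 2.5 mg/kg IV dose sampled at the
19 scheduled times over 672 h (`beagle_schedule_single()`), and optionally
a 6-dose once-weekly arm sampled richly after the first and last doses and
at trough/5-min-peak around intermediate doses
(`beagle_schedule_multidose()`). Measurement error is multiplicative
lognormal with 5% CV by default (parameterised to mean 1, so simulated
concentrations are unbiased around the curve), plus an optional additive
Gaussian term, truncated at zero. The 5% default is an invented but
realistic figure for a duplicate-measured ELISA; the source study reports
no residual-error model. In the multiple-dose arm the per-dose increment
defaults to each subject's `c_a` — a deliberately conservative choice, since
the true increment exceeds `c_a`; analyses that depend on the increment
take it explicitly.

What the generator does *not* emulate: target-level dynamics (the zero-order
rate is constant, not a saturable function of target occupancy),
anti-drug-antibody formation, inter-occasion variability, infusion
duration, and assay calibration-curve error structure. Passing recovery
tests on these simulations therefore demonstrates that the estimator
inverts its own forward model under realistic noise — not that the model is
correct for any particular real antibody.

Every study carries a manifest (seed, error model, schedule, truths,
regimen version) from which `regenerate_study()` rebuilds it
bit-identically; `recovery_experiment()` wraps generate-and-refit loops
into per-parameter bias/RMSE summaries, counting rather than raising fit
failures.

## Validation performed by the test suite

The shipped tests validate, among other things: the closed form against
independent numerical integration of the elimination ODE (relative 1e-6,
100 random parameter sets); exact nesting of the one-compartment model at
`k0_over_v = 0`; noiseless round-trip recovery of all three parameters to
0.1% for each reference parameter set; noisy recovery — 200 simulated
studies (40 per reference subject) at 5% CV on the 19-point schedule —
with median absolute relative error below 10% per parameter; agreement of
the steady-state fixed point with a 2000-dose recursion to 1e-9; and the
qualitative single-to-multiple failure of the classic model (its
predictions from single-dose fits fall systematically below
dual-elimination-generated late-dose observations, because it both absorbs
the first-dose binding loss into `k_el` and re-pays that loss at every
dose). These problem sizes keep the whole suite around ten seconds on one
CPU while leaving the Monte-Carlo margins wide.

## Known limitations

* The zero-order description of target-mediated clearance is an
  approximation valid while target production is constant and the drug is
  in excess; near and below target saturation a full target-mediated
  disposition model is more faithful.
* `V` and `K0` are not separately reported, by design; dose-based
  increment calculations need an external volume estimate.
* The increment `c0` must come from data or the user; predicting a first
  multiple-dose study from single-dose data alone requires the
  `equal_to_ca` fallback and inherits its underprediction.
* Weighted-R² fitting degrees are tool-specific (see above).
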