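# shared fixtures and independent oracles

# reference dual-elimination parameter set i (1..5)
ref_params <- function(i) {
  p <- beagle_reference_params()
  dual_elim_params(p$k1[i], p$c_a[i], p$k0_over_v[i])
}

# independent oracle: integrate dC/dt = -k1*C - K0/V numerically from an
# arbitrary start level (defaults to c_a); valid for the un-clamped curve
ode_conc <- function(params, times, start = params$c_a) {
  grid <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(
    c(C = start), times = grid,
    func = function(t, y, p) list(-p$k1 * y[[1]] - p$k0_over_v),
    parms = params, rtol = 1e-10, atol = 1e-12)
  unname(out[match(times, out[, "time"]), "C"])
}

# random but physically plausible parameter draws for property tests
random_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(k1 = 10^stats::runif(n, -3.3, -1.7),
             c_a = stats::runif(n, 2, 50),
             k0_over_v = 10^stats::runif(n, -3.5, -1.8))
}
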