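test_that("single-dose curve reproduces reference values and the ODE", {
  dog2 <- ref_params(2)

  # at t = 0 the curve starts at the post-binding concentration
  expect_equal(conc_single_dose(dog2, 0), 8.45)

  # frozen value computed with the ODE oracle (lsoda, rtol 1e-10)
  expect_equal(conc_single_dose(dog2, 168), 4.68244096, tolerance = 1e-7)
  expect_equal(conc_single_dose(dog2, 168),
               ode_conc(dog2, 168), tolerance = 1e-8)

  # without zero-order elimination the model is a pure mono-exponential
  p0 <- dual_elim_params(0.004, 12, 0)
  tt <- c(0, 1, 24, 300, 2000)
  expect_equal(conc_single_dose(p0, tt), 12 * exp(-0.004 * tt))

  expect_error(conc_single_dose(dog2, -1), "t must be >= 0")
})

test_that("closed form agrees with numerical ODE integration over random draws", {
  draws <- random_params(100, seed = 7)
  set.seed(8)
  for (i in seq_len(nrow(draws))) {
    p <- dual_elim_params(draws$k1[i], draws$c_a[i], draws$k0_over_v[i])
    tt <- sort(stats::runif(4, 0, 700))
    expect_equal(conc_single_dose(p, tt, clamp = FALSE), ode_conc(p, tt),
                 tolerance = 1e-6)
  }
})

test_that("un-clamped single-dose curve is strictly decreasing", {
  tt <- seq(0, 1500, by = 10)
  for (i in 1:5) {
    cc <- conc_single_dose(ref_params(i), tt, clamp = FALSE)
    expect_true(all(diff(cc) < 0))
  }
})

test_that("zero-crossing time matches a root-bracketing oracle", {
  dog2 <- ref_params(2)
  tstar <- zero_crossing_time(dog2)
  # independent oracle: bisection (uniroot) on the un-clamped closed form
  oracle <- stats::uniroot(function(t) conc_single_dose(dog2, t, clamp = FALSE),
                           c(1, 5000), tol = 1e-10)$root
  expect_equal(tstar, oracle, tolerance = 1e-8)
  expect_equal(tstar, 729.5, tolerance = 1e-3)
  expect_lt(abs(conc_single_dose(dog2, tstar, clamp = FALSE)), 1e-9)

  expect_identical(zero_crossing_time(dual_elim_params(0.01, 5, 0)), Inf)
})

test_that("within-interval propagator is consistent with the single-dose curve", {
  dog2 <- ref_params(2)
  tt <- c(0, 5, 100, 400)
  expect_equal(interval_solution(dog2$c_a, dog2, tt),
               conc_single_dose(dog2, tt))
  expect_equal(interval_solution(13.7, dog2, 0), 13.7)
  # frozen value from the ODE oracle started at 20 mg/L
  expect_equal(interval_solution(20, dog2, 168), 11.6599, tolerance = 1e-4)
  expect_equal(interval_solution(20, dog2, 168), ode_conc(dog2, 168, start = 20),
               tolerance = 1e-8)
  expect_error(interval_solution(-1, dog2, 10), "start_conc")
})

test_that("dose-start recursion matches its geometric closed form", {
  dog2 <- ref_params(2)
  expect_identical(multidose_start_levels(dog2, dose_regimen(168, 1, 5)),
                   dog2$c_a)

  # convergence of the recursion to the fixed point
  reg <- dose_regimen(168, 50, c0_increment = 8.45)
  starts <- multidose_start_levels(dog2, reg)
  expect_equal(starts[50], 20.2776, tolerance = 1e-4)

  # closed form x* + (start1 - x*) q^(n-1) vs the recursion, random params
  draws <- random_params(20, seed = 11)
  for (i in seq_len(nrow(draws))) {
    p <- dual_elim_params(draws$k1[i], draws$c_a[i], draws$k0_over_v[i])
    reg <- dose_regimen(tau = 168, n_doses = 12, c0_increment = draws$c_a[i])
    rec <- multidose_start_levels(p, reg)
    q <- exp(-p$k1 * 168)
    b <- p$k0_over_v / p$k1
    xstar <- draws$c_a[i] / (1 - q) - b
    closed <- xstar + (p$c_a - xstar) * q^(0:11)
    expect_equal(rec, closed, tolerance = 1e-9)
  }
})

test_that("multiple-dose profile is the single-dose curve in dose 1 and jumps by c0", {
  dog2 <- ref_params(2)
  reg <- dose_regimen(tau = 168, n_doses = 4, c0_increment = 12.44)
  tt <- c(0, 0.083, 24, 167.99)
  expect_equal(conc_multidose(dog2, reg, tt), conc_single_dose(dog2, tt))

  # right limit minus left limit at each dose instant equals the increment
  starts <- multidose_start_levels(dog2, reg)
  for (n in 2:4) {
    td <- (n - 1) * reg$tau
    left <- interval_solution(starts[n - 1], dog2, reg$tau)
    right <- conc_multidose(dog2, reg, td)
    expect_equal(right - left, 12.44)
    # superposition consistency: just before dose n the profile equals the
    # propagated previous start
    expect_equal(conc_multidose(dog2, reg, td - 1e-9), left, tolerance = 1e-6)
  }

  # zero increment: identical to the single-dose curve everywhere
  reg0 <- dose_regimen(tau = 168, n_doses = 5, c0_increment = 0)
  tt <- seq(0, 800, by = 7)
  expect_equal(conc_multidose(dog2, reg0, tt), conc_single_dose(dog2, tt))
})

test_that("output is clamped at zero and stays absorbed until the next dose", {
  # strong zero-order elimination: the curve dies inside one interval
  p <- dual_elim_params(k1 = 0.002, c_a = 4, k0_over_v = 0.05)
  tstar <- zero_crossing_time(p)
  reg <- dose_regimen(tau = 168, n_doses = 2, c0_increment = 6)
  expect_lt(tstar, 168)
  tt <- seq(0, 336, by = 1)
  cc <- conc_multidose(p, reg, tt)
  expect_true(all(cc >= 0))
  dead <- tt > tstar & tt < 168
  expect_true(all(cc[dead] == 0))
  expect_gt(conc_multidose(p, reg, 168), 0)  # revived by the second dose
})

test_that("steady-state extrema equal the long-run recursion fixed point", {
  dog2 <- ref_params(2)
  reg <- dose_regimen(tau = 168, n_doses = 500, c0_increment = 8.45)
  ss <- steady_state_extrema(dog2, reg)
  expect_equal(ss$c_max_ss, 20.2776, tolerance = 1e-4)
  expect_equal(ss$c_min_ss, 11.8276, tolerance = 1e-4)
  expect_false(ss$degenerate)

  # oracle: iterate the dose-start recursion to convergence
  starts <- multidose_start_levels(dog2, reg)
  expect_equal(ss$c_max_ss, starts[500], tolerance = 1e-9)
  expect_equal(ss$c_min_ss, interval_solution(starts[500], dog2, reg$tau),
               tolerance = 1e-7)

  # peak minus trough is the increment, for any parameters
  draws <- random_params(10, seed = 3)
  for (i in seq_len(nrow(draws))) {
    p <- dual_elim_params(draws$k1[i], draws$c_a[i], draws$k0_over_v[i])
    s <- steady_state_extrema(p, dose_regimen(100, 5, c0_increment = 7.3))
    expect_equal(s$c_max_ss - s$c_min_ss, 7.3)
  }

  # without zero-order elimination: textbook one-compartment accumulation
  p0 <- dual_elim_params(0.005, 10, 0)
  s0 <- steady_state_extrema(p0, dose_regimen(168, 10, c0_increment = 10))
  expect_equal(s0$c_max_ss, 10 / (1 - exp(-0.005 * 168)))

  # a regimen whose trough dies is flagged, not raised
  pz <- dual_elim_params(0.002, 4, 0.05)
  expect_true(steady_state_extrema(pz, dose_regimen(168, 10, 1))$degenerate)
})

test_that("classic one-compartment model behaves and nests in the dual model", {
  cp <- one_compartment_params(c0 = 18.3, k_el = 0.006)
  expect_equal(conc_classic(cp, 0), 18.3)
  expect_equal(conc_classic(cp, log(2) / 0.006), 18.3 / 2)
  expect_error(conc_classic(cp, -5), "t must be >= 0")

  # nesting: dual model with no zero-order term is the classic model
  pd <- dual_elim_params(k1 = 0.006, c_a = 18.3, k0_over_v = 0)
  tt <- c(0, 0.083, 24, 168, 672, 1500)
  expect_equal(conc_single_dose(pd, tt), conc_classic(cp, tt))

  # multiple doses by superposition: each dose adds an exponential
  reg <- dose_regimen(tau = 168, n_doses = 3)
  tt <- c(10, 170, 400)
  manual <- 18.3 * exp(-0.006 * tt) +
    18.3 * exp(-0.006 * pmax(tt - 168, 0)) * (tt >= 168) +
    18.3 * exp(-0.006 * pmax(tt - 336, 0)) * (tt >= 336)
  expect_equal(conc_classic(cp, tt, regimen = reg), manual)
})

test_that("parameter and regimen constructors validate their domains", {
  expect_error(dual_elim_params(-0.01, 5, 0), "k1")
  expect_error(dual_elim_params(0.01, 0, 0), "c_a")
  expect_error(dual_elim_params(0.01, 5, -1), "k0_over_v")
  expect_error(one_compartment_params(5, 0), "k_el")
  expect_error(dose_regimen(tau = 0), "tau")
  expect_error(dose_regimen(n_doses = 1.5), "n_doses")
  expect_error(dose_regimen(c0_increment = -2), "c0_increment")
  expect_error(observed_series(c(1, 1), c(2, 3)), "strictly increasing")
  expect_error(observed_series(c(1, 2), c(-2, 3)), ">= 0")
})
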