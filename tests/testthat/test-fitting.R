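test_that("noiseless data generated from reference parameters are recovered", {
  dog2 <- ref_params(2)
  obs <- generate_single_dose(dog2, error = error_model(0, 0))
  fit <- fit_pk(obs)
  expect_true(fit$converged)
  est <- coef(fit)
  truth <- c(k1 = 0.0030, c_a = 8.45, k0_over_v = 0.0032)
  expect_true(all(abs(est - truth) / truth < 1e-3))
  expect_equal(fit$fitting_degree, 1, tolerance = 1e-9)
  expect_lt(fit$wrss, 1e-12)
})

test_that("pure mono-exponential data drive the zero-order term to zero", {
  cp <- one_compartment_params(c0 = 9.5, k_el = 0.0042)
  tt <- beagle_schedule_single()
  d <- data.frame(time_h = tt, conc_mg_L = conc_classic(cp, tt))
  fd <- fit_pk(conc_mg_L ~ time_h, d)
  fc <- fit_pk(conc_mg_L ~ time_h, d, model = "one_compartment")
  expect_lt(coef(fd)[["k0_over_v"]], 1e-6)
  expect_lte(fd$wrss, fc$wrss + 1e-12)
  # classic fit recovers its own model essentially exactly
  expect_equal(coef(fc)[["c0"]], 9.5, tolerance = 1e-6)
  expect_equal(coef(fc)[["k_el"]], 0.0042, tolerance = 1e-6)
  expect_equal(fc$fitting_degree, 1, tolerance = 1e-9)
})

test_that("fitting is deterministic: identical inputs give identical results", {
  obs <- generate_single_dose(ref_params(3), error = error_model(0.05, seed = 99))
  f1 <- fit_pk(obs)
  f2 <- fit_pk(obs)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$wrss, f2$wrss)
  expect_identical(f1$residuals, f2$residuals)
  expect_identical(f1$irls_trace, f2$irls_trace)
})

test_that("IRLS converges fast on matched data and ends at reciprocal-observed weights", {
  for (i in c(1, 4)) {
    obs <- generate_single_dose(ref_params(i), error = error_model(0, 0))
    fit <- fit_pk(obs)
    expect_true(fit$converged)
    expect_lte(fit$n_irls_rounds, 5)
    # noiseless: predictions equal observations, so 1/pred == 1/obs
    expect_equal(fit$weights, 1 / pmax(fit$observed, fit$weighting$floor),
                 tolerance = 1e-6)
  }
})

test_that("alternative weighting schemes are honoured", {
  obs <- generate_single_dose(ref_params(2), error = error_model(0.05, seed = 5))
  fo <- fit_pk(obs, weighting = weight_config("reciprocal_observed"))
  fu <- fit_pk(obs, weighting = weight_config("unweighted"))
  expect_true(fo$converged && fu$converged)
  expect_equal(fo$weights, 1 / pmax(fo$observed, 0.01))
  expect_equal(fu$weights, rep(1, length(fu$observed)))
  # parameters from all schemes stay in the same ballpark (within 25%)
  fp <- fit_pk(obs)
  expect_true(all(abs(coef(fo) - coef(fp)) / coef(fp) < 0.25))
})

test_that("observations at or below the LOQ are excluded and counted", {
  dog2 <- ref_params(2)
  obs <- generate_single_dose(dog2, error = error_model(0, 0))
  loq <- 1.0  # censors the late tail of the noiseless curve
  fit <- fit_pk(obs, loq = loq)
  expect_equal(fit$n_below_loq, sum(obs$concentrations < loq))
  expect_true(all(fit$observed >= loq))
  expect_true(fit$converged)
  expect_true(all(abs(coef(fit) - as.vector(dog2)) / as.vector(dog2) < 1e-3))
})

test_that("fitting refuses series with too few quantifiable points", {
  expect_error(fit_pk(observed_series(c(1, 2, 3), c(5, 4, 3))),
               "at least 4")
  expect_error(fit_pk(observed_series(1, 5), model = "one_compartment"),
               "at least 2")
})

test_that("model comparison flags the lower-WRSS model and round-trips CSV", {
  obs <- generate_single_dose(ref_params(2), error = error_model(0.05, seed = 21))
  fn <- fit_pk(obs)
  fc <- fit_pk(obs, model = "one_compartment")
  cmp <- compare_pk_fits(fn, fc)
  expect_equal(cmp$table$model, c("dual_elimination", "one_compartment"))
  expect_true(cmp$table$winner[which.min(cmp$table$wrss)])

  # a model compared with itself ties with equal metrics
  tie <- compare_pk_fits(fn, fn)
  expect_equal(tie$table$wrss[1], tie$table$wrss[2])
  expect_true(all(tie$table$winner))

  # lossless CSV round trip
  path <- tempfile(fileext = ".csv")
  write_comparison_csv(cmp, path)
  back <- read_comparison_csv(path)
  expect_identical(back$wrss, cmp$table$wrss)
  expect_identical(back$fitting_degree, cmp$table$fitting_degree)
  expect_identical(back$model, cmp$table$model)

  # mismatched data are refused
  obs2 <- generate_single_dose(ref_params(3), error = error_model(0.05, seed = 22))
  expect_error(compare_pk_fits(fn, fit_pk(obs2)), "same observations")
})

test_that("data simulated from the dual model favour it over the classic fit", {
  # noiseless dual-model data with a real zero-order component: nesting
  # guarantees the richer model fits at least as well, and here strictly
  obs <- generate_single_dose(ref_params(1), error = error_model(0, 0))
  wu <- weight_config("unweighted")
  fn <- fit_pk(obs, weighting = wu)
  fc <- fit_pk(obs, model = "one_compartment", weighting = wu)
  expect_lt(fn$wrss, fc$wrss)
})

test_that("pk_fit methods expose the expected views of the fit", {
  obs <- generate_single_dose(ref_params(2), error = error_model(0.05, seed = 31))
  fit <- fit_pk(obs)
  expect_named(coef(fit), c("k1", "c_a", "k0_over_v"))
  expect_length(fitted(fit), length(fit$observed))
  expect_equal(residuals(fit, type = "raw"), fit$observed - fitted(fit))
  expect_equal(residuals(fit), sqrt(fit$weights) * residuals(fit, "raw"))
  expect_equal(predict(fit, times = 0), coef(fit)[["c_a"]])
  expect_output(print(fit), "Dual-elimination")
  expect_output(print(summary(fit)), "IRLS rounds")
  sims <- simulate(fit, nsim = 2, seed = 7)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "observed_series")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
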