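test_that("CO2 intramolecular inversion reproduces the mass-ratio identity", {
  ff <- mm_start_parameters()
  cf <- co2_intramolecular_fit(ff, nu_bend = 629, nu_sym = 1240)
  expect_equal(cf$nu_as_pred, 1240 * sqrt(1 + 2 * 15.999 / 12.011))
  expect_equal(cf$nu_as_pred, 2374, tolerance = 3e-4)
  # the installed constants really produce those frequencies
  mono <- minimize(build_monomer("CO2", ff = cf$ff), cf$ff)$system
  vib <- normal_modes(mono, cf$ff)$freq
  vib <- vib[abs(vib) >= 15]
  expect_equal(vib, c(629, 629, 1240, cf$nu_as_pred), tolerance = 1e-4)
  expect_error(co2_intramolecular_fit(ff, nu_bend = -10, nu_sym = 1240))
})

test_that("calibration recovers known parameters from synthetic data", {
  # round trip: generate observables from a known CO2 parameter vector,
  # then refit from a perturbed start and compare
  ff_true <- co2_intramolecular_fit(mm_start_parameters())$ff
  th_true <- c(1.60, 1.70, 1.50, 0.070, 0.076)
  ff_true <- co2mea:::.co2_theta_set(ff_true, th_true)
  ref <- build_reference_set()
  rows <- ref$structure %in% c("min", "parallel", "T") &
    ref$kind != "frequency" & ref$weight > 0
  synth <- ref
  synth$target[rows] <- co2mea:::.eval_observables(
    ff_true, ref[rows, , drop = FALSE])
  ff_start <- co2mea:::.co2_theta_set(
    co2_intramolecular_fit(mm_start_parameters())$ff,
    th_true * c(1.1, 0.97, 1.04, 1.3, 0.8))
  fit <- fit_parameters(synth, ff_start,
                        settings = list(stages = "co2", multistart = FALSE,
                                        maxit = 40))
  th_fit <- co2mea:::.co2_theta_get(fit$ff)
  expect_equal(unname(th_fit), th_true, tolerance = 0.01)
  # residuals on the synthetic targets collapse
  fitted <- fit$residuals[rows, ]
  expect_lt(max(abs(fitted$residual)), 0.01)
})

test_that("fit result bookkeeping aligns with the reference set", {
  ref <- build_reference_set()
  ff <- mm_parameters()   # shipped calibrated set: evaluate, no refit
  vals <- co2mea:::.eval_observables(ff, ref)
  expect_length(vals, nrow(ref))
  # context rows are not evaluated
  expect_true(all(is.na(vals[ref$kind == "context"])))
  expect_true(all(is.finite(vals[ref$weight > 0])))
})

test_that("zero-weight observables do not steer the fit", {
  ref <- build_reference_set()
  # keep only the minimum-dimer total: the fit should drive that residual
  # far below the others
  ref$weight[] <- 0
  ref$weight[ref$id == "co2_min_total"] <- 1
  ff0 <- co2_intramolecular_fit(mm_start_parameters())$ff
  ff0 <- co2mea:::.co2_theta_set(ff0, c(1.60, 1.70, 1.50, 0.070, 0.076))
  fit <- fit_parameters(ref, ff0,
                        settings = list(stages = "co2", multistart = FALSE,
                                        maxit = 25))
  r <- fit$residuals
  expect_lt(abs(r$residual[r$id == "co2_min_total"]), 0.05)
})
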