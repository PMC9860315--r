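test_that("peak extraction is exact on clean traces and baseline-invariant", {
  pro <- tevc_protocol(n_pulses = 2)
  flat <- simulate_tevc_trace(pro, peak_uA = 0)
  expect_equal(extract_peak_currents(flat), c(0, 0))

  tr <- simulate_tevc_trace(pro, peak_uA = 1.5, desensitization_fraction = 0.1)
  pk <- extract_peak_currents(tr)
  expect_equal(abs(pk), attr(tr, "planted_peaks_uA"), tolerance = 1e-6)
  expect_true(all(pk < 0))  # inward currents are negative

  shifted <- tr
  shifted$current_uA <- shifted$current_uA + 1
  expect_equal(extract_peak_currents(shifted), pk, tolerance = 1e-9)

  bad <- data.frame(t_on = 1e5, t_off = 1e5 + 1)
  expect_error(extract_peak_currents(tr, bad), "outside")
})

test_that("normalization maps each oocyte's maximum to 1 and is idempotent", {
  d <- data.frame(oocyte_id = c(1, 1, 1, 2, 2),
                  conc_uM = c(10, 100, 1000, 10, 100),
                  peak_uA = c(-2, -4, -8, -1, -5))
  dr <- normalize_responses(d)
  expect_equal(dr$response[dr$oocyte_id == 1], c(0.25, 0.5, 1))
  expect_equal(dr$response[dr$oocyte_id == 2], c(0.2, 1))
  again <- normalize_responses(data.frame(oocyte_id = dr$oocyte_id,
                                          conc_uM = dr$conc_uM,
                                          peak_uA = dr$response))
  expect_equal(again$response, dr$response)
  # single peak normalizes to 1; all-zero oocytes are dropped with a warning
  expect_equal(normalize_responses(data.frame(oocyte_id = 1, conc_uM = 1,
                                              peak_uA = -3))$response, 1)
  dz <- data.frame(oocyte_id = c(1, 1, 2, 2), conc_uM = c(1, 10, 1, 10),
                   peak_uA = c(0, 0, -1, -2))
  expect_warning(out <- normalize_responses(dz), "all-zero")
  expect_identical(unique(out$oocyte_id), 2)
})

test_that("noiseless EC50 recovery and half-max identity", {
  conc <- 211 * 10^seq(-1, 1, length.out = 8)
  dr <- simulate_dose_response(211, 1.5, concentrations_uM = conc,
                               n_oocytes = 6, noise_sd = 0)
  fit <- fit_hill_activation(dr)
  expect_lt(abs(fit$ec50 - 211) / 211, 0.01)
  expect_equal(fit$hill_coefficient, 1.5, tolerance = 1e-3)
  expect_identical(fit$model_order, 3)
  # the fitted curve passes through half-max at the EC50
  half <- fit$bottom + (fit$top - fit$bottom) /
    (1 + (fit$ec50 / fit$ec50)^fit$hill_coefficient)
  expect_equal(half, (fit$top + fit$bottom) / 2)
})

test_that("four-parameter data select the four-parameter model", {
  conc <- 100 * 10^seq(-1.5, 1.5, length.out = 9)
  dr <- simulate_dose_response(100, 1.2, top = 1, bottom = 0.3,
                               concentrations_uM = conc, n_oocytes = 4,
                               noise_sd = 0)
  fit <- fit_hill_activation(dr)
  expect_identical(fit$model_order, 4)
  expect_equal(fit$bottom, 0.3, tolerance = 1e-3)
  expect_lt(abs(fit$ec50 - 100) / 100, 0.01)
})

test_that("noiseless IC50 recovery for both antagonist regimes", {
  for (ic50 in c(973, 144)) {
    conc <- ic50 * 10^seq(-1, 1, length.out = 8)
    dr <- simulate_dose_response(ic50, 1.5, concentrations_uM = conc,
                                 n_oocytes = 6, noise_sd = 0,
                                 mode = "inhibition")
    fit <- fit_hill_inhibition(dr)
    expect_lt(abs(fit$ec50 - ic50) / ic50, 0.01)
    expect_identical(fit$mode, "inhibition")
  }
})

test_that("flat inhibition data are flagged as unidentifiable", {
  dr <- data.frame(conc_uM = rep(c(10, 100, 1000), 3), response = 1)
  expect_warning(fit_hill_inhibition(dr), "flat")
})

test_that("an EC50 outside the tested range triggers an extrapolation warning", {
  conc <- c(1, 3, 10, 30)  # all well below the EC50 of 1000
  dr <- simulate_dose_response(1000, 1, concentrations_uM = conc,
                               n_oocytes = 3, noise_sd = 0)
  expect_warning(fit_hill_activation(dr), "extrapolat")
})

test_that("noisy EC50 recovery: error, CI coverage, and model-order stability", {
  conc <- 211 * 10^seq(-1, 1, length.out = 8)
  stats <- vapply(1:100, function(s) {
    dr <- simulate_dose_response(211, 1.5, concentrations_uM = conc,
                                 n_oocytes = 6, noise_sd = 0.05, seed = s)
    f <- suppressWarnings(fit_hill_activation(dr))
    ci <- exp(log(f$ec50) + c(-2, 2) * f$se_log_ec50)
    c(abs(f$ec50 - 211) / 211,
      as.numeric(211 >= ci[1] && 211 <= ci[2]),
      as.numeric(f$model_order == 3))
  }, numeric(3))
  expect_lte(median(stats[1, ]), 0.05)
  expect_gte(mean(stats[2, ]), 0.9)
  expect_gte(mean(stats[3, ]), 0.9)
})

test_that("reversal potential extraction finds the zero crossing", {
  # analytic line I = V + 20
  ramp <- structure(data.frame(voltage_mV = seq(-80, 60, by = 0.5)),
                    class = c("iv_ramp", "data.frame"))
  ramp$current_uA <- ramp$voltage_mV + 20
  expect_equal(extract_reversal_potential(ramp), -20, tolerance = 1e-9)

  sim <- simulate_iv_ramp(erev_mV = -45, conductance = 0.05)
  expect_equal(extract_reversal_potential(sim), -45, tolerance = 1e-9)

  noisy <- simulate_iv_ramp(erev_mV = -45, conductance = 0.05,
                            noise_sd = 0.02, seed = 5)
  expect_lt(abs(extract_reversal_potential(noisy) + 45), 0.5)
})

test_that("reversal potential is invariant to scaling and same-reversal leak", {
  sim <- simulate_iv_ramp(erev_mV = -30, conductance = 0.05, noise_sd = 0.01,
                          seed = 8)
  e0 <- extract_reversal_potential(sim)
  scaled <- sim
  scaled$current_uA <- scaled$current_uA * 4
  expect_equal(extract_reversal_potential(scaled), e0, tolerance = 1e-6)
  leaky <- sim
  leaky$current_uA <- leaky$current_uA + 0.02 * (leaky$voltage_mV + 30)
  expect_equal(extract_reversal_potential(leaky), e0, tolerance = 0.5)
})

test_that("a ramp with no sign change reports a missing reversal", {
  ramp <- structure(data.frame(voltage_mV = seq(-80, 60, by = 1)),
                    class = c("iv_ramp", "data.frame"))
  ramp$current_uA <- ramp$voltage_mV + 200
  expect_warning(e <- extract_reversal_potential(ramp), "sign")
  expect_true(is.na(e))
})

test_that("delta_erev reports the paired shift with its SEM", {
  nd <- lapply(1:5, function(i) simulate_iv_ramp(0, 0.05))
  expect_equal(delta_erev(nd, nd)$mean_delta_mV, 0, tolerance = 1e-9)
  expect_equal(delta_erev(nd, nd)$sem_mV, 0, tolerance = 1e-9)

  low <- lapply(1:5, function(i) simulate_iv_ramp(-43.1, 0.05))
  res <- delta_erev(nd, low)
  expect_equal(res$mean_delta_mV, -43.1, tolerance = 1e-6)
  expect_identical(res$n, 5L)

  noisy_nd <- lapply(1:9, function(i) simulate_iv_ramp(0, 0.05,
                                                       noise_sd = 0.05,
                                                       seed = i))
  noisy_low <- lapply(1:9, function(i) simulate_iv_ramp(-43.1, 0.05,
                                                        noise_sd = 0.05,
                                                        seed = 100 + i))
  resn <- delta_erev(noisy_nd, noisy_low)
  expect_lt(abs(resn$mean_delta_mV + 43.1), 3 * max(resn$sem_mV, 0.1))

  expect_error(delta_erev(nd, nd[1:3]), "paired")
})

test_that("pulse ratios are peaks relative to the first pulse", {
  expect_equal(pulse_ratio(c(10, 10, 10))$ratios, c(1, 1))
  expect_equal(pulse_ratio(c(10, 8))$ratios, 0.8)
  tr <- simulate_tevc_trace(tevc_protocol(n_pulses = 3), peak_uA = 1,
                            desensitization_fraction = 0.2)
  expect_equal(pulse_ratio(extract_peak_currents(tr))$ratios, c(0.8, 0.64),
               tolerance = 1e-5)
  expect_warning(z <- pulse_ratio(c(0, 1)), "zero")
  expect_true(all(is.na(z$ratios)))
  expect_error(pulse_ratio(5), "at least 2")
})
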