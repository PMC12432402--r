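test_that("baseline estimator quantifies step mismatch", {
  tt <- seq(0, 180, 0.2)
  flat <- taylorgram(tt, gaussian_model(tt, 100, 106, 5.4, 0))
  bl <- estimate_baseline(flat)
  expect_equal(bl$baseline, 0, tolerance = 1e-9)
  expect_equal(bl$mismatch_score, 0, tolerance = 1e-9)
  # constructed 20%-of-peak step across the peak
  stepped <- taylorgram(tt, gaussian_model(tt, 100, 106, 5.4, 0) +
                              20 * (tt > 106))
  expect_equal(estimate_baseline(stepped)$mismatch_score, 0.2,
               tolerance = 0.1)
  expect_error(estimate_baseline(taylorgram(1:50, rnorm(50))), NA)
})

test_that("fit is equivariant under signal scaling and time shift", {
  tg <- simulate_taylorgram(default_method, species_state(1.15),
                            noise_sd = 0.5, seed = 21)
  f0 <- fit_taylorgram(tg, default_method)
  scaled <- taylorgram(tg$time, tg$signal * 7, tg$meta)
  fs <- fit_taylorgram(scaled, default_method)
  expect_lt(rel_err(fs$rh, f0$rh), 1e-6)
  expect_equal(fs$amplitude, 7 * f0$amplitude, tolerance = 1e-6)
  # consistent time-origin shift moves t_R and nothing else
  shifted <- taylorgram(tg$time + 13, tg$signal, tg$meta)
  fh <- fit_taylorgram(shifted, default_method)
  expect_equal(fh$retention_time, f0$retention_time + 13, tolerance = 1e-6)
  expect_equal(fh$sigma_t, f0$sigma_t, tolerance = 1e-8)
})

test_that("two-species fit with a locked free-label radius recovers mixtures", {
  mix <- simulate_taylorgram(default_method,
                             list(species_state(2.96, 0.8),
                                  species_state(0.6, 0.2)),
                             indicator_conc = 80e-9)
  opt <- fit_options(locked_rh_second_species = 0.6)
  f2 <- fit_taylorgram(mix, default_method, opt)
  expect_lt(rel_err(f2$rh, 2.96), 0.01)
  expect_lt(abs(f2$mole_fraction_main - 0.8), 0.02)
  # a single-species fit on the same mixture lands strictly between
  f1 <- fit_taylorgram(mix, default_method)
  expect_gt(f1$rh, 0.6); expect_lt(f1$rh, 2.96)
})

test_that("two-species fit nests the single-species fit", {
  tg <- simulate_taylorgram(default_method, species_state(2.96),
                            indicator_conc = 80e-9)
  f1 <- fit_taylorgram(tg, default_method)
  f2 <- fit_taylorgram(tg, default_method,
                       fit_options(locked_rh_second_species = 0.6))
  expect_lt(f2$locked_amplitude / f2$amplitude, 1e-4)
  expect_lt(rel_err(f2$rh, f1$rh), 1e-4)
})

test_that("a peak narrower than the injection plug is an explicit failure", {
  tt <- seq(0, 180, 0.02)
  narrow <- taylorgram(tt, gaussian_model(tt, 100, 106, 0.2, 0))
  f <- fit_taylorgram(narrow, default_method)
  expect_false(f$converged)
  expect_match(f$message, "plug")
  expect_error(predict(f), "failed")
})

test_that("low signal-to-noise and Taylor violations are flagged", {
  noisy <- simulate_taylorgram(default_method, species_state(1.15),
                               indicator_conc = 50e-9, noise_sd = 2,
                               seed = 31)  # S/N = 25
  f <- fit_taylorgram(noisy, default_method)
  expect_true("LOW_SNR" %in% f$flags)
  expect_lt(f$snr, 50)
  # a very large species at the default program leaves the Taylor regime
  big <- simulate_taylorgram(default_method, species_state(60))
  fb <- fit_taylorgram(big, default_method)
  expect_true("TAYLOR_INVALID" %in% fb$flags)
})

test_that("viscosity normalization is exact and linear", {
  tr0 <- transit_time(default_method, 400, 0.84)
  lys <- lysate_model("heat", viscosity_factor_at_stock = 2,
                      nonspecific_rh_shift = 0, autofluorescence_level = 0,
                      baseline_mismatch_amplitude = 0)
  tg <- simulate_taylorgram(default_method, species_state(1.15),
                            lysate = lys, dilution = 1)
  f <- fit_taylorgram(tg, default_method)
  # uncorrected radius inflated by the viscosity factor
  expect_equal(f$rh / 1.15, 2, tolerance = 0.02)
  fc <- viscosity_normalize(f, tr0)
  expect_lt(rel_err(fc$rh, 1.15), 0.02)
  expect_equal(fc$viscosity_factor, 2, tolerance = 0.01)
  expect_true("VISCOSITY_CORRECTED" %in% fc$flags)
  # correction is exactly linear: corrected rh x f = apparent rh
  expect_equal(fc$rh * fc$viscosity_factor, f$rh, tolerance = 1e-12)
  # f = 1 leaves the radius unchanged
  f1 <- viscosity_normalize(f, f$retention_time)
  expect_equal(f1$rh, f$rh)
  expect_warning(viscosity_normalize(f, f$retention_time * 2), "suspicious")
})

test_that("replicate summary follows the mean +/- SD convention", {
  mk <- function(rh, flags = character(0))
    structure(list(converged = TRUE, rh = rh, flags = flags),
              class = "fida_fit")
  s <- replicate_summary(list(mk(1.0), mk(1.1), mk(1.2, "LOW_SNR")))
  expect_equal(s$rh_mean, 1.1)
  expect_equal(s$rh_sd, 0.1)
  expect_equal(s$n, 3)
  expect_true("LOW_SNR" %in% s$flags)
  expect_identical(replicate_summary(list(mk(1.0)))$rh_sd, NA_real_)
  expect_equal(replicate_summary(list(mk(2), mk(2)))$rh_sd, 0)
  expect_error(replicate_summary(list()), "empty")
})

test_that("radius accuracy holds across sizes and noise levels", {
  # 200 seeded traces spanning rh 0.6-5 nm, S/N 50-500
  set.seed(17)
  rhs <- exp(runif(200, log(0.6), log(5)))
  snrs <- exp(runif(200, log(50), log(500)))
  errs <- vapply(seq_len(200), function(i) {
    tg <- simulate_taylorgram(default_method, species_state(rhs[i]),
                              indicator_conc = 100e-9,
                              noise_sd = 100 / snrs[i], seed = 1000 + i)
    f <- fit_taylorgram(tg, default_method)
    if (!f$converged) return(NA_real_)
    rel_err(f$rh, rhs[i])
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(median(errs), 0.02)
})
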