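test_that("all simulator randomness flows from the seed", {
  a <- simulate_taylorgram(default_method, species_state(1.15),
                           noise_sd = 1, seed = 5)
  b <- simulate_taylorgram(default_method, species_state(1.15),
                           noise_sd = 1, seed = 5)
  c <- simulate_taylorgram(default_method, species_state(1.15),
                           noise_sd = 1, seed = 6)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))

  truth <- campaign_preset("alfa")
  s1 <- simulate_screen_rh(truth, dilution = 30, seed = 2)
  s2 <- simulate_screen_rh(truth, dilution = 30, seed = 2)
  expect_identical(s1, s2)
})

test_that("noiseless single-species traces round-trip through the fitter", {
  for (rh in c(0.5, 1.15, 2.96, 5, 10)) {
    tg <- simulate_taylorgram(default_method, species_state(rh))
    f <- fit_taylorgram(tg, default_method)
    expect_true(f$converged)
    expect_lt(rel_err(f$rh, rh), 1e-3)
  }
})

test_that("lysate viscosity scales the retention time by the ideal-mixing rule", {
  lys <- lysate_model("heat", viscosity_factor_at_stock = 1.5,
                      nonspecific_rh_shift = 0, autofluorescence_level = 0,
                      baseline_mismatch_amplitude = 0)
  tg <- simulate_taylorgram(default_method, species_state(1.15),
                            lysate = lys, dilution = 2)
  f <- fit_taylorgram(tg, default_method)
  tr0 <- transit_time(default_method, 400, 0.84)
  # factor interpolates 1 + (1.5 - 1)/2 = 1.25
  expect_equal(f$retention_time / tr0, 1.25, tolerance = 1e-3)
})

test_that("a concentrated-lysate baseline mismatch is detected downstream", {
  lys <- lysate_model("chemical")
  tg <- simulate_taylorgram(default_method, species_state(1.15),
                            lysate = lys, dilution = 2,
                            indicator_conc = 200e-9)
  f <- fit_taylorgram(tg, default_method)
  expect_true("BASELINE_MISMATCH" %in% f$flags)
  # at high dilution the step fades below the documented 5% criterion
  tg2 <- simulate_taylorgram(default_method, species_state(1.15),
                             lysate = lys, dilution = 100,
                             indicator_conc = 200e-9)
  expect_false("BASELINE_MISMATCH" %in% fit_taylorgram(tg2, default_method)$flags)
})

test_that("titration generator respects equilibrium limits and kinetics", {
  ladder <- 0.1e-6 * 2^(0:11)
  # no analyte -> free radius exactly
  tt <- simulate_titration(2.76e-6, 1.15, 2.40, 50e-9, c(0, ladder))
  expect_equal(tt$rh_nm[1], 1.15)
  # fast-association limit reproduces the equilibrium curve point-wise
  eq <- simulate_titration(2.76e-6, 1.15, 2.40, 50e-9, ladder)
  kin <- simulate_titration(2.76e-6, 1.15, 2.40, 50e-9, ladder,
                            kinetics = list(kon = 1e12, koff = 1e3))
  expect_equal(kin$rh_nm, eq$rh_nm, tolerance = 1e-12)
  # slow association under-reads binding in capmix mode
  slow <- simulate_titration(2.76e-6, 1.15, 2.40, 50e-9, ladder,
                             kinetics = list(kon = 100, koff = 100 * 2.76e-6))
  expect_true(all(slow$rh_nm <= eq$rh_nm))
  expect_error(simulate_titration(1e-6, 1, 2, 5e-8, c(-1e-6, 1e-6)), ">= 0")
})

test_that("campaign sheet and truth record are mutually consistent", {
  truth <- campaign_preset("alfa")
  camp <- simulate_campaign(truth, lysate_model("heat"), default_method,
                            noise_sd = 1, seed = 4)
  # every trace maps to exactly one sheet row
  expect_setequal(names(camp$traces), camp$sheet$sample_id)
  expect_false(any(duplicated(camp$sheet$sample_id)))
  # all binder ids in the sheet exist in the truth record
  bid <- camp$sheet$binder_id[camp$sheet$role == "binder"]
  expect_true(all(bid %in% truth$binders$binder_id))
  # design: replicates x (binders + PC) x ladder + buffer references
  expect_equal(nrow(camp$sheet),
               truth$replicates *
                 ((nrow(truth$binders) + 1) * length(truth$dilution_ladder) + 1))
})

test_that("preculture traces recover the indicator radius plus host background", {
  truth <- campaign_preset("alfa")
  lys <- lysate_model("heat")
  camp <- simulate_campaign(truth, lys, default_method, noise_sd = 0, seed = 8)
  f <- fit_taylorgram(camp$traces[["PC_d30_r1"]], default_method)
  f <- viscosity_normalize(f, transit_time(default_method, 400, 0.84))
  expected <- 1.15 + lys$nonspecific_rh_shift * lys$preculture_shift_frac / 30
  expect_equal(f$rh, expected, tolerance = 5e-3)
})

test_that("mixtures must have mole fractions summing to one", {
  expect_error(simulate_taylorgram(default_method,
                                   list(species_state(1, 0.5),
                                        species_state(2, 0.4))), "sum to 1")
  expect_error(simulate_taylorgram(default_method, list()), "at least one")
})
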