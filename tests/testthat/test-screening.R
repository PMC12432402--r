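test_that("threshold rule implements the 10% cutoff and is scale-invariant", {
  sm <- data.frame(binder_id = c("a", "b", "c"),
                   rh_mean = c(1.15, 1.27, 1.26))
  out <- call_hits_threshold(sm, reference_rh = 1.15)
  # cutoff is 1.265 nm for the 1.15 nm indicator
  expect_identical(out$hit_threshold, c(FALSE, TRUE, FALSE))
  expect_equal(out$pct_change[1], 0)
  # degenerate theta = 0: anything above the reference is a hit
  out0 <- call_hits_threshold(sm, 1.15, theta = 0)
  expect_identical(out0$hit_threshold, c(TRUE, TRUE, TRUE))
  # scale invariance
  for (c_ in c(0.1, 3, 100)) {
    smc <- transform(sm, rh_mean = rh_mean * c_)
    expect_identical(call_hits_threshold(smc, 1.15 * c_)$hit_threshold,
                     out$hit_threshold)
  }
})

test_that("Dunnett p-values match the reference multivariate-t computation", {
  skip_if_not_installed("mvtnorm")
  set.seed(12)
  # unbalanced layout with one shifted group
  d <- data.frame(
    binder_id = rep(c("PC", "B1", "B2", "B3"), times = c(4, 3, 3, 5)),
    rh_nm = rnorm(15, 2.96, 0.02))
  d$rh_nm[d$binder_id == "B2"] <- d$rh_nm[d$binder_id == "B2"] + 0.08
  out <- call_hits_dunnett(d)
  # rebuild the adjusted p-values from first principles with pmvt
  nn <- table(d$binder_id)
  ids <- out$binder_id
  ybar <- tapply(d$rh_nm, d$binder_id, mean)
  ss <- tapply(d$rh_nm, d$binder_id, function(v) sum((v - mean(v))^2))
  df <- sum(nn) - length(nn)
  s2 <- sum(ss) / df
  tstat <- (ybar[ids] - ybar[["PC"]]) /
    sqrt(s2 * (1 / nn[ids] + 1 / nn[["PC"]]))
  lam <- sqrt(nn[ids] / (nn[ids] + nn[["PC"]]))
  R <- outer(lam, lam); diag(R) <- 1
  set.seed(1)
  ref <- vapply(tstat, function(ti)
    1 - mvtnorm::pmvt(upper = rep(ti, 3), df = df, corr = R,
                      algorithm = mvtnorm::GenzBretz(maxpts = 50000,
                                                     abseps = 1e-5))[1],
    numeric(1))
  expect_equal(out$p_adjusted, unname(ref), tolerance = 1e-3)
})

test_that("Dunnett adjustment is conservative relative to raw p-values", {
  set.seed(33)
  d <- data.frame(binder_id = rep(c("PC", paste0("B", 1:6)), each = 3),
                  rh_nm = rnorm(21, 1.15, 0.01))
  out <- call_hits_dunnett(d)
  nn <- table(d$binder_id); df <- sum(nn) - length(nn)
  s2 <- sum(tapply(d$rh_nm, d$binder_id,
                   function(v) sum((v - mean(v))^2))) / df
  ybar <- tapply(d$rh_nm, d$binder_id, mean)
  traw <- (ybar[out$binder_id] - ybar[["PC"]]) / sqrt(s2 * (2 / 3))
  p_raw <- stats::pt(traw, df, lower.tail = FALSE)
  expect_true(all(out$p_adjusted >= unname(p_raw) - 1e-10))
})

test_that("a large standardized shift is called at p < 0.001", {
  d <- data.frame(binder_id = rep(c("PC", "B1"), each = 3),
                  rh_nm = c(2.95, 2.96, 2.97, 3.40, 3.42, 3.41))
  out <- call_hits_dunnett(d)
  expect_true(out$hit_statistical)
  expect_lt(out$p_adjusted, 0.001)
  # identical to control: far from significant
  same <- data.frame(binder_id = rep(c("PC", "B1"), each = 3),
                     rh_nm = rep(c(2.95, 2.96, 2.97), 2))
  expect_false(call_hits_dunnett(same)$hit_statistical)
})

test_that("Dunnett errors name missing controls and tiny groups", {
  d <- data.frame(binder_id = rep(c("PC", "B1"), each = 3),
                  rh_nm = rnorm(6))
  expect_error(call_hits_dunnett(d, control = "CTRL"), "CTRL")
  d2 <- rbind(d, data.frame(binder_id = "B2", rh_nm = 1))
  expect_error(call_hits_dunnett(d2), "B2")
})

test_that("perfect separation scores zero false positives and negatives", {
  sm <- data.frame(
    role = c("preculture", rep("binder", 4)),
    binder_id = c(NA, "T1", "T2", "N1", "N2"),
    dilution_factor = 30,
    rh_mean = c(1.15, 2.0, 2.1, 1.16, 1.14),
    rh_sd = 0.01, n = 3)
  rep_rh <- do.call(rbind, lapply(seq_len(nrow(sm)), function(i)
    data.frame(role = sm$role[i], binder_id = sm$binder_id[i],
               dilution_factor = 30, replicate = 1:3,
               rh_nm = sm$rh_mean[i] + c(-0.01, 0, 0.01))))
  truth <- campaign_truth(
    data.frame(binder_id = c("T1", "T2", "N1", "N2"),
               true_kd_M = c(1e-6, 1e-6, NA, NA),
               expression_conc_M = 1e-4,
               complex_rh_nm = c(2.0, 2.1, NA, NA),
               nonspecific_scale = 1),
    indicator_rh_free_nm = 1.15, indicator_conc_M = 200e-9,
    dilution_ladder = 30)
  rep_ <- dilution_series_report(list(summaries = sm, replicate_rh = rep_rh),
                                 truth)
  expect_true(all(rep_$by_dilution$fp == 0))
  expect_true(all(rep_$by_dilution$fn == 0))
})

test_that("thermostability outcomes cover retained, lost and inconclusive", {
  expect_equal(thermostability_compare(1.9, 1.9, 1.15), "retained")
  # binder that loses binding after 5 min at 95 C (below the 1.265 cutoff)
  expect_equal(thermostability_compare(1.9, 1.16, 1.15), "lost")
  expect_equal(thermostability_compare(1.2, 1.9, 1.15), "inconclusive")
  expect_equal(thermostability_compare(1.2, 1.1, 1.15), "inconclusive")
})
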