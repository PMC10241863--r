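make_ramp_trace <- function(slope = 0.05, baseline = 0, rate = 100,
                            duration = 90, premove = 10, noise = 0,
                            seed = 1) {
  t <- seq(0, duration, by = 1 / rate)
  pos <- pmax(t - premove, 0) * 0.1
  f <- baseline + pmax(t - premove - 5, 0) * slope
  if (noise > 0) f <- with_seed(seed, f + rnorm(length(f), sd = noise))
  probe_trace(t, pos, f)
}

test_that("baseline correction removes a constant offset exactly", {
  tr <- make_ramp_trace(baseline = 0.3)
  corr <- baseline_correct(tr)
  expect_equal(attr(corr, "baseline_mN"), 0.3, tolerance = 1e-12)
  pre <- corr$time_s < attr(corr, "onset_s")
  expect_equal(mean(corr$force_mN[pre]), 0, tolerance = 1e-12)
})

test_that("baseline correction leaves slopes unchanged and needs pre-movement data", {
  tr <- make_ramp_trace(slope = 0.07, baseline = 0.5, noise = 0.01)
  corr <- baseline_correct(tr)
  fit_raw <- coef(lm(force_mN ~ time_s, tr[tr$time_s > 20, ]))[2]
  fit_cor <- coef(lm(force_mN ~ time_s, corr[corr$time_s > 20, ]))[2]
  expect_equal(unname(fit_cor), unname(fit_raw), tolerance = 1e-12)

  nohead <- probe_trace(tr$time_s, pmax(tr$time_s, 0) * 0.1, tr$force_mN)
  expect_error(baseline_correct(nohead),
               class = "vitmech_insufficient_baseline")
})

test_that("post-correction baseline mean shrinks with averaging", {
  tr <- gen_probe_trace(0.08, baseline_mN = 0.3, noise_sd_mN = 0.01, seed = 2)
  corr <- baseline_correct(tr)
  pre <- corr$time_s < attr(corr, "onset_s")
  # mean of the pre-movement residuals is of order sd/sqrt(n)
  n <- sum(pre)
  expect_lt(abs(mean(corr$force_mN[pre])), 4 * 0.01 / sqrt(n))
})

test_that("1-Hz averaging preserves constants and slopes, shrinks noise", {
  const <- probe_trace(seq(0, 30, by = 0.01), rep(0, 3001), rep(2.5, 3001))
  d <- downsample_1hz(const)
  expect_true(all(abs(d$force_mN - 2.5) < 1e-12))
  expect_equal(median(diff(d$time_s)), 1)

  tt <- seq(0, 60, by = 0.01)[-6001]        # whole 1-s bins only
  ramp <- probe_trace(tt, rep(0, 6000), 0.04 * tt)
  dr <- downsample_1hz(ramp)
  expect_equal(unname(coef(lm(force_mN ~ time_s, dr))[2]), 0.04,
               tolerance = 1e-10)

  sd_hi <- 0.5
  tn <- seq(0, 400, by = 0.01)[-40001]
  noise <- with_seed(7, probe_trace(tn, rep(0, 40000),
                                    rnorm(40000, sd = sd_hi)))
  dn <- downsample_1hz(noise)
  ratio <- sd(dn$force_mN) / (sd_hi / 10)     # sqrt(100) averaging law
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("QC flags rupture, holder hits, absent contact, and passes ramps", {
  ok <- analyse_probe_trace(gen_probe_trace(0.08, seed = 3))
  expect_equal(ok$qc, "ok")

  rup <- gen_probe_trace(0.08, rupture = list(time = 30, drop = 1), seed = 4)
  expect_equal(analyse_probe_trace(rup)$qc, "early_rupture")

  hit <- gen_probe_trace(0.3, noise_sd_mN = 0.005, seed = 5)
  expect_equal(analyse_probe_trace(hit, force_cap = 5)$qc, "holder_hit")

  flat <- gen_probe_trace(0, baseline_mN = 0.2, noise_sd_mN = 0.005, seed = 6)
  expect_equal(analyse_probe_trace(flat)$qc, "no_contact")
})

test_that("an exact ramp yields its slope exactly", {
  tr <- make_ramp_trace(slope = 0.05)
  res <- analyse_probe_trace(tr)
  expect_equal(res$slope_mN_per_s, 0.05, tolerance = 1e-10)
  expect_equal(res$window_end_s - res$window_start_s, 19)  # 20 samples at 1 Hz
})

test_that("slope recovery on noisy generator traces is within 5%", {
  for (seed in 1:4) {
    tr <- gen_probe_trace(0.08, noise_sd_mN = 0.01, seed = seed)
    res <- analyse_probe_trace(tr)
    expect_equal(res$qc, "ok")
    expect_lt(abs(res$slope_mN_per_s / 0.08 - 1), 0.05)
  }
})

test_that("the fitted window avoids a soft quadratic contact onset", {
  tr <- gen_probe_trace(0.08, onset_dur_s = 4, noise_sd_mN = 0.005, seed = 8)
  truth <- attr(tr, "truth")
  res <- analyse_probe_trace(tr)
  expect_gte(res$window_start_s, truth$contact_time_s + truth$onset_dur_s)
})

test_that("slope is invariant under force offset and time shift, linear in units", {
  tr <- gen_probe_trace(0.06, noise_sd_mN = 0.005, seed = 9)
  base <- analyse_probe_trace(tr)
  off <- probe_trace(tr$time_s, tr$position_mm, tr$force_mN + 1.23)
  shift <- probe_trace(tr$time_s + 100, tr$position_mm, tr$force_mN)
  dbl <- probe_trace(tr$time_s, tr$position_mm, tr$force_mN * 2)
  expect_equal(analyse_probe_trace(off)$slope_mN_per_s, base$slope_mN_per_s,
               tolerance = 1e-9)
  expect_equal(analyse_probe_trace(shift)$slope_mN_per_s,
               base$slope_mN_per_s, tolerance = 1e-9)
  expect_equal(analyse_probe_trace(dbl)$slope_mN_per_s,
               2 * base$slope_mN_per_s, tolerance = 1e-9)
})

test_that("a push phase shorter than the window is refused", {
  tr <- gen_probe_trace(0.08, duration_s = 40, contact_time_s = 15, seed = 10)
  corr <- downsample_1hz(baseline_correct(tr))
  expect_error(linear_phase_slope(corr, window = 20),
               class = "vitmech_insufficient_data")
})
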