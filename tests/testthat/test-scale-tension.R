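test_that("tension formulas are exact closed forms", {
  ev <- list(m_detached_g = 10, m_after_cut_g = 9.2, m_breaking_g = 6)
  expect_equal(native_tension(ev, width_m = 0.02), 0.392)          # 0.8 g
  ev2 <- list(m_detached_g = 10, m_after_cut_g = 8.5, m_breaking_g = 6)
  expect_equal(native_tension(ev2, width_m = 0.02), 0.735)         # 1.5 g
  ev3 <- list(m_detached_g = 10, m_after_cut_g = 10, m_breaking_g = 6)
  expect_equal(native_tension(ev3, width_m = 0.02), 0)
  expect_equal(max_tension(ev3, width_m = 0.02), 1.96)             # 4.0 g
  expect_equal(max_tension(list(m_detached_g = 5, m_breaking_g = 5),
                           width_m = 0.02), 0)
})

test_that("tension is linear in the weight difference and in 1/L", {
  base <- list(m_detached_g = 10, m_after_cut_g = 9, m_breaking_g = 6)
  doubled <- list(m_detached_g = 10, m_after_cut_g = 8, m_breaking_g = 6)
  expect_equal(native_tension(doubled), 2 * native_tension(base))
  expect_equal(native_tension(base, width_m = 0.01),
               2 * native_tension(base, width_m = 0.02))
  expect_error(native_tension(base, width_m = 0), class = "vitmech_domain_error")
})

test_that("event detection recovers generator plateaus and breaking weight", {
  tr <- gen_scale_trace(0.735, 1.96, clip_weight_g = 10, noise_sd_g = 0.02,
                        seed = 11)
  ev <- detect_events(tr, plateau_tol = 0.2, jump_tol = 0.3)
  truth <- attr(tr, "truth")
  expect_equal(ev$qc, "ok")
  expect_lt(abs(ev$m_detached_g - truth$m_detached_g), 0.2)
  expect_lt(abs(ev$m_after_cut_g - truth$m_after_cut_g), 0.2)
  expect_lt(abs(ev$m_breaking_g - truth$m_breaking_g), 0.2)
})

test_that("recovered tensions match generator truth over a batch", {
  plateau_tol <- 0.2
  traces <- lapply(1:6, function(i) {
    g_nat <- c(0.6, 0.24)[(i %% 2) + 1]
    g_max <- c(2.4, 1.0)[(i %% 2) + 1]
    gen_scale_trace(g_nat, g_max, seed = 100 + i)
  })
  names(traces) <- sprintf("s%d", 1:6)
  res <- analyse_scale_traces(traces, jump_tol = 0.2)
  truth_nat <- vapply(traces, function(t) attr(t, "truth")$gamma_native, 0)
  truth_max <- vapply(traces, function(t) attr(t, "truth")$gamma_max, 0)
  tol <- plateau_tol * 1e-3 * G / 0.02   # plateau_tol * g / L
  expect_true(all(abs(res$gamma_native_N_per_m - truth_nat) < tol))
  expect_true(all(abs(res$gamma_max_N_per_m - truth_max) < tol))
  # the ramp only adds load: max >= native for every complete trace
  expect_true(all(res$gamma_max_N_per_m >= res$gamma_native_N_per_m))
})

test_that("detected tensions are invariant under a constant reading offset", {
  tr <- gen_scale_trace(0.6, 2.4, seed = 12)
  shifted <- scale_trace(tr$time_s, tr$reading_g + 3,
                         width_m = attr(tr, "width_m"))
  ev0 <- detect_events(tr, jump_tol = 0.3)
  ev1 <- detect_events(shifted, jump_tol = 0.3)
  expect_equal(native_tension(ev1), native_tension(ev0), tolerance = 1e-10)
  expect_equal(max_tension(ev1), max_tension(ev0), tolerance = 1e-10)
})

test_that("zero native tension leaves the cut invisible: plateaus equal", {
  tr <- gen_scale_trace(0, 2.0, noise_sd_g = 0.01, seed = 13)
  # with no load transferred at the cut, the pre-cut and after-cut segments
  # sit at the same weight (cut at 10 s, ramp from 21 s in the generator)
  pre <- mean(tr$reading_g[tr$time_s < 9])
  post <- mean(tr$reading_g[tr$time_s > 12 & tr$time_s < 20])
  expect_lt(abs(pre - post), 0.01)
  expect_equal(attr(tr, "truth")$m_after_cut_g, attr(tr, "truth")$m_detached_g)
})

test_that("incomplete and malformed traces signal their failure modes", {
  # no rupture: native computable, max undefined, warning raised
  tr <- gen_scale_trace(0.6, gamma_max = NULL, seed = 14)
  expect_warning(ev <- detect_events(tr, jump_tol = 0.3),
                 class = "vitmech_incomplete_trace")
  expect_equal(ev$qc, "incomplete")
  expect_true(is.na(ev$m_breaking_g))
  expect_true(is.na(max_tension(ev)))
  expect_gt(native_tension(ev), 0)

  # flat constant trace: no events at all
  flat <- scale_trace(seq(0, 30, by = 0.1), rep(10, 301))
  expect_error(detect_events(flat), class = "vitmech_incomplete_trace")

  # cut straight into a ramp with no stable after-cut plateau
  t <- seq(0, 40, by = 0.1)
  r <- c(rep(10, 100), seq(10, 8.5, length.out = 10),
         seq(8.5, 6, length.out = 141), rep(10, 150))
  expect_error(detect_events(scale_trace(t, r), jump_tol = 0.3),
               class = "vitmech_qc_failure")
})

test_that("scale traces round-trip through CSV", {
  tr <- gen_scale_trace(0.6, 2.4, seed = 15)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tr), tmp, row.names = FALSE)
  back <- read_scale_trace(tmp)
  expect_equal(back$reading_g, tr$reading_g, tolerance = 1e-12)
})
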