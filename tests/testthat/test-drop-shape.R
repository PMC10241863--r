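test_that("near-zero Bond number recovers a sphere tangent to the plate", {
  prof <- solve_drop_shape(drop_params(gamma_for_bo(0.01)))
  expect_lt(abs(prof$yolk_index - 1), 0.02)
  # H and D both equal the diameter of a sphere of the same volume
  d_sphere <- 2 * (3 * YOLK_V_ML * 1e3 / (4 * pi))^(1 / 3)  # mm
  expect_lt(abs(prof$height_mm / d_sphere - 1), 0.02)
  expect_lt(abs(prof$diameter_mm / d_sphere - 1), 0.02)
})

test_that("high-Bond pancake limit reaches height 2*sqrt(gamma/(rho g))", {
  gam <- 0.5
  rho <- 1035
  bo <- rho * G * (YOLK_V_ML * 1e-6)^(2 / 3) / gam
  # rescale volume so Bo = 1000 at gamma = 0.5, rho = 1035
  v_ml <- ((1000 * gam / (rho * G))^(3 / 2)) * 1e6
  prof <- solve_drop_shape(drop_params(gam, volume_ml = v_ml,
                                       density_g_cm3 = 1.035))
  expect_equal(prof$bond_number, 1000, tolerance = 1e-10)
  h_pancake <- 2 * sqrt(gam / (rho * G)) * 1000  # 14.04 mm
  expect_lt(abs(prof$height_mm / h_pancake - 1), 0.05)
})

test_that("solved profiles conserve volume and have a sane meridian", {
  for (bo in c(0.05, 1, 20, 300)) {
    prof <- solve_drop_shape(drop_params(gamma_for_bo(bo)), rtol = 1e-6)
    expect_lt(abs(prof$volume_ml / YOLK_V_ML - 1), 1e-6)
    z <- prof$meridian$z_mm
    expect_true(all(diff(z) < 0))              # strictly descending
    expect_equal(z[1], prof$height_mm)
    expect_equal(z[length(z)], 0, tolerance = 1e-8)
    expect_gte(prof$diameter_mm, 2 * prof$base_radius_mm)
    expect_gt(prof$yolk_index, 0)
    expect_lte(prof$yolk_index, 1)
  }
})

test_that("yolk index is strictly increasing in tension", {
  gammas <- exp(seq(log(0.02), log(5), length.out = 10))
  yi <- vapply(gammas, function(g) {
    solve_drop_shape(drop_params(g))$yolk_index
  }, numeric(1))
  expect_true(all(diff(yi) > 0))
})

test_that("solution is invariant under the dimensional rescaling group", {
  # lengths x k, volume x k^3, gamma x k^2 leave Bo unchanged
  k <- 2.7
  base <- solve_drop_shape(drop_params(0.3))
  scaled <- solve_drop_shape(drop_params(0.3 * k^2,
                                         volume_ml = YOLK_V_ML * k^3))
  expect_equal(scaled$bond_number, base$bond_number, tolerance = 1e-12)
  expect_equal(scaled$yolk_index, base$yolk_index, tolerance = 1e-8)
  expect_equal(scaled$height_mm, base$height_mm * k, tolerance = 1e-6)
  expect_equal(scaled$diameter_mm, base$diameter_mm * k, tolerance = 1e-6)
})

test_that("yolk_index computes H/D and flags degenerate profiles", {
  prof <- solve_drop_shape(drop_params(0.3))
  expect_equal(yolk_index(prof), prof$height_mm / prof$diameter_mm)
  broken <- prof
  broken$diameter_mm <- 0
  expect_error(yolk_index(broken), class = "vitmech_degenerate_profile")
})

test_that("tension inversion round-trips the forward model within 0.1%", {
  truth <- 0.3
  prof <- solve_drop_shape(drop_params(truth))
  est <- invert_tension(prof$yolk_index)
  expect_lt(abs(est / truth - 1), 1e-3)
  # and from (H, D) in mm
  est2 <- invert_tension(c(prof$height_mm, prof$diameter_mm))
  expect_lt(abs(est2 / truth - 1), 1e-3)
})

test_that("a near-spherical observation exceeds any finite bracket", {
  expect_error(invert_tension(0.999), class = "vitmech_bracket_error")
})

test_that("inverted tension for the flattened/round puddle pair sits in the expected band", {
  g_flat <- invert_tension(0.25)
  g_round <- invert_tension(0.45)
  expect_gte(g_flat, 0.1)
  expect_lte(g_round, 1)
  expect_gt(g_round, g_flat)
})

test_that("tension_ratio follows the pancake-limit scaling gamma ~ H^2", {
  # deep-pancake pair at matched volume: H_B/H_A = 0.63 => ratio ~ 0.63^2.
  # build observations from forward solves at pancake Bond numbers
  gam_a <- gamma_for_bo(600)
  gam_b <- gam_a * 0.63^2
  prof_a <- solve_drop_shape(drop_params(gam_a))
  prof_b <- solve_drop_shape(drop_params(gam_b))
  expect_equal(prof_b$height_mm / prof_a$height_mm, 0.63, tolerance = 0.02)
  ratio <- tension_ratio(prof_a$yolk_index, prof_b$yolk_index)
  expect_equal(ratio, 0.63^2, tolerance = 0.02)
})

test_that("identical observations give a tension ratio of 1", {
  expect_equal(tension_ratio(0.3, 0.3), 1, tolerance = 1e-6)
})

test_that("parameter validation and Bond-number domain are enforced", {
  expect_error(drop_params(-1), class = "vitmech_domain_error")
  expect_error(drop_params(0.3, volume_ml = 0), class = "vitmech_domain_error")
  expect_error(solve_drop_shape(drop_params(gamma_for_bo(1e5))),
               class = "vitmech_domain_error")
  expect_error(solve_drop_shape(drop_params(0.3), rtol = 0.5),
               class = "vitmech_domain_error")
  expect_error(invert_tension(1.2), class = "vitmech_domain_error")
})

test_that("puddle tables read with defaults filled and invert per row", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  prof <- solve_drop_shape(drop_params(0.4))
  writeLines(c("sample_id,day,height_mm,diameter_mm",
               sprintf("s1,D0,%.4f,%.4f", prof$height_mm, prof$diameter_mm)),
             tmp)
  tab <- read_puddle_table(tmp)
  expect_equal(tab$volume_ml, 17)
  expect_equal(tab$density_g_per_cm3, 1.035)
  out <- invert_tension_table(tab)
  expect_lt(abs(out$gamma_N_per_m / 0.4 - 1), 1e-3)
})
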