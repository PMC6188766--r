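test_that("depth curves have the required shapes", {
  p <- kernel_params()
  expect_equal(depth_curve("thermal", 0, p), 0)
  expect_equal(depth_curve("boron", 0, p), 0)
  d <- seq(0, 12, by = 0.5)
  fast <- depth_curve("fast", d, p)
  expect_true(all(diff(fast) < 0))
  for (ch in c("thermal", "fast", "photon", "boron"))
    expect_lt(depth_curve(ch, 60, p), 1e-3 * max(depth_curve(ch, d, p)))
  expect_error(depth_curve("thermal", -1, p), ">= 0")
})

test_that("thermal peak depth matches the closed-form argmax", {
  p <- kernel_params(thermal_lambda1 = 4.2, thermal_lambda2 = 1.1)
  l1 <- 4.2; l2 <- 1.1
  closed <- l1 * l2 / (l1 - l2) * log(l1 / l2)
  grid <- seq(0, 10, by = 0.01)
  grid_max <- grid[which.max(depth_curve("thermal", grid, p))]
  expect_equal(grid_max, closed, tolerance = 0.011)
})

test_that("off-axis profile is normalized, monotone, and flattens with depth", {
  b <- beam_config(); p <- kernel_params()
  expect_equal(off_axis_profile(0, 3, 0, b, p), 1)
  for (d in c(0, 2.5, 6.5)) for (g in c(0, 2)) {
    prof <- off_axis_profile(seq(0, 12, by = 0.25), d, g, b, p)
    expect_true(all(diff(prof) <= 1e-12))
    expect_true(all(prof >= 0 & prof <= 1))
  }
  flat <- function(d) off_axis_profile(1.5, d, 0, b, p) /
    off_axis_profile(0, d, 0, b, p)
  # central 3 cm of the profile is flatter at the greater tumor depth
  expect_gt(flat(6.5), flat(2.5))
  # a more forward-peaked beam keeps a sharper penumbra at depth
  b_fwd <- beam_config(current_to_flux_ratio = 0.95)
  b_dif <- beam_config(current_to_flux_ratio = 0.5)
  expect_gte(off_axis_profile(6, 5, 0, b_fwd, p),
             off_axis_profile(6, 5, 0, b_dif, p))
})

test_that("air-gap attenuation is 1 at contact and strictly decreasing", {
  p <- kernel_params()
  expect_equal(air_gap_attenuation(0, params = p), 1)
  vals <- air_gap_attenuation(0:3, params = p)
  expect_true(all(diff(vals) < 0))
  expect_error(air_gap_attenuation(-0.1, params = p), ">= 0")
})

test_that("dose components match an independent ray-march oracle", {
  ph <- tiny_slab_phantom()
  b <- beam_config(reactor_power = 1.5)
  p <- kernel_params()
  comp <- compute_dose_components(ph, b, p)
  oracle <- oracle_dose_components(ph, b, p)
  for (ch in c("thermal", "fast", "photon", "boron")) {
    scale <- max(oracle[[ch]])
    expect_lt(max(abs(comp[[ch]] - oracle[[ch]])) / scale, 1e-9)
  }
  # air voxels receive nothing
  expect_true(all(comp$thermal[ph$material_grid == 0L] == 0))
})

test_that("dose components are linear in the channel amplitude", {
  ph <- tiny_slab_phantom()
  b <- beam_config()
  p1 <- kernel_params()
  p2 <- kernel_params(thermal_amp = 2 * p1$thermal_amp)
  c1 <- compute_dose_components(ph, b, p1)
  c2 <- compute_dose_components(ph, b, p2)
  expect_equal(c2$thermal, 2 * c1$thermal, tolerance = 1e-12)
  expect_equal(c2$fast, c1$fast, tolerance = 1e-12)
})

test_that("an all-air phantom yields zero dose with a warning", {
  mt <- data.frame(label = 0L, name = "air", density = 0.0012)
  ph <- voxel_phantom(array(0L, c(4, 4, 4)), c(1, 1, 1), c(0, 0, 0), mt)
  expect_warning(comp <- compute_dose_components(ph), "misses")
  expect_true(all(comp$thermal == 0))
})

test_that("advantage depth is calibrated to 8.5 cm and behaves with T/N", {
  w <- weighting_config()
  p <- calibrate_engine(beam_config(), w)
  ad <- advantage_depth(p, w)
  expect_equal(ad, 8.5, tolerance = 0.2)
  # AD grows with the tumor/normal boron concentration ratio
  expect_lt(advantage_depth(p, w, tn_ratio = 2), ad)
  # equal weighting on both curves collapses AD to the normal-curve argmax
  we <- weighting_config(cbe_tumor = 1.3, cbe_normal = 1.3, tn_ratio = 1)
  cur_max <- stats::optimize(function(d)
    0.64 * 3.2 * depth_curve("thermal", d, p) +
    1.39 * 3.2 * depth_curve("fast", d, p) +
    0.96 * 0.5 * depth_curve("photon", d, p) +
    0.65 * 1.3 * 25 * depth_curve("boron", d, p),
    c(0, 20), maximum = TRUE)$maximum
  expect_equal(advantage_depth(p, we, tn_ratio = 1), cur_max,
               tolerance = 1e-3)
})

test_that("calibration is deterministic and round-trips through its report", {
  w <- weighting_config()
  p1 <- calibrate_engine(beam_config(), w)
  p2 <- calibrate_engine(beam_config(), w)
  expect_identical(p1[setdiff(names(p1), "calibration")],
                   p2[setdiff(names(p2), "calibration")])
  path <- withr::local_tempfile(fileext = ".yaml")
  write_calibration_report(p1, path)
  back <- read_calibration_report(path)
  expect_equal(back$thermal_lambda1, p1$thermal_lambda1, tolerance = 1e-9)
  expect_equal(back$gap_z0, p1$gap_z0, tolerance = 1e-9)
})

test_that("infeasible calibration targets fail loudly", {
  expect_error(calibrate_engine(targets = list(ad = 50)), "calibration")
})
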