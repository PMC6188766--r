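test_that("cylinder voxel membership matches a brute-force inequality check", {
  res <- small_cylinder(spacing = 1)
  ph <- res$phantom
  dims <- dim(ph$material_grid)
  # independent loop over all voxel centers
  n_inside <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      x <- ph$origin[1] + (i - 0.5) * ph$spacing[1]
      y <- ph$origin[2] + (j - 0.5) * ph$spacing[2]
      z <- ph$origin[3] + (k - 0.5) * ph$spacing[3]
      if (x^2 + z^2 <= 8^2 && y >= 0 && y <= 25) n_inside <- n_inside + 1L
    }
  expect_identical(sum(ph$material_grid == 1L), n_inside)
})

test_that("cylinder tumor sits at the requested depth, centered on the axis", {
  res <- small_cylinder(spacing = 0.5, depth = 2.5)
  tum <- res$rois$tumor
  ph <- res$phantom
  cy <- ph$origin[2] + (slice.index(tum, 2)[tum] - 0.5) * ph$spacing[2]
  cx <- ph$origin[1] + (slice.index(tum, 1)[tum] - 0.5) * ph$spacing[1]
  # axial (beam-direction) extent is depth +/- tumor radius
  expect_equal(mean(range(cy)), 2.5, tolerance = 0.5)
  expect_lte(max(cy), 2.5 + 1.5)
  expect_gte(min(cy), 2.5 - 1.5)
  expect_equal(mean(cx), 0, tolerance = 1e-9)
  # tumor and surrounding tissue are disjoint, tumor nonempty
  expect_gt(sum(tum), 0)
  expect_false(any(tum & res$rois$normal_tissue))
})

test_that("degenerate cylinder inputs are rejected", {
  expect_error(build_cylinder_phantom(diameter = 0), "positive")
  expect_error(build_cylinder_phantom(tumor = tumor_spec(3, 5, 24.5)),
               "outside")
  expect_error(tumor_spec(diameter = -1), "positive")
})

test_that("head phantom places anterior structures beyond the tumor", {
  res <- build_head_phantom(tumor = tumor_spec(3, 5, 6.5), spacing = 0.5)
  ph <- res$phantom; rois <- res$rois
  expect_setequal(names(rois),
                  c("tumor", "normal_brain", "brainstem",
                    "circle_of_willis", "eye_L", "eye_R", "lens_L",
                    "lens_R", "optic_nerve_L", "optic_nerve_R"))
  for (nm in names(rois)) expect_gt(sum(rois[[nm]]), 0)
  ydep <- function(mask)
    ph$origin[2] + (slice.index(mask, 2)[mask] - 0.5) * ph$spacing[2]
  # tumor axis depth from the posterior scalp (y = 0) is 6.5 cm
  expect_equal(mean(range(ydep(rois$tumor))), 6.5, tolerance = 0.5)
  # lenses and eyes are farther from the entry surface than the tumor
  expect_gt(min(ydep(rois$lens_L)), max(ydep(rois$tumor)))
  expect_gt(min(ydep(rois$eye_R)), max(ydep(rois$tumor)))
  expect_false(any(rois$tumor & rois$normal_brain))
})

test_that("infeasible head geometries are rejected", {
  expect_error(build_head_phantom(tumor = tumor_spec(3, 5, 30)),
               "exceeds the head extent")
  expect_error(build_head_phantom(tumor = tumor_spec(3, 5, 17)),
               "fit inside the brain")
  g <- default_roi_geometry()
  g$lens_offset <- 1.4   # lens would poke out of the eye
  expect_error(build_head_phantom(roi_geometry = g), "lens")
})

test_that("sphere mask matches a brute-force voxel-center test", {
  res <- build_head_phantom(spacing = 1)
  ph <- res$phantom
  cw <- res$rois$circle_of_willis
  dims <- dim(cw)
  g <- default_roi_geometry()
  for (idx in which(cw)) {
    k <- (idx - 1) %/% (dims[1] * dims[2])
    rem <- (idx - 1) %% (dims[1] * dims[2])
    j <- rem %/% dims[1]; i <- rem %% dims[1]
    x <- ph$origin[1] + (i + 0.5) * ph$spacing[1]
    y <- ph$origin[2] + (j + 0.5) * ph$spacing[2]
    z <- ph$origin[3] + (k + 0.5) * ph$spacing[3]
    expect_lte((x - g$circle_of_willis$center[1])^2 +
               (y - g$circle_of_willis$center[2])^2 +
               (z - g$circle_of_willis$center[3])^2,
               g$circle_of_willis$radius^2 + 1e-12)
  }
})
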