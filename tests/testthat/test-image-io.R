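test_that("image-stack round trip is the identity on labels and masks", {
  res <- build_cylinder_phantom(diameter = 6, length = 8, spacing = 1,
                                tumor = tumor_spec(2, 3, 3), margin = 2)
  dir <- withr::local_tempdir()
  write_image_stack(res$phantom, res$rois, dir)
  back <- read_image_stack(dir)
  expect_identical(back$phantom$material_grid, res$phantom$material_grid)
  expect_identical(back$phantom$spacing, res$phantom$spacing)
  for (nm in names(res$rois))
    expect_identical(back$rois[[nm]], res$rois[[nm]])
})

test_that("manifest records the axial extent of a 125-slice 2 mm stack", {
  mt <- data.frame(label = 0:1, name = c("air", "tissue"),
                   density = c(0.0012, 1.0))
  mat <- array(rep(0:1, length.out = 6 * 6 * 125), c(6, 6, 125))
  ph <- voxel_phantom(mat, c(1, 1, 0.2), c(0, 0, 0), mt)
  dir <- withr::local_tempdir()
  write_image_stack(ph, NULL, dir)
  man <- readLines(file.path(dir, "manifest.txt"))
  expect_true("n_slices=125" %in% man)
  expect_true("axial_extent_cm=25" %in% man)
  back <- read_image_stack(dir)
  expect_identical(back$phantom$material_grid, mat)
})

test_that("corrupt stacks are rejected with the slice named", {
  res <- build_cylinder_phantom(diameter = 4, length = 5, spacing = 1,
                                tumor = tumor_spec(1, 2, 2), margin = 1)
  dir <- withr::local_tempdir()
  write_image_stack(res$phantom, NULL, dir)
  # wrong-size slice
  tiff::writeTIFF(matrix(0, 2, 2), file.path(dir, "slice_002.tif"),
                  bits.per.sample = 8L)
  expect_error(read_image_stack(dir), "slice_002")
  # unknown gray value
  write_image_stack(res$phantom, NULL, dir)
  dims <- dim(res$phantom$material_grid)
  tiff::writeTIFF(matrix(77 / 255, dims[2], dims[1]),
                  file.path(dir, "slice_003.tif"), bits.per.sample = 8L)
  expect_error(read_image_stack(dir), "slice_003")
  # missing manifest
  unlink(file.path(dir, "manifest.txt"))
  expect_error(read_image_stack(dir), "manifest")
})

test_that("voxelizing to the source dimensions is the identity on labels", {
  res <- build_cylinder_phantom(diameter = 6, length = 6, spacing = 1,
                                tumor = tumor_spec(2, 3, 3), margin = 2)
  out <- voxelize_to_planning_grid(res$phantom, res$rois,
                                   dims = dim(res$phantom$material_grid))
  expect_identical(out$phantom$material_grid, res$phantom$material_grid)
  expect_identical(out$rois$tumor, res$rois$tumor)
})

test_that("planning-grid conversion preserves extent and material count", {
  res <- small_cylinder(spacing = 0.5)
  out <- voxelize_to_planning_grid(res$phantom, res$rois,
                                   dims = c(21, 21, 25), n_materials = 56)
  src_extent <- dim(res$phantom$material_grid) * res$phantom$spacing
  new_extent <- dim(out$phantom$material_grid) * out$phantom$spacing
  expect_equal(new_extent, src_extent, tolerance = 1e-12)
  # a uniform PMMA cylinder in air can only yield PMMA-grade and air-grade
  # blocks plus surface mixtures; labels stay within n_materials and both
  # pure materials survive
  expect_lte(nrow(out$phantom$material_table), 56)
  expect_true(any(out$phantom$material_table$density > 1.1))
  expect_true(any(out$phantom$material_table$density < 0.1))
  # tumor volume conserved within one coarse voxel
  vt_fine <- sum(res$rois$tumor) * prod(res$phantom$spacing)
  vt_coarse <- sum(out$rois$tumor) * prod(out$phantom$spacing)
  expect_lt(abs(vt_coarse - pi * 1.5^2 * 5),
            prod(out$phantom$spacing) + abs(vt_fine - pi * 1.5^2 * 5))
  expect_false(any(out$rois$tumor & out$rois$normal_tissue))
})

test_that("a two-density phantom quantizes to exactly two materials", {
  res <- build_cylinder_phantom(diameter = 8, length = 8, spacing = 1,
                                tumor = tumor_spec(2, 3, 4), margin = 0.5)
  # dims chosen to divide the source grid exactly: no mixed surface blocks
  # along y; with all-air and all-PMMA blocks only two materials remain
  dims <- dim(res$phantom$material_grid)
  out <- voxelize_to_planning_grid(res$phantom, NULL, dims = dims,
                                   n_materials = 56)
  expect_identical(sort(unique(as.vector(out$phantom$material_grid))),
                   c(0L, 1L))
  expect_error(voxelize_to_planning_grid(res$phantom, NULL, dims = c(0, 5, 5)),
               "positive")
  expect_error(voxelize_to_planning_grid(res$phantom, NULL,
                                         dims = dims + 1L), "exceed")
})
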