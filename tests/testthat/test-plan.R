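uniform_grid <- function(u, dims = c(4, 4, 4)) {
  gyeq_grid(array(u, dims), "accumulated")
}

test_that("a uniform dose gives a step-function DVH and D_q = u", {
  g <- uniform_grid(12)
  mask <- array(TRUE, dim(g$values))
  dv <- dvh(g, mask)
  expect_equal(dv$volume_pct[1], 100)
  expect_true(all(dv$volume_pct == 100))   # all edges are <= max = u
  for (q in c(5, 50, 80, 100))
    expect_equal(d_percent(dv, q), 12, tolerance = 1e-12)
  m <- roi_metrics(g, roi_set(list(tumor = mask)))
  expect_equal(m$d_mean, m$d_max)
  expect_equal(m$d_mean, m$d_q)
})

test_that("the DVH starts at 100 % and is non-increasing", {
  set.seed(11)
  g <- gyeq_grid(array(rexp(1000), c(10, 10, 10)), "accumulated")
  mask <- array(runif(1000) < 0.6, c(10, 10, 10))
  dv <- dvh(g, mask)
  expect_equal(dv$volume_pct[1], 100)
  expect_true(all(diff(dv$volume_pct) <= 0))
  expect_error(dvh(g, array(FALSE, c(10, 10, 10))), "empty mask")
})

test_that("D_q matches a sort-based quantile oracle within one bin width", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- array(runif(512, 0, 30), c(8, 8, 8))
    g <- gyeq_grid(vals, "accumulated")
    mask <- array(TRUE, dim(vals))
    dv <- dvh(g, mask)
    bin <- diff(dv$edges[1:2])
    for (q in c(20, 50, 80, 95))
      expect_lt(abs(d_percent(dv, q) - oracle_d_percent(vals, q)), bin)
  }
})

test_that("D_mean integrated from the DVH matches the mask mean", {
  set.seed(3)
  vals <- array(rgamma(729, 2, 0.5), c(9, 9, 9))
  g <- gyeq_grid(vals, "accumulated")
  mask <- array(TRUE, dim(vals))
  dv <- dvh(g, mask)
  bin <- diff(dv$edges[1:2])
  dvh_mean <- sum(dv$volume_pct / 100) * bin  # right-endpoint integral
  expect_lt(abs(dvh_mean - mean(vals)), bin)
})

test_that("prescription normalization makes tumor D_80 exactly 20 Gy-Eq", {
  res <- small_cylinder(spacing = 0.5)
  rate <- weight_components(compute_dose_components(res$phantom),
                            weighting_config(), res$rois)
  bt <- normalize_to_prescription(rate, res$rois$tumor)
  dose <- accumulate(rate, bt)
  d80 <- d_percent(dvh(dose, res$rois$tumor), 80)
  expect_rel_equal(d80, 20, tol = 1e-9)
  # doubling the rate halves the beam-on time
  rate2 <- gyeq_grid(2 * rate$values, "rate", rate$spacing)
  expect_rel_equal(normalize_to_prescription(rate2, res$rois$tumor),
                   bt / 2, tol = 1e-9)
  # renormalizing the normalized plan is the identity
  bt2 <- normalize_to_prescription(gyeq_grid(dose$values, "rate",
                                             dose$spacing),
                                   res$rois$tumor)
  expect_rel_equal(bt2, 1, tol = 1e-9)
})

test_that("a beam that misses the tumor cannot be normalized", {
  g <- gyeq_grid(array(0, c(3, 3, 3)), "rate")
  mask <- array(TRUE, c(3, 3, 3))
  expect_error(normalize_to_prescription(g, mask), "misses the tumor")
})

test_that("ROI metrics match a brute-force per-voxel loop", {
  set.seed(9)
  vals <- array(runif(125, 0, 25), c(5, 5, 5))
  g <- gyeq_grid(vals, "accumulated")
  m1 <- array(runif(125) < 0.4, c(5, 5, 5)); m1[1] <- TRUE
  m2 <- array(FALSE, c(5, 5, 5))
  met <- roi_metrics(g, roi_set(list(a = m1, b = m2)))
  sel <- numeric(0)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    if (m1[i, j, k]) sel <- c(sel, vals[i, j, k])
  row_a <- met[met$roi == "a", ]
  expect_equal(row_a$d_mean, mean(sel))
  expect_equal(row_a$d_max, max(sel))
  expect_gte(row_a$d_max, row_a$d_mean)
  bin <- row_a$d_max / 512
  expect_lt(abs(row_a$d_q - oracle_d_percent(sel, 80)), bin)
  # empty ROI reports absent metrics, not zeros
  expect_true(is.na(met$d_mean[met$roi == "b"]))
  expect_identical(met$n_voxels[met$roi == "b"], 0L)
})
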