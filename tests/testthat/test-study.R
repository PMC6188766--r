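test_that("percent changes reproduce the benchmark arithmetic", {
  expect_equal(percent_change(24.45, 24.10), 1.43)
  expect_equal(percent_change(20.69, 18.75), 9.38)
  expect_equal(percent_change(20, 20), 0)
  expect_error(percent_change(0, 1), "> 0")
})

test_that("rounding for reported values is half-away-from-zero", {
  expect_equal(round_half_up(1.435), 1.44)
  expect_equal(round_half_up(-1.435), -1.44)
  expect_equal(round_half_up(2.004999), 2.00)
})

test_that("directional aggregation matches the direct formula", {
  vals <- c(23.95, 24.12, 23.80, 23.93)
  ag <- aggregate_directional(vals, 24.31)
  expect_equal(ag$mean, sum(vals) / 4)
  expect_equal(ag$sd, sqrt(sum((vals - mean(vals))^2) / 3))
  expect_identical(ag$n, 4L)
  # order invariance
  ag2 <- aggregate_directional(rev(vals), 24.31)
  expect_equal(ag, ag2)
  # degenerate cases
  expect_error(aggregate_directional(23.95, 24.31), "at least two")
  ag3 <- aggregate_directional(c(24.31, 24.31), 24.31)
  expect_equal(ag3$mean, 24.31)
  expect_equal(ag3$sd, 0)
  expect_false(ag3$p_defined)
})

test_that("the one-sample t-test matches a numeric integration oracle", {
  tt <- t_test_vs_baseline(c(1, 2, 3, 4), 0)
  expect_equal(tt$statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_identical(tt$df, 3L)
  # two-sided p by integrating the t density with df = 3
  dens <- function(x) (1 + x^2 / 3)^(-2) * gamma(2) /
    (sqrt(3 * pi) * gamma(1.5))
  p_oracle <- 2 * stats::integrate(dens, abs(tt$statistic), Inf)$value
  expect_equal(tt$p_value, p_oracle, tolerance = 1e-8)
  # mean equal to baseline gives p = 1
  expect_equal(t_test_vs_baseline(c(-1, 1), 0)$p_value, 1)
  # location invariance
  a <- t_test_vs_baseline(c(1, 2, 4), 1.5)
  b <- t_test_vs_baseline(c(1, 2, 4) + 10, 11.5)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # zero spread is flagged, not reported as p = 0
  z <- t_test_vs_baseline(c(2, 2), 1)
  expect_false(z$defined)
  expect_true(is.na(z$p_value))
})

small_config <- function() {
  cfg <- study_config(families = "cylinder", depths = 6.5)
  cfg$battery <- rbind(
    expand.grid(kind = c("left", "right", "superior", "inferior"),
                magnitude = 2, stringsAsFactors = FALSE),
    data.frame(kind = "outward", magnitude = 2),
    data.frame(kind = c("rotation", "rotation", "tilt", "tilt"),
               magnitude = c(5, -5, 5, -5))
  )
  cfg
}

test_that("a baseline-only battery reports the unperturbed plan", {
  cfg <- study_config(families = "cylinder", depths = 6.5)
  cfg$battery <- data.frame(kind = character(0), magnitude = numeric(0))
  rep <- run_study(cfg)
  tum <- rep$cases[rep$cases$roi == "tumor", ]
  expect_identical(nrow(tum), 1L)
  expect_identical(tum$kind, "none")
  expect_equal(tum$d_q, 20, tolerance = 1e-9)
})

test_that("the study pipeline is deterministic and internally consistent", {
  cfg <- small_config()
  r1 <- run_study(cfg)
  r2 <- run_study(cfg)
  expect_equal(r1$cases, r2$cases, tolerance = 0)
  expect_equal(r1$beam_times, r2$beam_times, tolerance = 0)
  # percent-change cells recompute from the same report's dose values
  pc <- r1$percent_change_table
  base <- r1$cases$d_mean[r1$cases$roi == "tumor" & r1$cases$kind == "none"]
  for (i in seq_len(nrow(pc)))
    expect_equal(pc$percent_change[i],
                 percent_change(base, pc$mean_dose[i]))
  # rotation/tilt rows aggregate the two senses against the D_mean baseline
  rt <- r1$rotation_table[r1$rotation_table$metric == "D_mean", ]
  expect_identical(unique(rt$baseline), base)
  expect_true(all(c("R5", "T5") %in% names(rt)))
})

test_that("report export round-trips and hashes follow the config", {
  cfg <- small_config()
  rep <- run_study(cfg)
  dir <- withr::local_tempdir()
  files <- export_report(rep, dir)
  expect_true(file.exists(file.path(dir, "table1.csv")))
  t4 <- utils::read.csv(file.path(dir, "table4.csv"))
  expect_equal(t4$percent_change, rep$percent_change_table$percent_change)
  expect_equal(t4$mean_dose, rep$percent_change_table$mean_dose,
               tolerance = 1e-12)
  man <- readLines(file.path(dir, "manifest.txt"))
  hash1 <- sub("config_hash=", "", man[startsWith(man, "config_hash")])
  # identical config -> identical hash; changed config -> changed hash
  dir2 <- withr::local_tempdir()
  export_report(rep, dir2)
  man2 <- readLines(file.path(dir2, "manifest.txt"))
  expect_identical(man[startsWith(man, "config_hash")],
                   man2[startsWith(man2, "config_hash")])
  rep2 <- rep
  rep2$config$seed <- 999L
  dir3 <- withr::local_tempdir()
  export_report(rep2, dir3)
  man3 <- readLines(file.path(dir3, "manifest.txt"))
  hash3 <- sub("config_hash=", "", man3[startsWith(man3, "config_hash")])
  expect_false(identical(hash1, hash3))
})
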