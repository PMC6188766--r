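#' Percent change of a dose metric relative to baseline
#'
#' `100 * (baseline - shifted) / baseline`, rounded half-away-from-zero to
#' `digits` decimals (the convention of the reference dose tables; positive
#' values are dose losses).
#'
#' @param baseline baseline metric, Gy-Eq (> 0), vectorized.
#' @param shifted perturbed-case metric, Gy-Eq.
#' @param digits decimals to report (default 2; NULL for full precision).
#' @return percent change(s).
#' @export
percent_change <- function(baseline, shifted, digits = 2) {
  if (any(baseline <= 0)) stop("baseline must be > 0")
  pc <- 100 * (baseline - shifted) / baseline
  if (is.null(digits)) pc else round_half_up(pc, digits)
}

#' Two-sided one-sample t-test of perturbed metrics against baseline
#'
#' The baseline is a single deterministic plan value, not a sample, so the
#' perturbed direction/sense values are tested one-sample:
#' `t = (mean(values) - baseline) / (sd(values) / sqrt(n))`, df = n - 1,
#' two-sided p from the t distribution. With zero sample SD the p-value is
#' undefined and flagged, never reported as 0.
#'
#' @param values numeric vector of perturbed-case metrics (n >= 2).
#' @param baseline baseline metric.
#' @return list with `statistic`, `df`, `p_value` (NA when undefined) and
#'   `defined` flag.
#' @export
t_test_vs_baseline <- function(values, baseline) {
  n <- length(values)
  if (n < 2L) stop("t-test needs at least two values")
  s <- stats::sd(values)
  if (s == 0)
    return(list(statistic = NA_real_, df = n - 1L, p_value = NA_real_,
                defined = FALSE))
  tstat <- (mean(values) - baseline) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1L,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1L), defined = TRUE)
}

#' Aggregate directional perturbations at one magnitude
#'
#' Mean and sample SD (n - 1 denominator) of a metric over the lateral
#' directions (left/right/superior/inferior, n = 4) or the two
#' rotation/tilt senses (n = 2), with the one-sample p-value against
#' baseline.
#'
#' @param values metric values across directions/senses (n >= 2).
#' @param baseline baseline metric.
#' @return one-row data frame: `n`, `mean`, `sd`, `p_value`, `p_defined`.
#' @export
aggregate_directional <- function(values, baseline) {
  if (length(values) < 2L)
    stop("directional aggregation needs at least two values ",
         "(p-value undefined otherwise)")
  tt <- t_test_vs_baseline(values, baseline)
  data.frame(n = length(values), mean = mean(values),
             sd = stats::sd(values), p_value = tt$p_value,
             p_defined = tt$defined)
}

#' The default positioning-error battery
#'
#' Lateral shifts (left, right, superior, inferior) and outward shifts of
#' 1, 2 and 3 cm; rotations and tilts of 5, 10 and 15 degrees, both senses.
#'
#' @param lateral_cm translation magnitudes, cm.
#' @param angles_deg rotation/tilt magnitudes, degrees.
#' @return data frame with columns `kind`, `magnitude`.
#' @export
default_battery <- function(lateral_cm = c(1, 2, 3),
                            angles_deg = c(5, 10, 15)) {
  rbind(
    expand.grid(kind = c("left", "right", "superior", "inferior"),
                magnitude = lateral_cm, stringsAsFactors = FALSE),
    data.frame(kind = "outward", magnitude = lateral_cm),
    expand.grid(kind = c("rotation", "tilt"),
                magnitude = c(angles_deg, -angles_deg),
                stringsAsFactors = FALSE)
  )
}

#' Default study configuration
#'
#' The full study: both phantom families (cylinder and head), tumors at
#' 6.5 and 2.5 cm depth, the default battery, the reference beam and
#' weighting constants, 20 Gy-Eq to 80 % of the tumor, planning grid
#' 21 x 21 x 25 with at most 56 materials, 0.4 cm working resolution.
#'
#' @param families phantom families to run.
#' @param depths tumor depths, cm.
#' @param fine_spacing working voxel size, cm.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return nested configuration list.
#' @export
study_config <- function(families = c("cylinder", "head"),
                         depths = c(6.5, 2.5),
                         fine_spacing = 0.5,
                         dose_grid = c("working", "planning"),
                         seed = 1L) {
  list(
    families = match.arg(families, several.ok = TRUE),
    depths = depths,
    fine_spacing = fine_spacing,
    dose_grid = match.arg(dose_grid),
    planning_dims = c(21L, 21L, 25L),
    n_materials = 56L,
    tumor = list(diameter = 3, length = 5),
    cylinder = list(diameter = 16, length = 25),
    head_axes = c(9.5, 12, 8),
    battery = default_battery(),
    beam = unclass(beam_config())[c("aperture_diameter", "reactor_power",
                                    "epithermal_flux_at_exit",
                                    "current_to_flux_ratio")],
    weighting = list(),
    prescription = list(dose = 20, coverage = 80),
    dvh_bins = 512L,
    seed = as.integer(seed)
  )
}

build_family <- function(config, family, depth) {
  tum <- tumor_spec(config$tumor$diameter, config$tumor$length, depth)
  if (family == "cylinder")
    build_cylinder_phantom(diameter = config$cylinder$diameter,
                           length = config$cylinder$length,
                           spacing = config$fine_spacing, tumor = tum)
  else
    build_head_phantom(head_axes = config$head_axes, tumor = tum,
                       spacing = config$fine_spacing)
}

case_label <- function(kind, magnitude) {
  if (kind == "none") "baseline"
  else if (kind %in% c("rotation", "tilt"))
    sprintf("%s_%+gdeg", kind, magnitude)
  else sprintf("%s_%gcm", kind, magnitude)
}

#' Run the positioning-sensitivity study
#'
#' For every (family, depth): build the working-resolution phantom,
#' normalize the unperturbed plan to the prescription (fixing the beam-on
#' time used by every sibling case), then run the battery — transform at
#' the working resolution, compute and weight dose, accumulate with the
#' baseline time, record ROI metrics and tumor DVHs. The analytic kernel
#' is evaluated at the working resolution by default; `dose_grid =
#' "planning"` instead runs the transport stand-in on the coarse planning
#' grid and samples it back onto the working ROI masks.
#' Directional cases are aggregated (lateral n = 4, angular senses n = 2)
#' with one-sample t-tests against baseline, and percent changes of the
#' mean tumor dose are tabulated per shift type and magnitude. The pipeline
#' is deterministic for a given configuration.
#'
#' @param config a [study_config()].
#' @param params calibrated [kernel_params()] (default: run
#'   [calibrate_engine()]).
#' @param progress print per-case progress (default FALSE).
#' @return an object of class `study_report`; see [export_report()].
#' @export
run_study <- function(config = study_config(), params = NULL,
                      progress = FALSE) {
  beam <- beam_config(
    aperture_diameter = config$beam$aperture_diameter,
    reactor_power = config$beam$reactor_power,
    epithermal_flux_at_exit = config$beam$epithermal_flux_at_exit,
    current_to_flux_ratio = config$beam$current_to_flux_ratio)
  weighting <- do.call(weighting_config, config$weighting)
  if (is.null(params)) params <- calibrate_engine(beam, weighting)
  presc <- prescription(config$prescription$dose,
                        config$prescription$coverage)
  battery <- config$battery

  cases <- list(); dvhs <- list(); beam_times <- list()
  for (family in config$families) for (depth in config$depths) {
    fine <- build_family(config, family, depth)
    # tilt pivots at the plan isocenter (tumor centroid)
    isocenter <- mask_centroid(fine$rois$tumor, fine$phantom$spacing,
                               fine$phantom$origin)
    run_case <- function(kind, magnitude) {
      tr <- transform_from_spec(shift_spec(kind, magnitude), beam, isocenter)
      moved <- if (kind == "none") fine
               else apply_transform(fine$phantom, fine$rois, tr)
      comp <- if (identical(config$dose_grid, "planning")) {
        # legacy mode: transport stand-in on the coarse planning grid, dose
        # sampled back onto the working grid (volume-weighted metrics)
        pg <- voxelize_to_planning_grid(moved$phantom, moved$rois,
                                        config$planning_dims,
                                        config$n_materials)
        upsample_dose_components(compute_dose_components(pg$phantom, beam,
                                                         params),
                                 dim(moved$phantom$material_grid),
                                 moved$phantom$spacing)
      } else {
        # the kernel is analytic, so it is evaluated at the working
        # resolution: coarse-grid surface rasterization would jump the
        # tissue depth by half a planning voxel and drown the 1-3 %
        # rotation/tilt effects under study
        compute_dose_components(moved$phantom, beam, params)
      }
      rate <- weight_components(comp, weighting, moved$rois)
      list(rate = rate, rois = moved$rois)
    }

    base <- run_case("none", 0)
    beam_time <- normalize_to_prescription(base$rate, base$rois$tumor,
                                           presc, config$dvh_bins)
    key <- paste(family, depth, sep = "_")
    beam_times[[key]] <- beam_time

    specs <- rbind(data.frame(kind = "none", magnitude = 0),
                   battery)
    for (i in seq_len(nrow(specs))) {
      kind <- specs$kind[i]; mag <- specs$magnitude[i]
      if (progress) message(sprintf("[%s d=%g] %s", family, depth,
                                    case_label(kind, mag)))
      cs <- if (kind == "none") base else run_case(kind, mag)
      dose <- accumulate(cs$rate, beam_time)
      met <- roi_metrics(dose, cs$rois, q = presc$coverage,
                         nbins = config$dvh_bins)
      met$family <- family; met$depth <- depth
      met$kind <- kind; met$magnitude <- mag
      met$case <- case_label(kind, mag)
      cases[[length(cases) + 1L]] <- met
      if (kind %in% c("none", "left", "outward")) {
        dv <- dvh(dose, cs$rois$tumor, config$dvh_bins)
        dvhs[[paste(key, case_label(kind, mag), sep = "_")]] <-
          data.frame(family = family, depth = depth,
                     case = case_label(kind, mag),
                     dose_gyeq = dv$edges, volume_pct = dv$volume_pct)
      }
    }
  }
  cases <- do.call(rbind, cases)
  report <- structure(list(
    cases = cases,
    beam_times = beam_times,
    tumor_tables = tumor_dose_tables(cases),
    rotation_table = rotation_tilt_table(cases),
    percent_change_table = percent_change_table(cases),
    normal_tissue_table = normal_tissue_table(cases),
    dvhs = do.call(rbind, dvhs),
    profiles = profile_table(beam, params),
    config = config,
    params = params[setdiff(names(params), "calibration")],
    calibration = params$calibration
  ), class = "study_report")
  report
}

# ---- report table builders -------------------------------------------------

tumor_metric <- function(cases, family, depth, kind, magnitude, col) {
  sel <- cases$roi == "tumor" & cases$family == family &
    cases$depth == depth & cases$kind == kind &
    cases$magnitude == magnitude
  cases[[col]][sel]
}

LATERAL_KINDS <- c("left", "right", "superior", "inferior")

tumor_dose_tables <- function(cases) {
  out <- list()
  for (family in unique(cases$family)) {
    rows <- list()
    for (depth in unique(cases$depth)) for (col in c("d_mean", "d_q")) {
      base <- tumor_metric(cases, family, depth, "none", 0, col)
      row <- data.frame(depth = depth,
                        metric = if (col == "d_mean") "D_mean" else "D_80pct",
                        baseline = base)
      for (m in sort(unique(cases$magnitude[cases$kind == "left"]))) {
        vals <- unlist(lapply(LATERAL_KINDS, function(k)
          tumor_metric(cases, family, depth, k, m, col)))
        ag <- aggregate_directional(vals, base)
        row[[sprintf("LS%g", m)]] <- ag$mean
        row[[sprintf("LS%g_sd", m)]] <- ag$sd
        row[[sprintf("LS%g_p", m)]] <- ag$p_value
      }
      for (m in sort(unique(cases$magnitude[cases$kind == "outward"]))) {
        row[[sprintf("OS%g", m)]] <-
          tumor_metric(cases, family, depth, "outward", m, col)
      }
      rows[[length(rows) + 1L]] <- row
    }
    out[[family]] <- do.call(rbind, rows)
  }
  out
}

rotation_tilt_table <- function(cases) {
  ang <- cases[cases$kind %in% c("rotation", "tilt") & cases$roi == "tumor", ]
  if (!nrow(ang)) return(NULL)
  rows <- list()
  for (family in unique(ang$family)) for (depth in unique(ang$depth))
    for (col in c("d_mean", "d_q")) {
      base <- tumor_metric(cases, family, depth, "none", 0, col)
      if (!length(base)) next
      row <- data.frame(family = family, depth = depth,
                        metric = if (col == "d_mean") "D_mean" else "D_80pct",
                        baseline = base)
      for (kind in c("rotation", "tilt")) {
        mags <- sort(unique(abs(ang$magnitude[ang$kind == kind])))
        for (m in mags) {
          vals <- c(tumor_metric(cases, family, depth, kind, m, col),
                    tumor_metric(cases, family, depth, kind, -m, col))
          if (length(vals) < 2L) next
          ag <- aggregate_directional(vals, base)
          pre <- sprintf("%s%g", if (kind == "rotation") "R" else "T", m)
          row[[pre]] <- ag$mean
          row[[paste0(pre, "_sd")]] <- ag$sd
          row[[paste0(pre, "_p")]] <- ag$p_value
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  do.call(rbind, rows)
}

percent_change_table <- function(cases) {
  rows <- list()
  for (family in unique(cases$family)) for (depth in unique(cases$depth)) {
    base <- tumor_metric(cases, family, depth, "none", 0, "d_mean")
    for (m in sort(unique(cases$magnitude[cases$kind == "left"]))) {
      vals <- unlist(lapply(LATERAL_KINDS, function(k)
        tumor_metric(cases, family, depth, k, m, "d_mean")))
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, depth = depth, shift = "lateral", magnitude = m,
        mean_dose = mean(vals),
        percent_change = percent_change(base, mean(vals)))
    }
    for (m in sort(unique(cases$magnitude[cases$kind == "outward"]))) {
      v <- tumor_metric(cases, family, depth, "outward", m, "d_mean")
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, depth = depth, shift = "outward", magnitude = m,
        mean_dose = v, percent_change = percent_change(base, v))
    }
  }
  do.call(rbind, rows)
}

NORMAL_ROI_LABELS <- c(normal_brain = "NB", circle_of_willis = "CW",
                       optic_nerve_L = "L-ON", optic_nerve_R = "R-ON",
                       lens_L = "L-lens", lens_R = "R-lens",
                       eye_L = "L-eye", eye_R = "R-eye", brainstem = "BS",
                       normal_tissue = "NT")

normal_tissue_table <- function(cases) {
  nt <- cases[cases$family == "head" & cases$roi %in%
                names(NORMAL_ROI_LABELS), ]
  if (!nrow(nt)) return(NULL)
  rows <- list()
  for (roi in intersect(names(NORMAL_ROI_LABELS), unique(nt$roi)))
    for (depth in unique(nt$depth)) {
      sub <- nt[nt$roi == roi & nt$depth == depth, ]
      base <- sub$d_mean[sub$kind == "none"]
      row <- data.frame(organ = NORMAL_ROI_LABELS[[roi]], depth = depth,
                        baseline_d_mean = base,
                        baseline_d_max = sub$d_max[sub$kind == "none"])
      for (m in sort(unique(sub$magnitude[sub$kind == "left"]))) {
        vals <- sub$d_mean[sub$kind %in% LATERAL_KINDS & sub$magnitude == m]
        row[[sprintf("LS%g", m)]] <- mean(vals)
        row[[sprintf("LS%g_sd", m)]] <- stats::sd(vals)
      }
      for (m in sort(unique(sub$magnitude[sub$kind == "outward"])))
        row[[sprintf("OS%g", m)]] <-
          sub$d_mean[sub$kind == "outward" & sub$magnitude == m]
      rows[[length(rows) + 1L]] <- row
    }
  do.call(rbind, rows)
}

profile_table <- function(beam, params, depths = c(2.5, 6.5),
                          radii = seq(0, 10, by = 0.25)) {
  do.call(rbind, lapply(depths, function(d)
    data.frame(depth = d, radius = radii,
               relative_dose = off_axis_profile(radii, d, 0, beam, params))))
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", length(unique(x$cases$case)), "cases x",
      length(x$beam_times), "(family, depth) plans\n")
  cat("beam-on times (min):\n")
  for (k in names(x$beam_times))
    cat(sprintf("  %-14s %.3f\n", k, x$beam_times[[k]]))
  cat("\nmean tumor dose percent changes:\n")
  print(x$percent_change_table, row.names = FALSE)
  invisible(x)
}
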