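#' Export a study report as CSV tables plus a run manifest
#'
#' Writes `table1.csv`/`table2.csv` (cylinder / head tumor dose tables),
#' `table3.csv` (rotation/tilt), `table4.csv` (percent changes),
#' `table5.csv` (normal-tissue doses), `cases.csv` (every case's raw ROI
#' metrics at full precision), `dvh.csv`, `profiles.csv`, the run
#' configuration (`config.yaml`) and a `manifest.txt` recording the config
#' hash, seed and calibration summary. Every percent-change cell is
#' recomputable from the dose tables in the same report.
#'
#' @param report a [run_study()] result.
#' @param directory output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
export_report <- function(report, directory) {
  if (!inherits(report, "study_report")) stop("not a study_report")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ok <- dir.exists(directory) && file.access(directory, 2L) == 0L
  if (!ok) stop("directory is not writable: ", directory)
  w <- function(df, name) {
    if (is.null(df)) return(NULL)
    path <- file.path(directory, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    w(report$tumor_tables$cylinder, "table1.csv"),
    w(report$tumor_tables$head, "table2.csv"),
    w(report$rotation_table, "table3.csv"),
    w(report$percent_change_table, "table4.csv"),
    w(report$normal_tissue_table, "table5.csv"),
    w(report$cases, "cases.csv"),
    w(report$dvhs, "dvh.csv"),
    w(report$profiles, "profiles.csv")
  )
  cfg_path <- file.path(directory, "config.yaml")
  yaml::write_yaml(report$config, cfg_path)
  cal <- report$calibration
  man <- c(
    sprintf("config_hash=%s", config_hash(report$config)),
    sprintf("seed=%d", report$config$seed),
    sprintf("advantage_depth_cm=%.6g",
            if (!is.null(cal)) cal$achieved$advantage_depth_cm else NA),
    sprintf("thermal_lambda1=%.10g", report$params$thermal_lambda1),
    sprintf("gap_z0=%.10g", report$params$gap_z0),
    sprintf("beam_time_min_%s=%.10g", names(report$beam_times),
            unlist(report$beam_times))
  )
  man_path <- file.path(directory, "manifest.txt")
  writeLines(man, man_path)
  invisible(c(files, cfg_path, man_path))
}

#' Benchmark mean tumor doses for the modeled THOR beam
#'
#' The published treatment-planning benchmark for this beam: baseline and
#' shifted mean tumor doses (D_mean, Gy-Eq) and 80 % coverage doses
#' (D_80%, Gy-Eq) for cylinder and head phantoms with tumors at 6.5 and
#' 2.5 cm depth, under 1-3 cm lateral (direction-averaged) and outward
#' shifts. Shipped as plain text under `extdata`; used to validate the
#' percent-change reporting, not produced by this package's dose engine.
#'
#' Two published percent-change cells are internally inconsistent with
#' these dose values (head 6.5 cm 2 cm lateral: printed 5.52 vs recomputed
#' 5.40; cylinder 6.5 cm 1 cm outward: printed 4.72 vs recomputed 8.72);
#' the `consistent` column flags them.
#'
#' @return data frame with columns `family`, `depth_cm`, `metric`,
#'   `shift`, `magnitude_cm`, `dose_gyeq`, `published_pct_change`,
#'   `consistent`.
#' @export
thor_benchmark_doses <- function() {
  path <- system.file("extdata", "thor_benchmark_doses.csv",
                      package = "bnctsens", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
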