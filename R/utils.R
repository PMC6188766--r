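#' Round half away from zero
#'
#' Table-style rounding: halves round away from zero (so 1.435 -> 1.44),
#' unlike [base::round()]'s round-half-even. Used wherever doses or percent
#' changes are reported at fixed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values printed at this precision
  # (e.g. 11.315 stored as 11.31499999...) land on the intended side
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Read a structured text configuration file
#'
#' Configuration files are YAML; JSON is valid YAML so either dialect works.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write a configuration list as YAML
#'
#' @param config named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# md5 of an R object via its canonical YAML rendering; used for run manifests
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a positive finite scalar")
  invisible(x)
}
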