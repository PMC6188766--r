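#' Biological weighting configuration
#'
#' Constants converting physical dose (Gy) to photon-equivalent dose
#' (Gy-Eq) for the four-component epithermal-beam field. Dose-rate scaling
#' factors (DRSF) align each computed component with measured depth-dose
#' curves: 0.64 (thermal neutron), 1.39 (fast neutron), 0.96 (photon), 0.65
#' (boron). High-LET components (nitrogen-capture products of thermal
#' neutrons, fast neutrons) carry RBE 3.2; photons 0.5. The boron channel
#' uses compound (BPA) factors CBE 3.8 in tumor and 1.3 in normal tissue,
#' with a tumor/normal 10-B concentration ratio of 3.5. The absolute normal
#' tissue concentration (default 25 ppm) only sets the overall dose scale,
#' which the prescription normalization removes.
#'
#' @param drsf named numeric, dose-rate scaling factor per channel.
#' @param rbe_high_let RBE of the thermal (nitrogen-capture) and fast
#'   channels (default 3.2).
#' @param rbe_photon photon RBE (default 0.5, as adopted for this beam;
#'   override to 1 for the photon-reference convention).
#' @param cbe_tumor,cbe_normal compound biological effectiveness of the
#'   boron channel in tumor / normal tissue (defaults 3.8 / 1.3).
#' @param tn_ratio tumor-to-normal boron concentration ratio (default 3.5).
#' @param boron_normal_ppm 10-B concentration in normal tissue, ppm
#'   (default 25).
#' @return an object of class `weighting_config`.
#' @export
weighting_config <- function(drsf = c(thermal = 0.64, fast = 1.39,
                                      photon = 0.96, boron = 0.65),
                             rbe_high_let = 3.2,
                             rbe_photon = 0.5,
                             cbe_tumor = 3.8,
                             cbe_normal = 1.3,
                             tn_ratio = 3.5,
                             boron_normal_ppm = 25) {
  if (!all(BEAM_CHANNELS %in% names(drsf)))
    stop("drsf must name all four channels: ",
         paste(BEAM_CHANNELS, collapse = ", "))
  vals <- c(drsf, rbe_high_let, rbe_photon, cbe_tumor, cbe_normal)
  if (any(vals <= 0)) stop("all weighting factors must be > 0")
  if (boron_normal_ppm < 0) stop("boron_normal_ppm must be >= 0")
  if (tn_ratio < 1) stop("tn_ratio must be >= 1")
  structure(list(drsf = drsf, rbe_high_let = rbe_high_let,
                 rbe_photon = rbe_photon, cbe_tumor = cbe_tumor,
                 cbe_normal = cbe_normal, tn_ratio = tn_ratio,
                 boron_normal_ppm = boron_normal_ppm),
            class = "weighting_config")
}

#' Gray-equivalent dose grid
#'
#' @param values 3-D numeric array (Gy-Eq/min for rates, Gy-Eq for
#'   accumulated dose).
#' @param kind `"rate"` or `"accumulated"`.
#' @param spacing voxel spacing of the aligned phantom, cm.
#' @return an object of class `gyeq_grid`.
#' @export
gyeq_grid <- function(values, kind = c("rate", "accumulated"),
                      spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(values < 0)) stop("Gy-Eq values must be >= 0")
  structure(list(values = values, kind = kind, spacing = as.numeric(spacing)),
            class = "gyeq_grid")
}

#' @export
print.gyeq_grid <- function(x, ...) {
  cat("gyeq_grid (", x$kind, "): ",
      paste(dim(x$values), collapse = " x "), " voxels, max ",
      signif(max(x$values), 4),
      if (x$kind == "rate") " Gy-Eq/min\n" else " Gy-Eq\n", sep = "")
  invisible(x)
}

#' Combine physical dose components into a Gray-equivalent rate grid
#'
#' Per voxel:
#' `GyEq = drsf_th * RBE_hi * D_th + drsf_f * RBE_hi * D_f +
#'  drsf_ph * RBE_ph * D_ph + drsf_B * CBE(v) * C(v) * D_B_per_ppm`,
#' where inside the tumor mask `C = tn_ratio * boron_normal_ppm` and
#' `CBE = cbe_tumor`, elsewhere (including voxels outside every mask,
#' treated as normal tissue) `C = boron_normal_ppm`, `CBE = cbe_normal`.
#'
#' @param components a [compute_dose_components()] result.
#' @param weighting a [weighting_config()].
#' @param rois a [roi_set()] with a `tumor` mask (NULL: all normal tissue).
#' @return a rate-flagged [gyeq_grid()].
#' @export
weight_components <- function(components, weighting = weighting_config(),
                              rois = NULL) {
  dims <- components$dims
  tumor <- if (!is.null(rois) && !is.null(rois$tumor)) rois$tumor
           else array(FALSE, dims)
  if (length(dim(tumor)) != 3L || any(dim(tumor) != dims))
    stop("tumor mask dimensions do not match the dose grids")
  w <- weighting
  cbe <- array(w$cbe_normal, dims); cbe[tumor] <- w$cbe_tumor
  conc <- array(w$boron_normal_ppm, dims)
  conc[tumor] <- w$tn_ratio * w$boron_normal_ppm
  vals <- w$drsf[["thermal"]] * w$rbe_high_let * components$thermal +
          w$drsf[["fast"]] * w$rbe_high_let * components$fast +
          w$drsf[["photon"]] * w$rbe_photon * components$photon +
          w$drsf[["boron"]] * cbe * conc * components$boron
  gyeq_grid(vals, "rate", components$spacing)
}

#' Export a Gray-equivalent grid as a flat CSV for inspection
#'
#' One row per voxel: world coordinates of the voxel center (cm, using the
#' grid spacing and an origin of 0) and the Gy-Eq value.
#'
#' @param grid a [gyeq_grid()].
#' @param path output CSV path.
#' @param origin world coordinate of the grid corner, cm.
#' @return `path`, invisibly.
#' @export
write_gyeq_csv <- function(grid, path, origin = c(0, 0, 0)) {
  if (!inherits(grid, "gyeq_grid")) stop("grid must be a gyeq_grid")
  dims <- dim(grid$values)
  cc <- lapply(1:3, function(a)
    origin[a] + (seq_len(dims[a]) - 0.5) * grid$spacing[a])
  df <- data.frame(
    x = cc[[1]][slice.index(grid$values, 1)],
    y = cc[[2]][slice.index(grid$values, 2)],
    z = cc[[3]][slice.index(grid$values, 3)],
    value = as.vector(grid$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Upsample planning-grid dose components to a finer aligned grid
#'
#' Block-replicates the piecewise-constant planning-grid dose onto the
#' working grid it was downsampled from (each fine voxel takes its coarse
#' voxel's value). Evaluating ROI metrics on the fine masks over this
#' upsampled dose is equivalent to fractional-volume weighting of the
#' coarse dose, which removes mask re-rasterization jumps from the metrics
#' while the transport stand-in still runs on the coarse material grid.
#'
#' @param components a [compute_dose_components()] result on the coarse
#'   grid.
#' @param dims integer triple of the fine grid (componentwise >= coarse).
#' @param spacing fine-grid spacing, cm.
#' @return a `dose_components` object on the fine grid.
#' @export
upsample_dose_components <- function(components, dims, spacing) {
  src <- components$dims
  dims <- as.integer(dims)
  if (any(dims < src)) stop("dims must be >= the coarse grid componentwise")
  cm <- lapply(1:3, function(a)
    as.integer(floor((seq_len(dims[a]) - 1) * src[a] / dims[a])) + 1L)
  out <- components
  for (ch in BEAM_CHANNELS)
    out[[ch]] <- components[[ch]][cm[[1]], cm[[2]], cm[[3]]]
  out$dims <- dims
  out$spacing <- as.numeric(spacing)
  out
}

#' Accumulate a Gray-equivalent rate grid over the beam-on time
#'
#' @param rate a rate-flagged [gyeq_grid()].
#' @param beam_time beam-on time in minutes (>= 0).
#' @return an accumulated [gyeq_grid()].
#' @export
accumulate <- function(rate, beam_time) {
  if (!inherits(rate, "gyeq_grid")) stop("rate must be a gyeq_grid")
  if (rate$kind != "rate")
    stop("grid is already accumulated; accumulate() takes a rate grid")
  if (!is.numeric(beam_time) || length(beam_time) != 1L || beam_time < 0)
    stop("beam_time must be a scalar >= 0")
  gyeq_grid(rate$values * beam_time, "accumulated", rate$spacing)
}
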