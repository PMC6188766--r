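#' Positioning-perturbation specification
#'
#' One element of the setup-error battery. Translations (`left`, `right`,
#' `superior`, `inferior`, `outward`) take a magnitude in cm (>= 0);
#' `rotation` (about the beam central axis) and `tilt` (about the
#' left-right axis through the phantom centroid, i.e. in the sagittal
#' plane) take a signed magnitude in degrees (positive = counterclockwise
#' looking down the rotation axis). `none` is the unperturbed baseline.
#'
#' @param kind one of `none`, `left`, `right`, `superior`, `inferior`,
#'   `outward`, `rotation`, `tilt`.
#' @param magnitude cm for translations, signed degrees for rotation/tilt.
#' @return an object of class `shift_spec`.
#' @export
shift_spec <- function(kind = c("none", "left", "right", "superior",
                                "inferior", "outward", "rotation", "tilt"),
                       magnitude = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(magnitude) || length(magnitude) != 1L ||
      !is.finite(magnitude))
    stop("magnitude must be a finite scalar")
  translation <- kind %in% c("left", "right", "superior", "inferior",
                             "outward")
  if (translation && magnitude < 0)
    stop("translation magnitudes must be >= 0")
  if (kind == "none" && magnitude != 0)
    stop("kind 'none' requires magnitude 0")
  structure(list(kind = kind, magnitude = magnitude), class = "shift_spec")
}

#' Rigid transform in the world frame
#'
#' Acts on points as `p -> R %*% p + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, cm.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8 ||
      abs(det(R) - 1) > 1e-8)
    stop("rotation must be a proper orthonormal 3x3 matrix")
  structure(list(rotation = R, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms (`a` after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return their composition as a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% t$translation))
}

rot_about_axis <- function(axis, theta) {
  # axis: unit 3-vector; Rodrigues formula
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# rotation about the line through `pivot` with direction `axis`
rot_about_line <- function(axis, theta, pivot) {
  R <- rot_about_axis(axis, theta)
  rigid_transform(R, pivot - as.vector(R %*% pivot))
}

#' Build the rigid transform realizing a perturbation
#'
#' Left/right translate along +/- x, superior/inferior along +/- z,
#' outward along +y (away from the aperture plane at y = 0, opening an air
#' gap). Rotation is about the beam central axis (the +y line through the
#' aperture center); tilt is about the left-right (x) axis through
#' `pivot`, i.e. in the sagittal plane. The study pipeline passes the plan
#' isocenter (the tumor centroid) as the tilt pivot — the radiotherapy
#' convention for angular setup errors; a pivot far from the target would
#' turn a pure tilt into a large effective translation.
#'
#' @param spec a [shift_spec()].
#' @param beam a [beam_config()] (provides the beam axis position).
#' @param pivot length-3 tilt pivot, cm (required for `tilt`).
#' @return a [rigid_transform()].
#' @export
transform_from_spec <- function(spec, beam = beam_config(),
                                pivot = NULL) {
  m <- spec$magnitude
  switch(spec$kind,
    none     = rigid_transform(),
    left     = rigid_transform(translation = c(m, 0, 0)),
    right    = rigid_transform(translation = c(-m, 0, 0)),
    superior = rigid_transform(translation = c(0, 0, m)),
    inferior = rigid_transform(translation = c(0, 0, -m)),
    outward  = rigid_transform(translation = c(0, m, 0)),
    rotation = rot_about_line(c(0, 1, 0), m * pi / 180,
                              c(beam$beam_axis_position[1], 0,
                                beam$beam_axis_position[2])),
    tilt     = {
      if (is.null(pivot))
        stop("tilt requires a pivot point (the plan isocenter)")
      rot_about_line(c(1, 0, 0), m * pi / 180, pivot)
    },
    stop("unknown shift kind: ", spec$kind)
  )
}

#' Tissue centroid of a phantom
#'
#' @param phantom a [voxel_phantom()].
#' @return length-3 world coordinates (cm) of the non-air voxel centroid.
#' @export
phantom_centroid <- function(phantom) {
  tis <- phantom$material_grid != air_label_of(phantom)
  cc <- voxel_centers(dim(tis), phantom$spacing, phantom$origin)
  c(mean(cc[[1]][slice.index(tis, 1)[tis]]),
    mean(cc[[2]][slice.index(tis, 2)[tis]]),
    mean(cc[[3]][slice.index(tis, 3)[tis]]))
}

#' Centroid of an ROI mask
#'
#' @param mask logical 3-D array.
#' @param spacing voxel spacing, cm.
#' @param origin grid origin, cm.
#' @return length-3 world coordinates (cm) of the mask centroid.
#' @export
mask_centroid <- function(mask, spacing, origin) {
  if (!any(mask)) stop("empty mask has no centroid")
  cc <- voxel_centers(dim(mask), spacing, origin)
  c(mean(cc[[1]][slice.index(mask, 1)[mask]]),
    mean(cc[[2]][slice.index(mask, 2)[mask]]),
    mean(cc[[3]][slice.index(mask, 3)[mask]]))
}

#' Resample a phantom and its ROI masks under a rigid transform
#'
#' Inverse-mapping nearest-neighbor resampling on the same grid: each
#' output voxel center is pulled back through the inverse transform and
#' takes the label/mask value of the nearest source voxel; locations mapped
#' from outside the source domain become air / empty mask. Material labels
#' stay integers and masks stay boolean; no dose interpolation ever occurs
#' because dose is computed after the transform.
#'
#' @param phantom a [voxel_phantom()].
#' @param rois a [roi_set()] (or NULL).
#' @param transform a [rigid_transform()].
#' @return list with elements `phantom` and `rois`.
#' @export
apply_transform <- function(phantom, rois, transform) {
  dims <- dim(phantom$material_grid)
  sp <- phantom$spacing; org <- phantom$origin
  inv <- invert_transform(transform)

  cc <- voxel_centers(dims, sp, org)
  n <- prod(dims)
  P <- cbind(cc[[1]][slice.index(phantom$material_grid, 1)],
             cc[[2]][slice.index(phantom$material_grid, 2)],
             cc[[3]][slice.index(phantom$material_grid, 3)])
  S <- P %*% t(inv$rotation) +
       matrix(inv$translation, n, 3, byrow = TRUE)
  ix <- as.integer(floor((S[, 1] - org[1]) / sp[1])) + 1L
  iy <- as.integer(floor((S[, 2] - org[2]) / sp[2])) + 1L
  iz <- as.integer(floor((S[, 3] - org[3]) / sp[3])) + 1L
  ok <- ix >= 1L & ix <= dims[1] & iy >= 1L & iy <= dims[2] &
        iz >= 1L & iz <= dims[3]
  lin <- ix + (iy - 1L) * dims[1] + (iz - 1L) * dims[1] * dims[2]

  air <- air_label_of(phantom)
  mat <- rep(air, n)
  mat[ok] <- phantom$material_grid[lin[ok]]
  ph <- voxel_phantom(array(mat, dims), sp, org, phantom$material_table)

  out_rois <- NULL
  if (!is.null(rois)) {
    masks <- lapply(names(rois), function(nm) {
      v <- rep(FALSE, n)
      v[ok] <- rois[[nm]][lin[ok]]
      array(v, dims)
    })
    names(masks) <- names(rois)
    out_rois <- roi_set(masks)
  }
  list(phantom = ph, rois = out_rois)
}
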