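#' Voxel phantom
#'
#' A labeled 3-D material grid with physical spacing and a material table.
#' The world frame is right-handed: the beam travels along +y
#' (posterior to anterior), +x is the patient's left, +z is superior.
#' Voxel `(i, j, k)` (1-based) owns the half-open box
#' `[origin + (i-1)*d, origin + i*d)`; its center is `origin + (i-1/2)*d`.
#' Depth is measured from the phantom entry surface along +y.
#'
#' @param material_grid 3-D integer array of material labels.
#' @param spacing numeric length-3, voxel size (dx, dy, dz) in cm.
#' @param origin numeric length-3, world coordinate (cm) of the corner of
#'   voxel (1, 1, 1).
#' @param material_table data frame with columns `label`, `name`, `density`
#'   (g/cm^3). Every label occurring in `material_grid` must be present.
#' @return an object of class `voxel_phantom` with fields `material_grid`,
#'   `density_grid`, `spacing`, `origin`, `material_table`.
#' @export
voxel_phantom <- function(material_grid, spacing, origin, material_table) {
  if (length(dim(material_grid)) != 3L)
    stop("material_grid must be a 3-D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be positive")
  if (length(origin) != 3L) stop("origin must have length 3")
  req <- c("label", "name", "density")
  if (!all(req %in% names(material_table)))
    stop("material_table needs columns label, name, density")
  labs <- sort(unique(as.vector(material_grid)))
  if (!all(labs %in% material_table$label))
    stop("labels missing from material_table: ",
         paste(setdiff(labs, material_table$label), collapse = ", "))
  dens <- material_table$density[match(as.vector(material_grid),
                                       material_table$label)]
  structure(list(
    material_grid  = material_grid,
    density_grid   = array(dens, dim = dim(material_grid)),
    spacing        = as.numeric(spacing),
    origin         = as.numeric(origin),
    material_table = material_table[order(material_table$label), , drop = FALSE]
  ), class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$material_grid)
  cat("voxel_phantom:", paste(d, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 3), collapse = " x "), "cm spacing\n")
  cat("  extent:", paste(signif(d * x$spacing, 4), collapse = " x "), "cm;",
      nrow(x$material_table), "materials\n")
  invisible(x)
}

# label used for empty space; density of air at room temperature
AIR_LABEL <- 0L
AIR_DENSITY <- 0.0012

air_label_of <- function(phantom) {
  mt <- phantom$material_table
  i <- which(mt$name == "air")
  if (length(i)) mt$label[i[1L]] else mt$label[which.min(mt$density)]
}

#' Region-of-interest mask set
#'
#' @param masks named list of logical 3-D arrays, all with identical
#'   dimensions. Recognized names: `tumor`, `normal_brain`, `brainstem`,
#'   `circle_of_willis`, `lens_L`, `lens_R`, `eye_L`, `eye_R`,
#'   `optic_nerve_L`, `optic_nerve_R`.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(masks) {
  if (!length(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be a non-empty named list")
  d <- dim(masks[[1L]])
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), d))
      stop("mask '", nm, "' must be a logical array matching the others")
  }
  if (!is.null(masks$tumor) && !any(masks$tumor))
    stop("tumor mask is empty")
  if (!is.null(masks$tumor) && !is.null(masks$normal_brain) &&
      any(masks$tumor & masks$normal_brain))
    stop("tumor and normal_brain masks overlap")
  structure(masks, class = "roi_set")
}

#' Tumor geometry specification
#'
#' The virtual tumor is a cylinder whose axis runs superior-inferior
#' (perpendicular to the beam), centered on the beam axis, with its axis at
#' `depth` cm from the phantom entry surface along the beam direction. A
#' 3 cm diameter tumor at 6.5 cm depth therefore spans tissue depths
#' 5 to 8 cm.
#'
#' @param diameter tumor diameter in cm (default 3).
#' @param length tumor axis length in cm (default 5).
#' @param depth depth of the tumor axis from the entry surface in cm
#'   (2.5 or 6.5 in the reference battery).
#' @return an object of class `tumor_spec`.
#' @export
tumor_spec <- function(diameter = 3, length = 5, depth = 6.5) {
  stopifnot_scalar_pos(diameter, "diameter")
  stopifnot_scalar_pos(length, "length")
  if (!is.numeric(depth) || base::length(depth) != 1L || depth < 0)
    stop("depth must be >= 0")
  structure(list(diameter = diameter, length = length, depth = depth),
            class = "tumor_spec")
}

# voxel center coordinate vectors for a grid
voxel_centers <- function(dims, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * spacing[a])
}

# logical mask of a z-axis capsule/cylinder primitive, by voxel-center test
mask_zcylinder <- function(cx, cy, cz, center, radius, half_length) {
  r2 <- outer((cx - center[1])^2, (cy - center[2])^2, "+")
  inplane <- r2 <= radius^2
  zin <- abs(cz - center[3]) <= half_length
  outer(inplane, zin, "&")
}

mask_sphere <- function(cx, cy, cz, center, radius) {
  d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
              (cz - center[3])^2, "+")
  d2 <= radius^2
}

mask_ellipsoid <- function(cx, cy, cz, center, semi) {
  d2 <- outer(outer(((cx - center[1]) / semi[1])^2,
                    ((cy - center[2]) / semi[2])^2, "+"),
              ((cz - center[3]) / semi[3])^2, "+")
  d2 <= 1
}

# capsule: all points within `radius` of the segment p1--p2
mask_capsule <- function(cx, cy, cz, p1, p2, radius) {
  dims <- c(length(cx), length(cy), length(cz))
  X <- array(rep(cx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2] + (Z - p1[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  (X - p1[1] - t * v[1])^2 + (Y - p1[2] - t * v[2])^2 +
    (Z - p1[3] - t * v[3])^2 <= radius^2
}

tumor_mask <- function(cx, cy, cz, tumor, axis_x, axis_z, entry_y) {
  # cylinder along z: axis at (axis_x, entry_y + depth), length along z
  r <- tumor$diameter / 2
  r2 <- outer((cx - axis_x)^2, (cy - (entry_y + tumor$depth))^2, "+")
  outer(r2 <= r^2, abs(cz - axis_z) <= tumor$length / 2, "&")
}

#' Build the homogeneous cylindrical PMMA phantom
#'
#' A PMMA cylinder (density 1.19 g/cm^3) with its axis along the beam
#' direction (+y), flat entry face at y = 0, surrounded by air. The virtual
#' tumor cylinder (see [tumor_spec()]) is centered on the beam axis with its
#' axis at `tumor$depth` cm of tissue depth. Lateral air margins are included
#' so that the perturbation battery (shifts up to 3 cm) keeps the phantom
#' inside the grid.
#'
#' @param diameter cylinder diameter in cm (default 16).
#' @param length cylinder length along the beam in cm (default 25).
#' @param spacing voxel size in cm, scalar or length-3 (default 0.4 cm
#'   isotropic).
#' @param tumor a [tumor_spec()].
#' @param margin lateral/axial air margin in cm (default 4).
#' @return list with elements `phantom` ([voxel_phantom()]) and
#'   `rois` ([roi_set()] with `tumor` and `normal_tissue` masks).
#' @export
build_cylinder_phantom <- function(diameter = 16, length = 25,
                                   spacing = 0.4,
                                   tumor = tumor_spec(),
                                   margin = 4) {
  stopifnot_scalar_pos(diameter, "diameter")
  stopifnot_scalar_pos(length, "length")
  if (base::length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing components must be positive")
  R <- diameter / 2
  rt <- tumor$diameter / 2
  if (tumor$depth - rt < 0 || tumor$depth + rt > length)
    stop("tumor extends outside the phantom along the beam axis (depth ",
         tumor$depth, " cm, radius ", rt, " cm, cylinder length ",
         length, " cm)")
  if (rt > R || tumor$length / 2 > R)
    stop("tumor extends outside the phantom cross-section")

  # odd lateral voxel counts keep the beam axis on a voxel-center column,
  # which makes left/right shifts exactly mirror-symmetric
  half_span <- R + margin
  nx <- 2L * ceiling(half_span / spacing[1] - 0.5) + 1L
  nz <- 2L * ceiling(half_span / spacing[3] - 0.5) + 1L
  ny <- as.integer(ceiling((length + margin) / spacing[2]))
  dims <- c(nx, ny, nz)
  origin <- c(-nx / 2 * spacing[1], 0, -nz / 2 * spacing[3])
  cc <- voxel_centers(dims, spacing, origin)

  inside <- outer(outer(cc[[1]]^2, rep(1, ny), "*"),
                  cc[[3]]^2, "+") <= R^2
  inside <- inside & outer(matrix(rep(cc[[2]] >= 0 & cc[[2]] <= length,
                                      each = nx), nx, ny),
                           rep(TRUE, nz), "&")
  mat <- array(AIR_LABEL, dims)
  mat[inside] <- 1L
  mt <- data.frame(label = c(AIR_LABEL, 1L),
                   name = c("air", "pmma"),
                   density = c(AIR_DENSITY, 1.19))
  ph <- voxel_phantom(mat, spacing, origin, mt)
  tm <- tumor_mask(cc[[1]], cc[[2]], cc[[3]], tumor,
                   axis_x = 0, axis_z = 0, entry_y = 0) & inside
  rois <- roi_set(list(tumor = tm, normal_tissue = inside & !tm))
  list(phantom = ph, rois = rois)
}

#' Default head ROI geometry
#'
#' Positions and sizes (cm) of the head-model regions of interest, in the
#' head frame whose posterior scalp pole sits at y = 0 on the beam axis
#' (x = z = 0). All anterior structures (eyes, lenses, optic nerves) lie on
#' the far side of the head from the beam entry surface.
#'
#' @param head_axes semi-axes (AP, SI, LR) of the outer head ellipsoid, cm.
#' @return named list of ROI geometry parameters.
#' @export
default_roi_geometry <- function(head_axes = c(9.5, 12, 8)) {
  list(
    shell_thickness = 0.7,                     # scalp + skull, cm
    brainstem   = list(center = c(0, 10.5, -5.5), radius = 1.0,
                       half_length = 3.0),     # z-axis cylinder
    circle_of_willis = list(center = c(0, 11.0, -1.0), radius = 1.0),
    eye_radius  = 1.2,
    eye_center_L = c( 2.8, 16.9, 1.0),
    eye_center_R = c(-2.8, 16.9, 1.0),
    lens_radius = 0.45,
    lens_offset = 0.7,                          # anterior of eye center
    nerve_radius = 0.25,
    nerve_target = c(0.5, 11.5, 0)              # chiasm-ward endpoint (|x|)
  )
}

#' Build the synthetic head phantom
#'
#' An ellipsoidal head (soft-tissue scalp/skull shell around a brain
#' interior) facing the beam with its posterior surface, plus nine ROI
#' masks: tumor, normal brain, brainstem, circle of Willis, left/right eyes,
#' lenses and optic nerves. Anterior structures lie on the far side from the
#' entry surface. `normal_brain` is the brain interior minus the tumor.
#'
#' @param head_axes semi-axes (AP, SI, LR) of the head ellipsoid in cm
#'   (default 9.5, 12, 8 — adult-head scale).
#' @param tumor a [tumor_spec()]; the tumor must fit inside the brain.
#' @param roi_geometry parameter set, see [default_roi_geometry()].
#' @param spacing voxel size in cm, scalar or length-3 (default 0.4).
#' @param margin lateral air margin in cm (default 4).
#' @return list with elements `phantom` and `rois`.
#' @export
build_head_phantom <- function(head_axes = c(9.5, 12, 8),
                               tumor = tumor_spec(),
                               roi_geometry = default_roi_geometry(head_axes),
                               spacing = 0.4,
                               margin = 4) {
  if (base::length(head_axes) != 3L || any(head_axes <= 0))
    stop("head_axes must be three positive semi-axes (AP, SI, LR)")
  if (base::length(spacing) == 1L) spacing <- rep(spacing, 3)
  g <- roi_geometry
  aAP <- head_axes[1]; aSI <- head_axes[2]; aLR <- head_axes[3]
  if (tumor$depth + tumor$diameter / 2 > 2 * aAP)
    stop("tumor depth exceeds the head extent along the beam axis")

  head_center <- c(0, aAP, 0)   # posterior pole at y = 0
  brain_semi <- c(aLR, aAP, aSI) - g$shell_thickness  # (x, y, z) order below

  # grid: beam axis centered laterally, y from -margin to 2*aAP + margin
  nx <- 2L * ceiling((aLR + margin) / spacing[1] - 0.5) + 1L
  nz <- 2L * ceiling((aSI + margin) / spacing[3] - 0.5) + 1L
  ny <- as.integer(ceiling((2 * aAP + 2 * margin) / spacing[2]))
  dims <- c(nx, ny, nz)
  origin <- c(-nx / 2 * spacing[1], -margin, -nz / 2 * spacing[3])
  cc <- voxel_centers(dims, spacing, origin)

  head <- mask_ellipsoid(cc[[1]], cc[[2]], cc[[3]],
                         center = head_center, semi = c(aLR, aAP, aSI))
  brain <- mask_ellipsoid(cc[[1]], cc[[2]], cc[[3]],
                          center = head_center, semi = brain_semi)

  # tumor must fit inside the brain: check the extreme points analytically
  rt <- tumor$diameter / 2
  ext <- rbind(c(0, tumor$depth - rt, 0), c(0, tumor$depth + rt, 0),
               c(rt, tumor$depth, 0), c(-rt, tumor$depth, 0),
               c(0, tumor$depth - rt,  tumor$length / 2),
               c(0, tumor$depth - rt, -tumor$length / 2),
               c(rt, tumor$depth,  tumor$length / 2),
               c(-rt, tumor$depth, -tumor$length / 2))
  q <- ((ext[, 1] - head_center[1]) / brain_semi[1])^2 +
       ((ext[, 2] - head_center[2]) / brain_semi[2])^2 +
       ((ext[, 3] - head_center[3]) / brain_semi[3])^2
  if (any(q > 1))
    stop("tumor does not fit inside the brain region (depth ", tumor$depth,
         " cm); reduce depth or enlarge the head")

  # lens must sit inside its eye (center distance + lens radius <= eye radius)
  if (g$lens_offset + g$lens_radius > g$eye_radius)
    stop("inconsistent lens/eye geometry: lens (offset ", g$lens_offset,
         " + radius ", g$lens_radius, ") pokes outside the eye (radius ",
         g$eye_radius, ")")

  mat <- array(AIR_LABEL, dims)
  mat[head] <- 1L
  mat[brain] <- 2L
  mt <- data.frame(label = c(AIR_LABEL, 1L, 2L),
                   name = c("air", "soft_tissue", "brain"),
                   density = c(AIR_DENSITY, 1.03, 1.04))
  ph <- voxel_phantom(mat, spacing, origin, mt)

  tm <- tumor_mask(cc[[1]], cc[[2]], cc[[3]], tumor,
                   axis_x = 0, axis_z = 0, entry_y = 0) & brain
  bs <- mask_zcylinder(cc[[1]], cc[[2]], cc[[3]], g$brainstem$center,
                       g$brainstem$radius, g$brainstem$half_length) & brain
  cw <- mask_sphere(cc[[1]], cc[[2]], cc[[3]], g$circle_of_willis$center,
                    g$circle_of_willis$radius) & brain
  eyeL <- mask_sphere(cc[[1]], cc[[2]], cc[[3]], g$eye_center_L,
                      g$eye_radius) & head
  eyeR <- mask_sphere(cc[[1]], cc[[2]], cc[[3]], g$eye_center_R,
                      g$eye_radius) & head
  lensL <- mask_sphere(cc[[1]], cc[[2]], cc[[3]],
                       g$eye_center_L + c(0, g$lens_offset, 0),
                       g$lens_radius) & head
  lensR <- mask_sphere(cc[[1]], cc[[2]], cc[[3]],
                       g$eye_center_R + c(0, g$lens_offset, 0),
                       g$lens_radius) & head
  tgt <- g$nerve_target
  onL <- mask_capsule(cc[[1]], cc[[2]], cc[[3]],
                      g$eye_center_L + c(0, -g$eye_radius + 0.2, 0),
                      c(abs(tgt[1]), tgt[2], tgt[3]), g$nerve_radius) & head
  onR <- mask_capsule(cc[[1]], cc[[2]], cc[[3]],
                      g$eye_center_R + c(0, -g$eye_radius + 0.2, 0),
                      c(-abs(tgt[1]), tgt[2], tgt[3]), g$nerve_radius) & head

  rois <- roi_set(list(
    tumor = tm, normal_brain = brain & !tm,
    brainstem = bs, circle_of_willis = cw,
    eye_L = eyeL, eye_R = eyeR, lens_L = lensL, lens_R = lensR,
    optic_nerve_L = onL, optic_nerve_R = onR))
  list(phantom = ph, rois = rois)
}
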