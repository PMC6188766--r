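#' Write a phantom as an 8-bit grayscale TIFF slice stack
#'
#' One single-channel 8-bit TIFF per axial (z) slice with zero-padded
#' numeric names (`slice_001.tif`, ...), ROI masks as per-ROI TIFF stacks in
#' subdirectories (`roi_<name>/slice_001.tif`, 0/255 valued), and a
#' plain-text `manifest.txt` with `key=value` lines recording dimensions,
#' spacing, origin, axial extent and the label-to-gray mapping so the
#' encoding is never implicit. Gray levels: air maps to 0, the remaining
#' materials are spread evenly over 1–255 in density order.
#'
#' @param phantom a [voxel_phantom()].
#' @param rois a [roi_set()] aligned to `phantom` (or NULL to skip masks).
#' @param directory output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_image_stack <- function(phantom, rois, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(phantom$material_grid)
  mt <- phantom$material_table
  air <- air_label_of(phantom)
  others <- mt[mt$label != air, , drop = FALSE]
  others <- others[order(others$density, others$label), , drop = FALSE]
  m <- nrow(others)
  grays <- if (m == 0L) integer(0)
           else if (m == 1L) 255L
           else as.integer(round(1 + (seq_len(m) - 1) * 254 / (m - 1)))
  lmap <- data.frame(label = c(air, others$label),
                     gray = c(0L, grays),
                     name = c("air", others$name),
                     density = c(mt$density[mt$label == air], others$density))
  gray_of <- integer(max(lmap$label) + 1L)
  gray_of[lmap$label + 1L] <- lmap$gray

  nslice <- dims[3]
  for (k in seq_len(nslice)) {
    sl <- gray_of[phantom$material_grid[, , k] + 1L]
    img <- matrix(sl / 255, nrow = dims[2], ncol = dims[1], byrow = TRUE)
    # TIFF rows run top-to-bottom; store y as rows, x as columns
    tiff::writeTIFF(img, file.path(directory,
                                   sprintf("slice_%03d.tif", k)),
                    bits.per.sample = 8L)
  }
  roi_names <- character(0)
  if (!is.null(rois)) {
    roi_names <- names(rois)
    for (nm in roi_names) {
      sub <- file.path(directory, paste0("roi_", nm))
      dir.create(sub, showWarnings = FALSE)
      for (k in seq_len(nslice)) {
        img <- matrix(as.numeric(rois[[nm]][, , k]),
                      nrow = dims[2], ncol = dims[1], byrow = TRUE)
        tiff::writeTIFF(img, file.path(sub, sprintf("slice_%03d.tif", k)),
                        bits.per.sample = 8L)
      }
    }
  }
  man <- c(
    sprintf("dims=%d %d %d", dims[1], dims[2], dims[3]),
    sprintf("spacing=%.10g %.10g %.10g", phantom$spacing[1],
            phantom$spacing[2], phantom$spacing[3]),
    sprintf("origin=%.10g %.10g %.10g", phantom$origin[1],
            phantom$origin[2], phantom$origin[3]),
    sprintf("n_slices=%d", nslice),
    sprintf("slice_thickness_cm=%.10g", phantom$spacing[3]),
    sprintf("axial_extent_cm=%.10g", nslice * phantom$spacing[3]),
    sprintf("rois=%s", paste(roi_names, collapse = ",")),
    "# label_map: label:gray:name:density",
    sprintf("label_map=%d:%d:%s:%.10g", lmap$label, lmap$gray,
            lmap$name, lmap$density)
  )
  writeLines(man, file.path(directory, "manifest.txt"))
  invisible(directory)
}

read_manifest <- function(directory) {
  path <- file.path(directory, "manifest.txt")
  if (!file.exists(path)) stop("missing manifest.txt in ", directory)
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1L], collapse = "="), "")
  get1 <- function(k) {
    v <- vals[keys == k]
    if (!length(v)) stop("manifest is missing key '", k, "'")
    v[1L]
  }
  lm <- do.call(rbind, lapply(vals[keys == "label_map"], function(s) {
    p <- strsplit(s, ":", fixed = TRUE)[[1L]]
    data.frame(label = as.integer(p[1]), gray = as.integer(p[2]),
               name = p[3], density = as.numeric(p[4]))
  }))
  rois <- strsplit(get1("rois"), ",", fixed = TRUE)[[1L]]
  list(dims = as.integer(strsplit(get1("dims"), " ")[[1L]]),
       spacing = as.numeric(strsplit(get1("spacing"), " ")[[1L]]),
       origin = as.numeric(strsplit(get1("origin"), " ")[[1L]]),
       label_map = lm,
       rois = rois[nzchar(rois)])
}

#' Read a phantom written by [write_image_stack()]
#'
#' Reconstructs the material labels from the manifest's gray mapping; the
#' round trip is exact (bitwise label equality). A slice with unexpected
#' dimensions or a gray value absent from the manifest raises an error
#' naming the slice.
#'
#' @param directory directory containing `manifest.txt` and the slices.
#' @return list with elements `phantom` and `rois` (NULL if no masks).
#' @export
read_image_stack <- function(directory) {
  man <- read_manifest(directory)
  dims <- man$dims
  label_of <- rep(NA_integer_, 256L)
  label_of[man$label_map$gray + 1L] <- man$label_map$label

  read_stack <- function(dir, decode) {
    arr <- array(0L, dims)
    for (k in seq_len(dims[3])) {
      f <- file.path(dir, sprintf("slice_%03d.tif", k))
      if (!file.exists(f)) stop("missing slice file: ", f)
      img <- tiff::readTIFF(f)
      if (!identical(dim(img), c(dims[2], dims[1])))
        stop("slice ", basename(f), " has dimensions ",
             paste(dim(img), collapse = "x"), ", expected ",
             dims[2], "x", dims[1])
      arr[, , k] <- decode(t(img), f)
    }
    arr
  }
  mat <- read_stack(directory, function(m, f) {
    g <- as.integer(round(m * 255))
    lab <- label_of[g + 1L]
    if (anyNA(lab))
      stop("slice ", basename(f), " contains gray values not in the ",
           "manifest label map: ", paste(unique(g[is.na(lab)]), collapse = ", "))
    matrix(lab, nrow = dims[1])
  })
  mt <- man$label_map[, c("label", "name", "density")]
  phantom <- voxel_phantom(mat, man$spacing, man$origin, mt)
  rois <- NULL
  if (length(man$rois)) {
    masks <- lapply(man$rois, function(nm) {
      arr <- read_stack(file.path(directory, paste0("roi_", nm)),
                        function(m, f) matrix(m > 0.5, nrow = dims[1]))
      array(as.logical(arr), dims)
    })
    names(masks) <- man$rois
    rois <- roi_set(masks)
  }
  list(phantom = phantom, rois = rois)
}

#' Downsample a phantom to the treatment-planning grid
#'
#' Block-averages the density onto `dims` coarse voxels, quantizes the
#' averaged densities to at most `n_materials` levels by uniform density
#' binning (labels sorted by density, ties broken by lower label), and
#' downsamples each ROI mask by a volume-corrected overlap vote: the coarse
#' voxels with the largest ROI overlap fraction are kept, as many as match
#' the ROI's physical volume (a plain > 50 % majority vote systematically
#' shrinks convex ROIs whose boundary blocks sit just under half coverage).
#' An ROI smaller than one coarse voxel keeps the single coarse voxel
#' nearest its centroid. Spacing is rescaled so the physical extent is
#' preserved. Tumor/normal-brain disjointness is re-enforced after the
#' vote.
#'
#' @param phantom a [voxel_phantom()].
#' @param rois a [roi_set()] (or NULL).
#' @param dims integer triple, target grid (default 21 x 21 x 25).
#' @param n_materials maximum number of quantized materials (default 56).
#' @return list with elements `phantom` and `rois`.
#' @export
voxelize_to_planning_grid <- function(phantom, rois = NULL,
                                      dims = c(21L, 21L, 25L),
                                      n_materials = 56L) {
  src <- dim(phantom$material_grid)
  dims <- as.integer(dims)
  if (any(dims <= 0L)) stop("dims must be positive")
  if (any(dims > src)) stop("dims must not exceed the source grid ",
                            paste(src, collapse = "x"))

  # fine voxel i -> coarse voxel floor((i-1)*dims/src) + 1
  cmap <- lapply(1:3, function(a)
    as.integer(floor((seq_len(src[a]) - 1) * dims[a] / src[a])) + 1L)
  ci <- cmap[[1]][slice.index(phantom$density_grid, 1)]
  cj <- cmap[[2]][slice.index(phantom$density_grid, 2)]
  ck <- cmap[[3]][slice.index(phantom$density_grid, 3)]
  lin <- ci + (cj - 1L) * dims[1] + (ck - 1L) * dims[1] * dims[2]
  ncoarse <- prod(dims)
  counts <- tabulate(lin, nbins = ncoarse)
  dens <- rowsum(as.vector(phantom$density_grid), lin)[, 1] / counts

  uq <- sort(unique(dens))
  if (length(uq) <= n_materials) {
    lab <- match(dens, uq) - 1L
    level_density <- uq
  } else {
    brk <- seq(min(dens), max(dens), length.out = n_materials + 1L)
    bin <- pmin(findInterval(dens, brk, rightmost.closed = TRUE),
                n_materials)
    used <- sort(unique(bin))
    lab <- match(bin, used) - 1L
    level_density <- as.vector(rowsum(dens, bin)[, 1] / tabulate(bin,
                     nbins = n_materials)[used])
  }
  # carry source names over when a level's density equals a source material's
  src_mt <- phantom$material_table
  nm <- vapply(level_density, function(d) {
    i <- which(abs(src_mt$density - d) < 1e-12)
    if (length(i)) src_mt$name[i[1L]] else sprintf("material_%03d",
                                                   which(level_density == d)[1L])
  }, "")
  mt <- data.frame(label = seq_along(level_density) - 1L,
                   name = nm, density = level_density)
  new_spacing <- phantom$spacing * src / dims
  ph <- voxel_phantom(array(lab, dims), new_spacing, phantom$origin, mt)

  out_rois <- NULL
  if (!is.null(rois)) {
    fine_vol <- prod(phantom$spacing)
    coarse_vol <- prod(new_spacing)
    masks <- lapply(names(rois), function(roi) {
      v <- as.vector(rois[[roi]])
      frac <- rowsum(as.numeric(v), lin)[, 1] / counts
      k <- round(sum(v) * fine_vol / coarse_vol)
      m <- array(FALSE, dims)
      if (k >= 1L) {
        keep <- order(-frac, seq_along(frac))[seq_len(k)]
        m[keep] <- frac[keep] > 0
      } else if (any(v)) {
        # ROI smaller than one coarse voxel: keep its centroid voxel
        cx <- round(c(mean(ci[v]), mean(cj[v]), mean(ck[v])))
        m[cx[1], cx[2], cx[3]] <- TRUE
      }
      m
    })
    names(masks) <- names(rois)
    if (!is.null(masks$tumor) && !is.null(masks$normal_brain))
      masks$normal_brain <- masks$normal_brain & !masks$tumor
    if (!is.null(masks$tumor) && !is.null(masks$normal_tissue))
      masks$normal_tissue <- masks$normal_tissue & !masks$tumor
    out_rois <- roi_set(masks)
  }
  list(phantom = ph, rois = out_rois)
}
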