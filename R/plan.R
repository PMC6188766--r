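#' Dose prescription
#'
#' @param dose prescribed dose in Gy-Eq (default 20).
#' @param coverage percent of the tumor volume that must receive at least
#'   `dose` (default 80).
#' @return an object of class `prescription`.
#' @export
prescription <- function(dose = 20, coverage = 80) {
  stopifnot_scalar_pos(dose, "dose")
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      coverage <= 0 || coverage > 100)
    stop("coverage must be in (0, 100]")
  structure(list(dose = dose, coverage = coverage), class = "prescription")
}

#' Cumulative dose-volume histogram
#'
#' Cumulative DVH over the masked voxels: `nbins` uniform bins from 0 to
#' the maximum masked dose; at each bin edge the curve records the percent
#' of the ROI volume receiving at least that dose. Starts at 100 % and is
#' non-increasing.
#'
#' @param dose a [gyeq_grid()].
#' @param mask logical array matching the grid; must select >= 1 voxel.
#' @param nbins number of bins (default 512).
#' @return an object of class `dvh` with fields `edges` (Gy-Eq) and
#'   `volume_pct`.
#' @export
dvh <- function(dose, mask, nbins = 512L) {
  if (!inherits(dose, "gyeq_grid")) stop("dose must be a gyeq_grid")
  if (!identical(dim(mask), dim(dose$values)))
    stop("mask dimensions do not match the dose grid")
  v <- dose$values[mask]
  if (!length(v)) stop("empty mask: DVH undefined")
  top <- max(v)
  edges <- seq(0, if (top > 0) top else 1, length.out = nbins + 1L)
  sv <- sort(v)
  n_less <- findInterval(edges, sv, left.open = TRUE)
  structure(list(edges = edges,
                 volume_pct = 100 * (length(v) - n_less) / length(v),
                 n_voxels = length(v), kind = dose$kind),
            class = "dvh")
}

#' Dose covering q percent of the ROI volume
#'
#' `D_q`: the largest dose received by at least `q` percent of the ROI,
#' read off the cumulative DVH with linear interpolation between the
#' bracketing bin edges (`D_80%` is the reference-study tumor coverage
#' metric).
#'
#' @param x a [dvh()].
#' @param q coverage percent in (0, 100].
#' @return dose in the DVH's units.
#' @export
d_percent <- function(x, q) {
  if (!inherits(x, "dvh")) stop("x must be a dvh")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100)
    stop("q must be in (0, 100]")
  f <- x$volume_pct; e <- x$edges
  j <- max(which(f >= q))          # f[1] = 100 >= q always
  if (j == length(e)) return(e[j])
  # f[j] >= q > f[j+1]
  e[j] + (f[j] - q) / (f[j] - f[j + 1]) * (e[j + 1] - e[j])
}

#' Beam-on time normalizing a plan to its prescription
#'
#' `beam_time = dose / D_coverage(rate)`: accumulating the rate grid for
#' the returned time makes the tumor `D_coverage` equal the prescription
#' exactly (linearity). The reference battery fixes this time from the
#' unperturbed plan and reuses it for every perturbed case.
#'
#' @param rate a rate-flagged [gyeq_grid()].
#' @param tumor_mask logical array selecting the tumor.
#' @param p a [prescription()].
#' @param nbins DVH resolution used for the coverage dose (default 512).
#' @return beam-on time in minutes.
#' @export
normalize_to_prescription <- function(rate, tumor_mask, p = prescription(),
                                      nbins = 512L) {
  if (!inherits(rate, "gyeq_grid") || rate$kind != "rate")
    stop("normalize_to_prescription needs a rate grid")
  if (!any(rate$values[tumor_mask] > 0))
    stop("tumor dose rate is zero everywhere: the beam misses the tumor")
  dq <- d_percent(dvh(rate, tumor_mask, nbins), p$coverage)
  if (dq <= 0)
    stop("tumor coverage dose rate is zero: the beam misses the tumor")
  p$dose / dq
}

#' ROI dose metrics
#'
#' Per-ROI mean, maximum and q-percent coverage dose over the masked
#' voxels. An empty ROI yields NA metrics (absent, not zero).
#'
#' @param dose a [gyeq_grid()].
#' @param rois a [roi_set()].
#' @param q coverage percent for the D_q column (default 80).
#' @param nbins DVH resolution for D_q (default 512).
#' @return data frame with columns `roi`, `n_voxels`, `d_mean`, `d_max`,
#'   `d_q`.
#' @export
roi_metrics <- function(dose, rois, q = 80, nbins = 512L) {
  if (!inherits(dose, "gyeq_grid")) stop("dose must be a gyeq_grid")
  rows <- lapply(names(rois), function(nm) {
    m <- rois[[nm]]
    if (!any(m))
      return(data.frame(roi = nm, n_voxels = 0L, d_mean = NA_real_,
                        d_max = NA_real_, d_q = NA_real_))
    v <- dose$values[m]
    data.frame(roi = nm, n_voxels = length(v), d_mean = mean(v),
               d_max = max(v), d_q = d_percent(dvh(dose, m, nbins), q))
  })
  do.call(rbind, rows)
}
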