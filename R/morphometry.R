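# Shape / texture morphometry and physical estimates. The shape descriptor
# is the classical moment-based roundness: 1 for an ideal disk, decreasing
# with elongation; texture descriptors quantify spheroid granularity.

#' Moment-based sphericity (roundness) of a ROI mask
#'
#' Computes `S = m00^2 / (2 * pi * (mu20 + mu02))`, where `m00` is the mask
#' area and `mu20`, `mu02` are its second central moments, all in pixel
#' units. `S = 1` for an ideal disk and `2ab / (a^2 + b^2)` for an ellipse
#' with semi-axes `a`, `b`; elongated or irregular shapes score lower.
#' Rasterization makes disk values deviate from 1 by well under 2% for radii
#' of 10 px and above.
#'
#' @param mask logical matrix (the ROI's pixel membership).
#' @return list with `S` and a `degenerate` flag (set when the mask is
#'   line-like, `S < 0.05`).
#' @examples
#' m <- outer(1:101, 1:101, function(i, j) (i - 51)^2 + (j - 51)^2 <= 40^2)
#' sphericity(m)$S
#' @export
sphericity <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  n <- sum(mask)
  if (n < 5) stop("mask must contain at least 5 pixels")
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  mu20 <- sum((x - mean(x))^2)
  mu02 <- sum((y - mean(y))^2)
  S <- n^2 / (2 * pi * (mu20 + mu02))
  list(S = S, degenerate = S < 0.05)
}

#' Gray-level texture descriptors of a ROI
#'
#' Shannon entropy (natural log) of the ROI's gray-level histogram over
#' `bins` equal-width bins spanning the ROI's own min--max range, plus the
#' pixel standard deviation (n - 1 denominator) and the gray-value range.
#' Because the binning spans each ROI's own range, absolute entropy values
#' are comparative between ROIs analysed with the same `bins`, not absolute
#' information measures. A constant ROI returns `(0, 0, 0)`.
#'
#' @param image a [field_image()] or numeric matrix.
#' @param mask logical ROI mask.
#' @param bins number of histogram bins.
#' @return list with `entropy` (nats), `gray_sd`, `gray_range`.
#' @export
texture <- function(image, mask, bins = 64) {
  px <- if (inherits(image, "field_image")) image$pixels else image
  stopifnot(is.matrix(px), is.matrix(mask), all(dim(px) == dim(mask)))
  v <- px[mask]
  if (!length(v)) stop("empty ROI mask")
  rng <- range(v)
  if (diff(rng) == 0)
    return(list(entropy = 0, gray_sd = 0, gray_range = 0))
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          bins), nbins = bins)
  p <- counts[counts > 0] / length(v)
  list(entropy = -sum(p * log(p)),
       gray_sd = stats::sd(v),
       gray_range = diff(rng))
}

#' Single-cell volume from projected sectional area
#'
#' Cells resting on a non-adherent substrate remain globular, so a cell's
#' volume can be estimated from its projected bright-field area by assuming
#' a sphere: `r = sqrt(area / pi)`, `V = 4/3 * pi * r^3`, reported in
#' picoliters (1 pL = 1000 um^3).
#'
#' @param area_um2 projected cell area, um^2 (> 0).
#' @return volume in pL.
#' @examples
#' cell_volume_from_area(pi * 7.4^2) # ~1.70 pL
#' @export
cell_volume_from_area <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("'area_um2' must be > 0")
  r <- sqrt(area_um2 / pi)
  (4 / 3) * pi * r^3 / 1000
}

#' Estimated number of cells in a spheroid
#'
#' Converts a spheroid's sectional area to a sphere-equivalent volume
#' (`r = sqrt(A / pi)`, `V = 4/3 * pi * r^3`) and divides by the mean
#' single-cell volume, rounding to the nearest integer (minimum 1).
#'
#' @param area_um2 spheroid sectional area, um^2 (> 0).
#' @param cell_volume_pl mean single-cell volume, pL (> 0).
#' @return integer cell count estimate.
#' @examples
#' cells_per_spheroid(4900, 1.69) # ~153 cells
#' @export
cells_per_spheroid <- function(area_um2, cell_volume_pl) {
  if (any(area_um2 <= 0) || any(cell_volume_pl <= 0))
    stop("areas and cell volumes must be > 0")
  r <- sqrt(area_um2 / pi)
  v_sph_pl <- (4 / 3) * pi * r^3 / 1000
  pmax(1L, as.integer(round(v_sph_pl / cell_volume_pl)))
}

#' Population doubling time from two cell counts
#'
#' `Td = dt * log(2) / log(N2 / N1)`. Defined (finite, positive) only for
#' growing populations; `N2 <= N1` yields `NA` with a flag.
#'
#' @param n1,n2 cell counts at the start and end of the interval (> 0).
#' @param dt_hours interval length, hours (> 0).
#' @return list with `td_hours` and `grew` flag.
#' @examples
#' doubling_time(116, 232, 24)$td_hours # 24 h
#' @export
doubling_time <- function(n1, n2, dt_hours) {
  if (any(n1 <= 0) || any(n2 <= 0) || any(dt_hours <= 0))
    stop("counts and interval must be > 0")
  grew <- n2 > n1
  td <- ifelse(grew, dt_hours * log(2) / log(n2 / n1), NA_real_)
  list(td_hours = td, grew = grew)
}
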