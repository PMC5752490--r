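# Per-ROI fluorescence quantification. Background is the mean of the pixels
# between the outlined regions, estimated independently for every acquired
# plane; metrics are computed on background-subtracted intensities, with the
# positivity threshold applied after subtraction so that adding a constant
# offset to a plane changes nothing.

#' Estimate the fluorescence background of a plane
#'
#' Mean intensity of all pixels lying outside every ROI. ROI outlines come
#' from the matching bright-field plane and are mapped onto the fluorescence
#' plane unchanged. With no ROIs the whole-field mean is returned; ROIs
#' covering the entire field leave no background pixels and raise an error.
#'
#' @param image a [field_image()] (fluorescence plane).
#' @param rois `spheroid_roi_set` from the matching bright-field plane.
#' @return list with `mean`, `sd` (n - 1 denominator, 0 for a single pixel)
#'   and `n_pixels` of the inter-ROI background.
#' @export
estimate_background <- function(image, rois = NULL) {
  px <- if (inherits(image, "field_image")) image$pixels else image
  outside <- if (is.null(rois) || !nrow(rois$table)) rep(TRUE, length(px))
             else rois$labels == 0
  v <- px[outside]
  if (!length(v))
    stop("ROIs cover the entire field; no background pixels remain")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n_pixels = length(v))
}

#' Default positivity threshold above background
#'
#' The threshold separating signal-positive pixels from background, in
#' background-subtracted units: `k` times the background pixel sd (default
#' `k = 2`).
#'
#' @param background result of [estimate_background()].
#' @param k multiple of the background sd.
#' @return threshold, arbitrary units.
#' @export
default_threshold <- function(background, k = 2) k * background$sd

#' Fluorescence metrics of one ROI
#'
#' The plane is background-subtracted (negative residuals clipped to 0) and
#' thresholded; then
#' * `mean_fi` — mean of the ROI pixels at or above the threshold (0 when
#'   none are),
#' * `area_fraction` — percentage of the ROI's pixels at or above the
#'   threshold,
#' * `pixel_cv` — sd / mean of all (unthresholded) background-subtracted ROI
#'   pixels, the within-spheroid heterogeneity of the stain.
#'
#' @param image a [field_image()] or intensity matrix.
#' @param roi logical ROI mask, or integer linear pixel indices.
#' @param background background level (au), e.g.
#'   `estimate_background(image, rois)$mean`.
#' @param threshold positivity threshold in background-subtracted units; see
#'   [default_threshold()].
#' @return list with `mean_fi`, `area_fraction` (percent), `pixel_cv`,
#'   `n_pixels`, `background`.
#' @export
measure_roi <- function(image, roi, background = 0, threshold = 0) {
  px <- if (inherits(image, "field_image")) image$pixels else image
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (!length(idx)) stop("empty ROI mask")
  v <- pmax(px[idx] - background, 0)
  pos <- v >= threshold & v > 0
  mu <- mean(v)
  list(mean_fi = if (any(pos)) mean(v[pos]) else 0,
       area_fraction = 100 * sum(pos) / length(v),
       pixel_cv = if (mu > 0) stats::sd(v) / mu else 0,
       n_pixels = length(v),
       background = background)
}

#' Fluorescence metrics for every ROI of a plane
#'
#' Convenience wrapper: estimates the inter-ROI background of the plane,
#' derives the default threshold (background + 2 sd) unless given, and runs
#' [measure_roi()] for each ROI.
#'
#' @param image fluorescence [field_image()].
#' @param rois `spheroid_roi_set` from the matching bright-field plane.
#' @param threshold positivity threshold (background-subtracted units);
#'   `NULL` for the default.
#' @param k sd multiple for the default threshold.
#' @return data.frame with one row per ROI: id, chamber indices, `mean_fi`,
#'   `area_fraction`, `pixel_cv`, `background`, `channel`, `timepoint`.
#' @export
quantify_rois <- function(image, rois, threshold = NULL, k = 2) {
  stopifnot(inherits(rois, "spheroid_roi_set"))
  bg <- estimate_background(image, rois)
  if (is.null(threshold)) threshold <- default_threshold(bg, k)
  tb <- rois$table
  res <- lapply(tb$id, function(id)
    measure_roi(image, roi_indices(rois, id), bg$mean, threshold))
  data.frame(id = tb$id,
             chamber_row = tb$chamber_row, chamber_col = tb$chamber_col,
             mean_fi = vapply(res, `[[`, numeric(1), "mean_fi"),
             area_fraction = vapply(res, `[[`, numeric(1), "area_fraction"),
             pixel_cv = vapply(res, `[[`, numeric(1), "pixel_cv"),
             background = bg$mean,
             channel = if (inherits(image, "field_image")) image$channel
                       else NA_character_,
             timepoint = if (inherits(image, "field_image")) image$timepoint
                         else NA_real_)
}

#' Two-timepoint intensity ratio (TMRM-style)
#'
#' Ratio of one spheroid's mean fluorescence intensity at two timepoints,
#' `FI(t2) / FI(t1)`; used with potentiometric dyes, where the ratio tracks
#' the change in mitochondrial membrane potential. Undefined when
#' `FI(t1) <= 0`; such records are returned as `NA` with `defined = FALSE`.
#'
#' @param fi_t1,fi_t2 mean FI at the two timepoints (vectorized).
#' @param id optional spheroid ids.
#' @return data.frame with `id`, `fi_t1`, `fi_t2`, `ratio`, `defined`.
#' @export
tmrm_ratio <- function(fi_t1, fi_t2, id = seq_along(fi_t1)) {
  stopifnot(length(fi_t1) == length(fi_t2))
  defined <- fi_t1 > 0
  data.frame(id = id, fi_t1 = fi_t1, fi_t2 = fi_t2,
             ratio = ifelse(defined, fi_t2 / fi_t1, NA_real_),
             defined = defined)
}

#' Build a mean +/- SD cutoff rule from a control population
#'
#' The classification rule used throughout: a reference (control) population
#' defines `upper = mean + SD` and `lower = mean - SD` (sample SD, n - 1
#' denominator). Values above `upper` are "positive" (or high-proliferating
#' for growth ratios); values below `lower` are low.
#'
#' @param reference numeric vector of control measurements (n >= 2, finite).
#' @return object of class `cutoff_rule`: `mean`, `sd`, `upper`, `lower`,
#'   `n`.
#' @examples
#' make_cutoff(c(0, 2)) # upper = 1 + sqrt(2)
#' @export
make_cutoff <- function(reference) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 2)
    stop("need at least 2 finite reference values")
  m <- mean(reference); s <- stats::sd(reference)
  structure(list(mean = m, sd = s, upper = m + s, lower = m - s,
                 n = length(reference)),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("cutoff_rule: mean %.4g, sd %.4g -> lower %.4g / upper %.4g (n = %d)\n",
              x$mean, x$sd, x$lower, x$upper, x$n))
  invisible(x)
}

#' Classify values against a cutoff rule
#'
#' Positive iff the value strictly exceeds the upper cutoff (a value exactly
#' at the cutoff is negative).
#'
#' @param values numeric vector (e.g. per-spheroid mean FI).
#' @param rule a [make_cutoff()] rule.
#' @return logical vector.
#' @export
classify_positive <- function(values, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  values > rule$upper
}

#' Staining-homogeneity QC across a z-stack
#'
#' Coefficient of variation of the per-focal-plane mean FI of one spheroid;
#' a low CV indicates the probe penetrated the spheroid uniformly along z, so
#' single-plane measurements represent the whole object. QC passes when the
#' CV does not exceed `limit` (default 0.08).
#'
#' @param plane_means per-plane mean FI values (>= 2 planes).
#' @param limit maximum acceptable CV.
#' @return list with `cv`, `pass`, `n_planes`.
#' @export
staining_homogeneity <- function(plane_means, limit = 0.08) {
  if (length(plane_means) < 2) stop("need at least 2 focal planes")
  mu <- mean(plane_means)
  cv <- if (mu > 0) stats::sd(plane_means) / mu else Inf
  list(cv = cv, pass = cv <= limit, n_planes = length(plane_means))
}
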