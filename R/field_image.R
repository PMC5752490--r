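#' Construct a field image
#'
#' A `field_image` is one 2D intensity plane acquired from a microscope field:
#' a matrix of arbitrary-unit intensities plus the metadata needed to interpret
#' it physically (channel label, timepoint in hours, pixel size in microns).
#' The matrix is indexed `[row, col]`; physical coordinates use the
#' pixel-center convention, so pixel `[i, j]` sits at
#' `x = (j - 0.5) * microns_per_pixel`, `y = (i - 0.5) * microns_per_pixel`,
#' with the origin at the top-left corner of the field.
#'
#' @param pixels numeric matrix of non-negative intensities (arbitrary units).
#' @param channel character channel label, e.g. `"bf"` for bright field.
#' @param timepoint acquisition time in hours.
#' @param microns_per_pixel physical pixel size, microns per pixel (> 0).
#' @param field_id identifier of the acquired field.
#' @return An object of class `field_image`.
#' @examples
#' fi <- field_image(matrix(100, 64, 64), "bf", 48, 2)
#' dim(fi$pixels)
#' @export
field_image <- function(pixels, channel, timepoint, microns_per_pixel,
                        field_id = "field1") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(pixels < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      microns_per_pixel <= 0)
    stop("'microns_per_pixel' must be a single positive number")
  structure(
    list(pixels = pixels, channel = as.character(channel),
         timepoint = as.numeric(timepoint),
         microns_per_pixel = as.numeric(microns_per_pixel),
         field_id = as.character(field_id)),
    class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image '%s': channel '%s', t = %g h, %d x %d px @ %g um/px\n",
              x$field_id, x$channel, x$timepoint,
              nrow(x$pixels), ncol(x$pixels), x$microns_per_pixel))
  invisible(x)
}

#' Retrieve one plane from a simulated acquisition
#'
#' @param sim result of [simulate_array()] or [simulate_invasion()].
#' @param channel channel label.
#' @param timepoint timepoint in hours.
#' @return The matching [field_image()].
#' @export
get_plane <- function(sim, channel, timepoint) {
  for (img in sim$images) {
    if (img$channel == channel && img$timepoint == timepoint) return(img)
  }
  stop(sprintf("no plane with channel '%s' at t = %g h", channel, timepoint))
}
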