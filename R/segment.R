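# Spheroid ROI detection on bright-field planes. The pipeline follows the
# classical edge-based recipe: Sobel gradient magnitude -> Otsu threshold on
# the gradient -> morphological closing to seal dashed edges -> hole filling
# -> one erosion step to compensate the thickness of the gradient band ->
# connected components filtered by physical area.

sobel_gradient <- function(px) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(px, kx, boundary = "replicate")
  gy <- EBImage::filter2(px, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

# Re-draw each filled edge component by Otsu thresholding the raw intensity
# in the component's padded bounding box: the edge band straddles the true
# boundary symmetrically, so the intensity split (object side = the darker of
# interior vs surround) recovers the outline without the band's half-width
# bias. Holes re-filled afterwards (dark objects can enclose brighter
# texture).
refine_by_intensity <- function(px, filled) {
  lab0 <- EBImage::imageData(EBImage::bwlabel(filled))
  n0 <- max(lab0)
  if (n0 == 0) return(filled)
  refined <- matrix(FALSE, nrow(px), ncol(px))
  nr <- nrow(px); nc <- ncol(px)
  for (k in seq_len(n0)) {
    idx <- which(lab0 == k)
    ii <- ((idx - 1L) %% nr) + 1L
    jj <- ((idx - 1L) %/% nr) + 1L
    pad <- 4L
    i0 <- max(1L, min(ii) - pad); i1 <- min(nr, max(ii) + pad)
    j0 <- max(1L, min(jj) - pad); j1 <- min(nc, max(jj) + pad)
    box <- px[i0:i1, j0:j1]
    rng <- range(box)
    if (diff(rng) == 0) { refined[idx] <- TRUE; next }
    boxn <- (box - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(boxn), range = c(0, 1))
    inmask <- matrix(FALSE, i1 - i0 + 1L, j1 - j0 + 1L)
    inmask[cbind(ii - i0 + 1L, jj - j0 + 1L)] <- TRUE
    object_dark <- mean(box[inmask]) < mean(box[!inmask])
    sel <- if (object_dark) boxn <= thr else boxn > thr
    refined[i0:i1, j0:j1] <- refined[i0:i1, j0:j1] | sel
  }
  EBImage::fillHull(EBImage::Image(refined))
}

roi_table_row <- function(id, n_px, area, cx, cy, border) {
  data.frame(id = id, n_px = n_px, area_um2 = area, cx_um = cx, cy_um = cy,
             chamber_row = rep(NA_integer_, length(id)),
             chamber_col = rep(NA_integer_, length(id)),
             touches_border = border)
}

empty_roi_table <- function() roi_table_row(integer(0), integer(0),
                                            numeric(0), numeric(0),
                                            numeric(0), logical(0))

#' Segment spheroid ROIs on a bright-field plane
#'
#' Detects spheroids as closed regions of high Sobel gradient magnitude:
#' the gradient map is thresholded with Otsu's method, the binary edge map is
#' morphologically closed (disc of radius `close_radius`) and hole-filled,
#' and labelled into connected components. Because the gradient of a step
#' edge is high on both sides of the true boundary, the filled components
#' overshoot the object by about the half-width of the edge band; each
#' component's outline is therefore refined by Otsu intensity thresholding
#' within its own neighbourhood (`refine = "intensity"`, the default — the
#' object side is whichever of the component's interior/exterior is darker),
#' which removes the bias to sub-pixel level. `refine = "none"` keeps the raw
#' filled components. Components outside `[min_area, max_area]` (physical
#' units) are discarded.
#'
#' A blank or constant plane yields an empty ROI set (not an error).
#'
#' @param image a bright-field [field_image()].
#' @param min_area,max_area component area bounds, um^2.
#' @param close_radius closing disc radius, px.
#' @param refine boundary refinement of the filled edge components.
#' @return An object of class `spheroid_roi_set`: the integer label matrix
#'   (`labels`, 0 = background) plus a per-ROI `table` with pixel count,
#'   area (um^2), centroid (um, pixel-center convention), chamber indices
#'   (`NA` until [assign_chambers()]) and a flag for ROIs touching the field
#'   border.
#' @examples
#' sim <- simulate_array(sim_config(grid_rows = 2, grid_cols = 2,
#'                                  occupancy = 1, rng_seed = 3))
#' rois <- segment_field(get_plane(sim, "bf", 48))
#' rois$table$area_um2
#' @export
segment_field <- function(image, min_area = 500, max_area = 60000,
                          close_radius = 3,
                          refine = c("intensity", "none")) {
  stopifnot(inherits(image, "field_image"))
  refine <- match.arg(refine)
  if (min_area >= max_area) stop("'min_area' must be < 'max_area'")
  px <- image$pixels
  mpp <- image$microns_per_pixel
  out <- structure(list(labels = matrix(0L, nrow(px), ncol(px)),
                        table = empty_roi_table(),
                        microns_per_pixel = mpp,
                        field_id = image$field_id,
                        channel = image$channel,
                        timepoint = image$timepoint),
                   class = "spheroid_roi_set")
  g <- sobel_gradient(px)
  gmax <- max(g)
  # a blank/constant plane has no real gradient, only FFT round-off
  if (gmax <= 1e-8 * (max(abs(px)) + 1)) return(out)
  g <- g / gmax
  thr <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  edges <- EBImage::Image(g > thr)
  if (close_radius > 0)
    edges <- EBImage::closing(edges,
                              EBImage::makeBrush(2 * close_radius + 1, "disc"))
  filled <- EBImage::fillHull(edges)
  if (refine == "intensity")
    filled <- refine_by_intensity(px, filled)
  lab <- EBImage::imageData(EBImage::bwlabel(filled))
  nlab <- max(lab)
  if (nlab == 0) return(out)
  counts <- tabulate(lab[lab > 0], nbins = nlab)
  areas <- counts * mpp^2
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) return(out)
  # relabel kept components 1..n in original label order
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  newlab <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  newlab[nz] <- remap[lab[nz]]
  rows <- vector("list", length(keep))
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(newlab > 0)
  ii <- ((idx - 1L) %% nr) + 1L
  jj <- ((idx - 1L) %/% nr) + 1L
  ll <- newlab[idx]
  for (k in seq_along(keep)) {
    sel <- ll == k
    i <- ii[sel]; j <- jj[sel]
    rows[[k]] <- roi_table_row(
      k, sum(sel), sum(sel) * mpp^2,
      mean(j - 0.5) * mpp, mean(i - 0.5) * mpp,
      any(i == 1L | i == nr | j == 1L | j == nc))
  }
  out$labels <- newlab
  out$table <- do.call(rbind, rows)
  out
}

#' @export
print.spheroid_roi_set <- function(x, ...) {
  cat(sprintf("spheroid_roi_set: %d ROI(s) on field '%s' (t = %g h)\n",
              nrow(x$table), x$field_id, x$timepoint))
  invisible(x)
}

#' Logical mask / pixel indices of one ROI
#'
#' @param rois a `spheroid_roi_set`.
#' @param id ROI id.
#' @return `roi_mask`: logical matrix; `roi_indices`: integer linear indices
#'   into the plane.
#' @export
roi_mask <- function(rois, id) rois$labels == id

#' @rdname roi_mask
#' @export
roi_indices <- function(rois, id) which(rois$labels == id)

#' Outline polygon of one ROI
#'
#' @inheritParams roi_mask
#' @return two-column matrix of boundary coordinates in microns
#'   (pixel-center convention).
#' @export
roi_outline <- function(rois, id) {
  oc <- EBImage::ocontour(EBImage::Image((rois$labels == id) * 1))[[1]]
  # ocontour returns 0-based (x, y) pixel indices
  (oc + 0.5) * rois$microns_per_pixel
}

#' Assign segmented ROIs to microchambers
#'
#' Each ROI is assigned to the grid cell containing its centroid; centroids
#' outside the grid extent get `NA`. A centroid falling exactly on a cell
#' boundary is assigned to the lower (row, col) index — a deterministic
#' tie-break.
#'
#' @param rois a `spheroid_roi_set`.
#' @param grid grid geometry as returned by [grid_geometry()]: a list with
#'   `pitch_um`, `rows`, `cols`, `origin_x`, `origin_y` (um).
#' @return The ROI set with `chamber_row` / `chamber_col` filled in.
#' @export
assign_chambers <- function(rois, grid) {
  stopifnot(inherits(rois, "spheroid_roi_set"))
  tb <- rois$table
  if (nrow(tb)) {
    col <- ceiling((tb$cx_um - grid$origin_x) / grid$pitch_um)
    row <- ceiling((tb$cy_um - grid$origin_y) / grid$pitch_um)
    ok <- col >= 1 & col <= grid$cols & row >= 1 & row <= grid$rows
    tb$chamber_col <- ifelse(ok, as.integer(col), NA_integer_)
    tb$chamber_row <- ifelse(ok, as.integer(row), NA_integer_)
  }
  rois$table <- tb
  rois
}

#' Match ROIs of the same spheroid across two timepoints
#'
#' ROIs are paired by identical chamber index, which is valid because the
#' chamber walls keep each spheroid in place between acquisitions. Chambers
#' holding more than one ROI at either timepoint are ambiguous and excluded
#' from tracks; chambers present at only one timepoint are reported as
#' unpaired.
#'
#' @param rois_t1,rois_t2 chamber-assigned `spheroid_roi_set`s of the same
#'   field at two timepoints.
#' @return list with `tracks` (data.frame: chamber_row, chamber_col, id_t1,
#'   id_t2), `unpaired_t1`, `unpaired_t2` (ROI ids) and `ambiguous`
#'   (data.frame of flagged chambers).
#' @export
track_rois <- function(rois_t1, rois_t2) {
  t1 <- rois_t1$table; t2 <- rois_t2$table
  if ((nrow(t1) && all(is.na(t1$chamber_row))) ||
      (nrow(t2) && all(is.na(t2$chamber_row))))
    stop("ROIs must be chamber-assigned before tracking; run assign_chambers()")
  key <- function(tb) ifelse(is.na(tb$chamber_row), NA,
                             paste(tb$chamber_row, tb$chamber_col))
  k1 <- key(t1); k2 <- key(t2)
  amb <- unique(c(k1[duplicated(k1) & !is.na(k1)],
                  k2[duplicated(k2) & !is.na(k2)]))
  usable1 <- !is.na(k1) & !(k1 %in% amb)
  usable2 <- !is.na(k2) & !(k2 %in% amb)
  common <- intersect(k1[usable1], k2[usable2])
  tracks <- data.frame(chamber_row = integer(0), chamber_col = integer(0),
                       id_t1 = integer(0), id_t2 = integer(0))
  if (length(common)) {
    i1 <- match(common, k1)
    i2 <- match(common, k2)
    tracks <- data.frame(chamber_row = t1$chamber_row[i1],
                         chamber_col = t1$chamber_col[i1],
                         id_t1 = t1$id[i1], id_t2 = t2$id[i2])
  }
  amb_df <- if (length(amb)) {
    parts <- do.call(rbind, strsplit(amb, " "))
    data.frame(chamber_row = as.integer(parts[, 1]),
               chamber_col = as.integer(parts[, 2]))
  } else data.frame(chamber_row = integer(0), chamber_col = integer(0))
  list(tracks = tracks,
       unpaired_t1 = t1$id[usable1 & !(k1 %in% common)],
       unpaired_t2 = t2$id[usable2 & !(k2 %in% common)],
       ambiguous = amb_df)
}
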