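# Collective-migration analysis of matrix-embedded spheroids from
# two-timepoint centroid positions.

#' Migration distance of one spheroid
#'
#' Euclidean displacement of a spheroid's centroid between two timepoints,
#' `d = sqrt((X1 - X2)^2 + (Y1 - Y2)^2)`, in microns. Accepts either two
#' `(x, y)` coordinate vectors in microns or two single-ROI rows of
#' chamber-tracked `spheroid_roi_set` tables.
#'
#' @param before,after length-2 numeric `(x, y)` in um, or single rows of a
#'   ROI table carrying `cx_um` / `cy_um`.
#' @param elapsed_hours assay interval, hours (recorded, not used in d).
#' @param id spheroid id.
#' @return data.frame (class `migration_record`) with centroids, `d_um` and
#'   `elapsed_hours`.
#' @examples
#' migration_distance(c(0, 0), c(3, 4))$d_um # 5
#' @export
migration_distance <- function(before, after, elapsed_hours = NA_real_,
                               id = 1L) {
  xy <- function(p) {
    if (is.numeric(p) && length(p) == 2) return(as.numeric(p))
    if (is.data.frame(p) && nrow(p) == 1 &&
        all(c("cx_um", "cy_um") %in% names(p)))
      return(c(p$cx_um, p$cy_um))
    stop("centroid must be an (x, y) pair or a single ROI-table row")
  }
  p1 <- xy(before); p2 <- xy(after)
  data.frame(id = id, x1_um = p1[1], y1_um = p1[2],
             x2_um = p2[1], y2_um = p2[2],
             d_um = sqrt(sum((p1 - p2)^2)),
             elapsed_hours = elapsed_hours)
}

#' Migration records for all tracked spheroids of a field pair
#'
#' Builds one migration record per track returned by [track_rois()],
#' pairing each spheroid's centroid at the two timepoints.
#'
#' @param rois_t1,rois_t2 chamber-assigned ROI sets at the two timepoints.
#' @param tracks result of [track_rois()] on them (recomputed if `NULL`).
#' @param elapsed_hours assay interval, hours.
#' @return data.frame of migration records.
#' @export
migration_records <- function(rois_t1, rois_t2, tracks = NULL,
                              elapsed_hours = NA_real_) {
  if (is.null(tracks)) tracks <- track_rois(rois_t1, rois_t2)
  tr <- tracks$tracks
  if (!nrow(tr))
    return(migration_distance(c(0, 0), c(0, 0))[0, ])
  do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    r1 <- rois_t1$table[rois_t1$table$id == tr$id_t1[i], ]
    r2 <- rois_t2$table[rois_t2$table$id == tr$id_t2[i], ]
    migration_distance(r1, r2, elapsed_hours, id = tr$id_t1[i])
  }))
}

#' Summarize migration distances by condition
#'
#' Per-condition mean, SD and n of the migration distance, a fixed-width
#' histogram for distribution plots, and (for exactly two conditions) a
#' two-sided rank-sum comparison of the distance distributions.
#'
#' @param d_um migration distances, um.
#' @param condition condition label per record (single condition if omitted).
#' @param bin_width_um histogram bin width, um.
#' @return list with `summary` (data.frame: condition, n, mean, sd),
#'   `histograms` (per condition), and `test` (Wilcoxon rank-sum result, or
#'   `NULL` unless exactly two conditions).
#' @export
invasion_summary <- function(d_um, condition = rep("all", length(d_um)),
                             bin_width_um = 25) {
  if (!length(d_um)) stop("no migration records")
  condition <- as.character(condition)
  if (any(tapply(d_um, condition, length) < 1)) stop("empty condition")
  conds <- unique(condition)
  summ <- do.call(rbind, lapply(conds, function(cn) {
    v <- d_um[condition == cn]
    data.frame(condition = cn, n = length(v), mean_um = mean(v),
               sd_um = if (length(v) > 1) stats::sd(v) else 0)
  }))
  top <- max(d_um) + bin_width_um
  breaks <- seq(0, top, by = bin_width_um)
  hists <- lapply(conds, function(cn)
    graphics::hist(d_um[condition == cn], breaks = breaks, plot = FALSE))
  names(hists) <- conds
  test <- NULL
  if (length(conds) == 2) {
    a <- d_um[condition == conds[1]]
    b <- d_um[condition == conds[2]]
    if (identical(sort(a), sort(b))) {
      test <- list(method = "Wilcoxon rank sum", p_value = 1,
                   statistic = NA_real_)
    } else {
      wt <- stats::wilcox.test(a, b, exact = FALSE)
      test <- list(method = wt$method, p_value = wt$p.value,
                   statistic = unname(wt$statistic))
    }
  }
  list(summary = summ, histograms = hists, test = test)
}
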