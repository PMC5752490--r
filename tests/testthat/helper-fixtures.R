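# Shared fixtures. Simulations are cached per test run so several test
# files can reuse the same rendered fields without re-simulating.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .sim_cache)) assign(key, maker(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# rasterized disk mask (pixel-center convention)
disk_mask <- function(radius_px, size = 2 * radius_px + 11) {
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= radius_px^2)
}

# rasterized axis-aligned ellipse mask with semi-axes a, b (px)
ellipse_mask <- function(a_px, b_px, size = 2 * ceiling(max(a_px, b_px)) + 11) {
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) ((j - c0) / a_px)^2 + ((i - c0) / b_px)^2 <= 1)
}

# brute-force second-moment oracle: direct pixel summation in loop order
brute_sphericity <- function(mask) {
  n <- 0; sx <- 0; sy <- 0
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask)))
    if (mask[i, j]) { n <- n + 1; sx <- sx + j; sy <- sy + i }
  xb <- sx / n; yb <- sy / n
  mu20 <- 0; mu02 <- 0
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask)))
    if (mask[i, j]) { mu20 <- mu20 + (j - xb)^2; mu02 <- mu02 + (i - yb)^2 }
  n^2 / (2 * pi * (mu20 + mu02))
}

# a minimal chamber-assignable ROI table wrapped as a spheroid_roi_set
fake_roi_set <- function(cx_um, cy_um, id = seq_along(cx_um), mpp = 2) {
  n <- length(cx_um)
  structure(list(
    labels = matrix(0L, 1, 1),
    table = data.frame(id = id, n_px = rep(1L, n),
                       area_um2 = rep(1, n), cx_um = cx_um, cy_um = cy_um,
                       chamber_row = rep(NA_integer_, n),
                       chamber_col = rep(NA_integer_, n),
                       touches_border = rep(FALSE, n)),
    microns_per_pixel = mpp, field_id = "fake", channel = "bf",
    timepoint = 0), class = "spheroid_roi_set")
}

# standard 3x3 fully-occupied array used by several files
sim_3x3 <- function() cached("sim_3x3", function()
  simulate_array(sim_config(grid_rows = 3, grid_cols = 3, occupancy = 1,
                            rng_seed = 42)))

# segment + chamber-assign a bright-field plane of a simulation
seg_assigned <- function(sim, tp, ...) {
  assign_chambers(segment_field(get_plane(sim, "bf", tp), ...),
                  grid_geometry(sim$config))
}

# match segmented ROIs to truth rows of one timepoint via chamber indices
match_truth <- function(rois, truth, tp_index = 1) {
  tr <- truth[truth$t_index == tp_index, ]
  merge(rois$table, tr,
        by.x = c("chamber_row", "chamber_col"), by.y = c("row", "col"),
        suffixes = c("_seg", "_true"))
}
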