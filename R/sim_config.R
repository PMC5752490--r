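#' Fluorescence channel specification for the synthetic generator
#'
#' Describes how one fluorescence channel is rendered per spheroid. Three
#' signal models cover the staining patterns the pipeline quantifies:
#'
#' * `"fraction"` — a controllable fraction of the spheroid's pixels carries
#'   signal at `fg` above a `bg` background (apoptosis-marker-like, e.g.
#'   Annexin V). The per-spheroid true positive fraction is drawn from a
#'   normal distribution with mean `frac_mean`, sd `frac_sd`, clipped to
#'   \[0, 1\].
#' * `"graded"` — the whole spheroid carries one intensity drawn per spheroid
#'   from N(`intensity_mean`, `intensity_sd`) (receptor/NO-probe-like, e.g.
#'   ER or DAF-2 staining).
#' * `"ratio"` — as `"graded"` at the first timepoint; at the second timepoint
#'   the spheroid's intensity is multiplied by a per-spheroid factor drawn
#'   from N(`ratio_mean`, `ratio_sd`) truncated below at 0.1
#'   (membrane-potential-dye-like, e.g. TMRM at two timepoints).
#'
#' @param label channel label.
#' @param mode one of `"fraction"`, `"graded"`, `"ratio"`.
#' @param frac_mean,frac_sd mean and sd of the true positive-area fraction
#'   (`"fraction"` mode), on \[0, 1\].
#' @param fg foreground intensity added above background for positive pixels
#'   (`"fraction"` mode), arbitrary units.
#' @param intensity_mean,intensity_sd per-spheroid intensity distribution
#'   (`"graded"`/`"ratio"` modes), arbitrary units above background.
#' @param ratio_mean,ratio_sd per-spheroid multiplicative timepoint-2 factor
#'   (`"ratio"` mode).
#' @param bg background intensity, arbitrary units.
#' @param noise_sd additive Gaussian pixel noise sd, arbitrary units.
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(label, mode = c("fraction", "graded", "ratio"),
                         frac_mean = 0.5, frac_sd = 0.2, fg = 5000,
                         intensity_mean = 5000, intensity_sd = 1000,
                         ratio_mean = 1, ratio_sd = 0,
                         bg = 400, noise_sd = 120) {
  mode <- match.arg(mode)
  stopifnot(frac_mean >= 0, frac_mean <= 1, frac_sd >= 0,
            fg >= 0, bg >= 0, noise_sd >= 0)
  structure(list(label = as.character(label), mode = mode,
                 frac_mean = frac_mean, frac_sd = frac_sd, fg = fg,
                 intensity_mean = intensity_mean, intensity_sd = intensity_sd,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 bg = bg, noise_sd = noise_sd),
            class = "channel_spec")
}

#' Configuration of a synthetic microchamber-array acquisition
#'
#' Defines the statistical structure of a simulated spheroid population and
#' the geometry of the microchamber array it grows in. The defaults emulate
#' the 2-day breast-cancer spheroid populations the pipeline was designed for:
#' sectional areas of 4900 +/- 2450 um^2 and a control growth-ratio
#' population with mean 1.23 and SD 0.20 over a 24 h interval (so that the
#' mean +/- SD growth-ratio cutoffs fall at 1.43 and 1.03).
#'
#' `gr_components` is a mixture over growth-ratio subpopulations: a list of
#' `c(weight, mean, sd)` triplets with non-negative weights summing to 1.
#' A single component is the control condition; adding components with higher
#' or lower means plants high- and low-proliferating subgroups.
#'
#' @param grid_rows,grid_cols microchamber grid dimensions.
#' @param chamber_pitch center-to-center chamber spacing, microns.
#' @param microns_per_pixel pixel size, microns per pixel (> 0). Real
#'   acquisitions must supply this from their own calibration; there is no
#'   universal default beyond the one here, chosen so typical spheroids span
#'   ~40 px.
#' @param occupancy probability in \[0, 1\] that a chamber holds a spheroid.
#' @param area_mean,area_sd mean and sd of the day-2 sectional area, um^2.
#' @param area_min lower truncation of the sampled area, um^2; sampling is by
#'   rejection, so the realized mean exceeds `area_mean` slightly when
#'   `area_min` cuts into the distribution.
#' @param gr_components growth-ratio mixture, list of `c(weight, mean, sd)`.
#' @param axis_ratio_range range of the ellipse minor/major axis ratio,
#'   sampled uniformly per spheroid; `c(1, 1)` gives circular spheroids.
#' @param timepoints acquisition times, hours; areas grow geometrically by
#'   the spheroid's growth ratio between consecutive timepoints.
#' @param channel_specs list of [channel_spec()] objects.
#' @param displacement_scale Rayleigh scale sigma of per-spheroid displacement
#'   between the two timepoints of an invasion simulation, microns
#'   (displacement components are independent N(0, sigma^2), so the distance
#'   is Rayleigh(sigma) with mean sigma * sqrt(pi / 2)).
#' @param texture_sd sd of the bright-field interior texture, arbitrary
#'   units; higher values give rougher-looking spheroids.
#' @param bf_bg,bf_interior,bf_rim bright-field background, spheroid interior
#'   and rim intensities, arbitrary units (bright background, dark rim).
#' @param bf_noise_sd additive Gaussian noise sd on the bright-field plane.
#' @param rim_width_um width of the dark spheroid rim, microns.
#' @param cell_volume_pl mean single-cell volume used for ground-truth cell
#'   counts, picoliters.
#' @param rng_seed integer seed; identical configurations and seeds produce
#'   bit-identical images and truth tables.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_array()], [simulate_invasion()]
#' @export
sim_config <- function(grid_rows = 4, grid_cols = 5, chamber_pitch = 250,
                       microns_per_pixel = 2, occupancy = 0.9,
                       area_mean = 4900, area_sd = 2450, area_min = 350,
                       gr_components = list(c(1, 1.23, 0.20)),
                       axis_ratio_range = c(1, 1),
                       timepoints = c(48, 72),
                       channel_specs = list(),
                       displacement_scale = 0,
                       texture_sd = 1000,
                       bf_bg = 30000, bf_interior = 18000, bf_rim = 8000,
                       bf_noise_sd = 200, rim_width_um = 4,
                       cell_volume_pl = 1.69,
                       rng_seed = 1L) {
  if (occupancy < 0 || occupancy > 1) stop("'occupancy' must be in [0, 1]")
  if (area_mean <= 0) stop("'area_mean' must be > 0")
  if (microns_per_pixel <= 0) stop("'microns_per_pixel' must be > 0")
  if (grid_rows < 1 || grid_cols < 1) stop("grid must have >= 1 chamber")
  w <- vapply(gr_components, `[`, numeric(1), 1L)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("'gr_components' weights must be non-negative and sum to 1")
  if (length(axis_ratio_range) != 2 || any(axis_ratio_range <= 0) ||
      any(axis_ratio_range > 1) ||
      axis_ratio_range[1] > axis_ratio_range[2])
    stop("'axis_ratio_range' must be an increasing pair in (0, 1]")
  if (length(timepoints) < 1) stop("need at least one timepoint")
  for (cs in channel_specs)
    if (!inherits(cs, "channel_spec"))
      stop("'channel_specs' must be a list of channel_spec objects")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         chamber_pitch = chamber_pitch,
         microns_per_pixel = microns_per_pixel, occupancy = occupancy,
         area_mean = area_mean, area_sd = area_sd, area_min = area_min,
         gr_components = gr_components,
         axis_ratio_range = axis_ratio_range,
         timepoints = as.numeric(timepoints),
         channel_specs = channel_specs,
         displacement_scale = displacement_scale,
         texture_sd = texture_sd, bf_bg = bf_bg,
         bf_interior = bf_interior, bf_rim = bf_rim,
         bf_noise_sd = bf_noise_sd, rim_width_um = rim_width_um,
         cell_volume_pl = cell_volume_pl,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

#' Microchamber grid geometry of a configuration
#'
#' @param config a [sim_config()].
#' @return list with `pitch_um`, `rows`, `cols` and the field origin (um).
#' @export
grid_geometry <- function(config) {
  list(pitch_um = config$chamber_pitch,
       rows = config$grid_rows, cols = config$grid_cols,
       origin_x = 0, origin_y = 0)
}
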