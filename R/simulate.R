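# Synthetic microchamber-array generator. Spheroids are rendered as filled
# ellipses (dark rim + textured interior on the bright-field analog; uniform
# or partially-positive signal on fluorescence planes) with every sampled
# quantity recorded in a ground-truth table, so each downstream stage of the
# pipeline can be tested against known truth.

# All sampling goes through one RNG seeded from config$rng_seed; the caller's
# RNG state is left untouched.
with_sim_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# truncated-normal sampling by rejection (truncation mass is small in all
# configured uses, so rejection is cheap)
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  for (it in seq_len(1000)) {
    bad <- x < lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

# logical mask of an ellipse over the pixel lattice (pixel-center convention);
# returns linear indices into an nr x nc matrix
ellipse_pixels <- function(nr, nc, cx_um, cy_um, a_um, b_um, theta, mpp) {
  half_x <- abs(a_um * cos(theta)) + abs(b_um * sin(theta))
  half_y <- abs(a_um * sin(theta)) + abs(b_um * cos(theta))
  j0 <- max(1L, floor((cx_um - half_x) / mpp))
  j1 <- min(nc, ceiling((cx_um + half_x) / mpp) + 1L)
  i0 <- max(1L, floor((cy_um - half_y) / mpp))
  i1 <- min(nr, ceiling((cy_um + half_y) / mpp) + 1L)
  if (j0 > j1 || i0 > i1) return(integer(0))
  jj <- j0:j1; ii <- i0:i1
  x <- (rep(jj, each = length(ii)) - 0.5) * mpp - cx_um
  y <- (rep(ii, times = length(jj)) - 0.5) * mpp - cy_um
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  inside <- (u / a_um)^2 + (v / b_um)^2 <= 1
  idx <- rep((jj - 1L) * nr, each = length(ii)) + rep(ii, times = length(jj))
  idx[inside]
}

sample_gr <- function(components) {
  w <- vapply(components, `[`, numeric(1), 1L)
  k <- sample.int(length(components), 1L, prob = w)
  comp <- components[[k]]
  rnorm_trunc(1L, comp[2], comp[3], lower = 0.2)
}

# draw all per-spheroid quantities; chambers scanned row-major
sample_population <- function(config) {
  rows <- config$grid_rows; cols <- config$grid_cols
  recs <- list()
  id <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      if (stats::runif(1) >= config$occupancy) next
      id <- id + 1L
      area <- rnorm_trunc(1L, config$area_mean, config$area_sd,
                          lower = config$area_min)
      gr <- sample_gr(config$gr_components)
      q <- stats::runif(1, config$axis_ratio_range[1],
                        config$axis_ratio_range[2])
      theta <- stats::runif(1, 0, pi)
      jit <- 0.04 * config$chamber_pitch
      dx <- stats::runif(1, -jit, jit)
      dy <- stats::runif(1, -jit, jit)
      chan <- list()
      for (cs in config$channel_specs) {
        chan[[cs$label]] <- switch(cs$mode,
          fraction = list(frac = min(1, max(0, stats::rnorm(1, cs$frac_mean,
                                                            cs$frac_sd))),
                          fi = cs$fg, factor = NA_real_),
          graded = list(frac = 1,
                        fi = rnorm_trunc(1L, cs$intensity_mean,
                                         cs$intensity_sd, lower = 0),
                        factor = NA_real_),
          ratio = list(frac = 1,
                       fi = rnorm_trunc(1L, cs$intensity_mean,
                                        cs$intensity_sd, lower = 1),
                       factor = rnorm_trunc(1L, cs$ratio_mean, cs$ratio_sd,
                                            lower = 0.1)))
      }
      recs[[id]] <- list(id = id, row = r, col = cc,
                         cx = (cc - 0.5) * config$chamber_pitch + dx,
                         cy = (r - 0.5) * config$chamber_pitch + dy,
                         area = area, gr = gr, q = q, theta = theta,
                         chan = chan)
    }
  }
  recs
}

# semi-axes of a spheroid at growth scale s (area scales by s^2)
axes_at <- function(rec, s) {
  a <- sqrt(rec$area / (pi * rec$q)) * s
  c(a = a, b = a * rec$q)
}

render_brightfield <- function(config, recs, scales, nr, nc) {
  mpp <- config$microns_per_pixel
  img <- matrix(config$bf_bg, nr, nc)
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    ax <- axes_at(rec, scales[k])
    pix <- ellipse_pixels(nr, nc, rec$cx, rec$cy, ax["a"], ax["b"],
                          rec$theta, mpp)
    rim_w <- config$rim_width_um
    inner <- if (ax["a"] > rim_w && ax["b"] > rim_w)
      ellipse_pixels(nr, nc, rec$cx, rec$cy, ax["a"] - rim_w,
                     ax["b"] - rim_w, rec$theta, mpp) else integer(0)
    img[pix] <- config$bf_rim
    if (length(inner))
      img[inner] <- config$bf_interior +
        stats::rnorm(length(inner), 0, config$texture_sd)
  }
  img <- img + stats::rnorm(length(img), 0, config$bf_noise_sd)
  matrix(pmin(pmax(img, 0), 65535), nr, nc)
}

render_channel <- function(config, recs, scales, cs, tp_index, nr, nc) {
  mpp <- config$microns_per_pixel
  img <- matrix(cs$bg, nr, nc)
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    ax <- axes_at(rec, scales[k])
    pix <- ellipse_pixels(nr, nc, rec$cx, rec$cy, ax["a"], ax["b"],
                          rec$theta, mpp)
    if (!length(pix)) next
    ch <- rec$chan[[cs$label]]
    if (cs$mode == "fraction") {
      npos <- round(ch$frac * length(pix))
      if (npos > 0) {
        pos <- if (npos >= length(pix)) pix else sample(pix, npos)
        img[pos] <- cs$bg + cs$fg
      }
    } else {
      fi <- ch$fi
      if (cs$mode == "ratio" && tp_index > 1) fi <- fi * ch$factor
      img[pix] <- cs$bg + fi
    }
  }
  img <- img + stats::rnorm(length(img), 0, cs$noise_sd)
  matrix(pmin(pmax(img, 0), 65535), nr, nc)
}

truth_row <- function(config, rec, tp_index, tp, scale,
                      dx = 0, dy = 0, clipped = FALSE) {
  ax <- axes_at(rec, scale)
  area_t <- rec$area * scale^2
  row <- data.frame(id = rec$id, row = rec$row, col = rec$col,
                    t_index = tp_index, timepoint = tp,
                    cx_um = rec$cx, cy_um = rec$cy,
                    a_um = unname(ax["a"]), b_um = unname(ax["b"]),
                    theta = rec$theta, area_um2 = area_t, gr = rec$gr,
                    cell_count = cells_per_spheroid(area_t,
                                                    config$cell_volume_pl),
                    dx_um = dx, dy_um = dy, clipped = clipped,
                    stringsAsFactors = FALSE)
  for (cs in config$channel_specs) {
    ch <- rec$chan[[cs$label]]
    fi <- ch$fi
    if (cs$mode == "ratio" && tp_index > 1) fi <- fi * ch$factor
    row[[paste0("frac_", cs$label)]] <- ch$frac
    row[[paste0("fi_", cs$label)]] <- fi
    row[[paste0("factor_", cs$label)]] <-
      if (cs$mode == "ratio") ch$factor else NA_real_
  }
  row
}

empty_truth <- function(config) {
  truth_row(config,
            list(id = 1L, row = 1L, col = 1L, cx = 0, cy = 0, area = 1,
                 gr = 1, q = 1, theta = 0,
                 chan = lapply(stats::setNames(config$channel_specs,
                   vapply(config$channel_specs, `[[`, "", "label")),
                   function(cs) list(frac = 1, fi = 1, factor = NA_real_))),
            1L, 0, 1)[0, ]
}

check_fit <- function(config, recs, max_scale) {
  half <- config$chamber_pitch / 2
  margin <- 2 * config$microns_per_pixel
  for (rec in recs) {
    a_max <- sqrt(rec$area / (pi * rec$q)) * max_scale
    jit <- 0.04 * config$chamber_pitch
    if (a_max + jit + margin > half)
      stop(sprintf(paste0("chamber pitch %g um too small to contain a sampled",
                          " spheroid (max semi-axis %.1f um); increase",
                          " chamber_pitch or reduce area_mean/area_sd"),
                   config$chamber_pitch, a_max))
  }
  invisible(TRUE)
}

#' Simulate a multi-timepoint microchamber-array acquisition
#'
#' Generates one bright-field-analog plane plus one plane per fluorescence
#' channel at each configured timepoint, with at most one spheroid per
#' microchamber, and returns the full ground-truth table. Spheroid sectional
#' areas grow geometrically between consecutive timepoints by each spheroid's
#' growth ratio; spheroids never cross chamber boundaries (configurations in
#' which a sampled spheroid could not fit its chamber are rejected with a
#' sizing error).
#'
#' Identical configurations (including `rng_seed`) produce bit-identical
#' images and truth tables. Sampling order is fixed: chambers are scanned
#' row-major; for each occupied chamber the area, growth-ratio mixture
#' component and value, axis ratio, orientation, center jitter and then the
#' per-channel parameters are drawn; rendering noise is drawn afterwards,
#' plane by plane in timepoint-major, channel order.
#'
#' @param config a [sim_config()].
#' @return list with elements `images` (list of [field_image()] planes),
#'   `truth` (data.frame, one row per spheroid per timepoint, coordinates in
#'   microns from the field's top-left corner) and `config`.
#' @examples
#' sim <- simulate_array(sim_config(grid_rows = 2, grid_cols = 2,
#'                                  rng_seed = 7))
#' nrow(sim$truth)
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mpp <- config$microns_per_pixel
  nr <- round(config$grid_rows * config$chamber_pitch / mpp)
  nc <- round(config$grid_cols * config$chamber_pitch / mpp)
  ntp <- length(config$timepoints)
  with_sim_seed(config$rng_seed, {
    recs <- sample_population(config)
    scales <- function(rec) sqrt(rec$gr)^(seq_len(ntp) - 1)
    if (length(recs))
      check_fit(config, recs, max(vapply(recs, function(r)
        max(scales(r)), numeric(1))))
    images <- list()
    truth <- list()
    for (k in seq_len(ntp)) {
      tp <- config$timepoints[k]
      sc <- vapply(recs, function(r) scales(r)[k], numeric(1))
      images[[length(images) + 1L]] <- field_image(
        render_brightfield(config, recs, sc, nr, nc),
        "bf", tp, mpp)
      for (cs in config$channel_specs)
        images[[length(images) + 1L]] <- field_image(
          render_channel(config, recs, sc, cs, k, nr, nc),
          cs$label, tp, mpp)
      for (i in seq_along(recs))
        truth[[length(truth) + 1L]] <-
          truth_row(config, recs[[i]], k, tp, sc[i])
    }
    truth <- if (length(truth)) do.call(rbind, truth) else empty_truth(config)
    list(images = images, truth = truth, config = config)
  })
}

#' Simulate a two-timepoint collagen-invasion field
#'
#' Renders the same spheroid population at two timepoints with each spheroid
#' translated by a per-spheroid displacement whose x and y components are
#' independent N(0, `displacement_scale`^2) draws, so migration distances
#' follow a Rayleigh distribution with mean `displacement_scale * sqrt(pi/2)`.
#' Spheroids embedded in matrix are not confined by chamber walls, so no
#' chamber-fit check is applied; a displacement that would push a spheroid
#' outside the field is clipped to the field boundary and flagged in the
#' truth table. Spheroids may optionally flatten (axis-ratio multiplier
#' `flatten`) at the second timepoint, mimicking the shape change of
#' invading spheroids.
#'
#' @param config a [sim_config()] with `displacement_scale` set; the first
#'   two entries of `timepoints` define the assay interval (default 0 and
#'   18 h if only one is given).
#' @param flatten multiplier in (0, 1] applied to the axis ratio at the
#'   second timepoint.
#' @return As [simulate_array()]; the truth rows at the second timepoint
#'   carry the realized displacement (`dx_um`, `dy_um`) and `clipped` flag.
#' @export
simulate_invasion <- function(config, flatten = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (flatten <= 0 || flatten > 1) stop("'flatten' must be in (0, 1]")
  mpp <- config$microns_per_pixel
  nr <- round(config$grid_rows * config$chamber_pitch / mpp)
  nc <- round(config$grid_cols * config$chamber_pitch / mpp)
  tps <- if (length(config$timepoints) >= 2) config$timepoints[1:2]
         else c(0, 18)
  with_sim_seed(config$rng_seed, {
    recs <- sample_population(config)
    disp <- lapply(recs, function(r)
      stats::rnorm(2, 0, config$displacement_scale))
    images <- list()
    truth <- list()
    # timepoint 1: in place
    images[[1]] <- field_image(
      render_brightfield(config, recs, rep(1, length(recs)), nr, nc),
      "bf", tps[1], mpp)
    for (i in seq_along(recs))
      truth[[length(truth) + 1L]] <- truth_row(config, recs[[i]], 1L,
                                               tps[1], 1)
    # timepoint 2: translated (and optionally flattened)
    recs2 <- recs
    for (i in seq_along(recs2)) {
      rec <- recs2[[i]]
      rec$q <- rec$q * flatten
      a <- sqrt(rec$area / (pi * rec$q))
      cx <- rec$cx + disp[[i]][1]
      cy <- rec$cy + disp[[i]][2]
      clipped <- FALSE
      lim_x <- c(a, nc * mpp - a); lim_y <- c(a, nr * mpp - a)
      if (cx < lim_x[1] || cx > lim_x[2] ||
          cy < lim_y[1] || cy > lim_y[2]) {
        cx <- min(max(cx, lim_x[1]), lim_x[2])
        cy <- min(max(cy, lim_y[1]), lim_y[2])
        clipped <- TRUE
      }
      rec$clip <- clipped
      rec$dx <- cx - recs[[i]]$cx
      rec$dy <- cy - recs[[i]]$cy
      rec$cx <- cx; rec$cy <- cy
      recs2[[i]] <- rec
    }
    images[[2]] <- field_image(
      render_brightfield(config, recs2, rep(1, length(recs2)), nr, nc),
      "bf", tps[2], mpp)
    for (i in seq_along(recs2))
      truth[[length(truth) + 1L]] <-
        truth_row(config, recs2[[i]], 2L, tps[2],
                  1, dx = recs2[[i]]$dx, dy = recs2[[i]]$dy,
                  clipped = recs2[[i]]$clip)
    truth <- if (length(truth)) do.call(rbind, truth) else empty_truth(config)
    list(images = images, truth = truth, config = config)
  })
}
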