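# The generator is the ground-truth source for every other module, so its
# own statistical and geometric guarantees are tested first.

test_that("config validation rejects impossible populations", {
  expect_error(sim_config(occupancy = 1.2), "occupancy")
  expect_error(sim_config(area_mean = -5), "area_mean")
  expect_error(sim_config(gr_components = list(c(0.5, 1.2, 0.1))),
               "sum to 1")
  expect_error(sim_config(axis_ratio_range = c(0.8, 0.2)), "axis_ratio")
  # spheroids of ~4900 um^2 cannot fit a 60 um chamber
  expect_error(simulate_array(sim_config(chamber_pitch = 60, occupancy = 1,
                                         rng_seed = 1)),
               "too small")
})

test_that("occupancy endpoints give empty and full arrays", {
  empty <- simulate_array(sim_config(grid_rows = 3, grid_cols = 3,
                                     occupancy = 0, rng_seed = 1))
  expect_identical(nrow(empty$truth), 0L)
  bf <- get_plane(empty, "bf", 48)$pixels
  cfg <- empty$config
  # background-only plane: pure Gaussian noise around the background level
  expect_lt(abs(mean(bf) - cfg$bf_bg), 5 * cfg$bf_noise_sd)
  expect_lt(max(abs(bf - cfg$bf_bg)), 6 * cfg$bf_noise_sd)

  full <- sim_3x3()
  tr1 <- full$truth[full$truth$t_index == 1, ]
  expect_identical(nrow(tr1), 9L)
  expect_identical(nrow(unique(tr1[, c("row", "col")])), 9L)
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- sim_config(grid_rows = 2, grid_cols = 3, rng_seed = 77,
                    channel_specs = list(channel_spec("ann", "fraction")))
  a <- simulate_array(cfg)
  b <- simulate_array(cfg)
  expect_identical(a$truth, b$truth)
  for (k in seq_along(a$images))
    expect_identical(a$images[[k]]$pixels, b$images[[k]]$pixels)
  c <- simulate_array(sim_config(grid_rows = 2, grid_cols = 3, rng_seed = 78,
                                 channel_specs = list(
                                   channel_spec("ann", "fraction"))))
  expect_false(identical(a$truth, c$truth))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_array(sim_config(grid_rows = 2, grid_cols = 2,
                                      rng_seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("sampled population moments match the configured distributions", {
  sim <- cached("sim_big", function()
    simulate_array(sim_config(grid_rows = 15, grid_cols = 14, occupancy = 1,
                              chamber_pitch = 250, microns_per_pixel = 2,
                              rng_seed = 101)))
  tr1 <- sim$truth[sim$truth$t_index == 1, ]
  n <- nrow(tr1)
  expect_gte(n, 200)
  cfg <- sim$config
  # areas: within 3 SE of the configured mean (truncation at area_min shifts
  # the expectation by ~150 um^2, well inside the band)
  se_area <- cfg$area_sd / sqrt(n)
  expect_lt(abs(mean(tr1$area_um2) - cfg$area_mean), 3 * se_area + 160)
  expect_lt(abs(stats::sd(tr1$area_um2) - cfg$area_sd),
            3 * cfg$area_sd / sqrt(2 * n) + 100)
  # growth ratios
  comp <- cfg$gr_components[[1]]
  se_gr <- comp[3] / sqrt(n)
  expect_lt(abs(mean(tr1$gr) - comp[2]), 3 * se_gr)
  # truth GR is exactly the area ratio
  tr2 <- sim$truth[sim$truth$t_index == 2, ]
  expect_equal(tr2$area_um2 / tr1$area_um2, tr1$gr, tolerance = 1e-12)
})

test_that("rendered foreground geometry matches truth areas within 2%", {
  sim <- sim_3x3()
  cfg <- sim$config
  bf <- get_plane(sim, "bf", 48)$pixels
  tr <- sim$truth[sim$truth$t_index == 1, ]
  for (i in seq_len(nrow(tr))) {
    npix <- length(spheroquant:::ellipse_pixels(
      nrow(bf), ncol(bf), tr$cx_um[i], tr$cy_um[i],
      tr$a_um[i], tr$b_um[i], tr$theta[i], cfg$microns_per_pixel))
    expect_gte(tr$b_um[i] / cfg$microns_per_pixel, 10) # radii >= 10 px here
    expect_lt(abs(npix * cfg$microns_per_pixel^2 - tr$area_um2[i]) /
                tr$area_um2[i], 0.02)
  }
})

test_that("invasion mode plants Rayleigh displacements with known moments", {
  # zero scale: nobody moves
  still <- simulate_invasion(sim_config(grid_rows = 2, grid_cols = 2,
                                        displacement_scale = 0,
                                        rng_seed = 8))
  t2 <- still$truth[still$truth$t_index == 2, ]
  expect_true(all(t2$dx_um == 0 & t2$dy_um == 0))

  # Rayleigh scale sigma: mean distance sigma * sqrt(pi/2), closed form
  sigma <- 316
  sim <- simulate_invasion(sim_config(grid_rows = 15, grid_cols = 14,
                                      occupancy = 1, chamber_pitch = 2000,
                                      microns_per_pixel = 16,
                                      displacement_scale = sigma,
                                      rng_seed = 9))
  t2 <- sim$truth[sim$truth$t_index == 2, ]
  d <- sqrt(t2$dx_um^2 + t2$dy_um^2)
  ok <- !t2$clipped
  expect_gt(mean(ok), 0.95) # clipping is rare on a field this large
  n <- sum(ok)
  ray_mean <- sigma * sqrt(pi / 2)
  ray_sd <- sigma * sqrt((4 - pi) / 2)
  expect_lt(abs(mean(d[ok]) - ray_mean), 3 * ray_sd / sqrt(n))
})

test_that("displacements that leave the field are clipped and flagged", {
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, chamber_pitch = 250,
                    displacement_scale = 400, rng_seed = 21)
  sim <- simulate_invasion(cfg)
  t2 <- sim$truth[sim$truth$t_index == 2, ]
  expect_true(any(t2$clipped))
  mpp <- cfg$microns_per_pixel
  lim_x <- 2 * 250 # field extent, um
  expect_true(all(t2$cx_um >= t2$a_um - 1e-9 &
                  t2$cx_um <= lim_x - t2$a_um + 1e-9))
})

test_that("truth tables round-trip losslessly through CSV", {
  sim <- simulate_array(sim_config(
    grid_rows = 3, grid_cols = 3, occupancy = 1, rng_seed = 4,
    channel_specs = list(channel_spec("ann", "fraction"),
                         channel_spec("tmrm", "ratio", ratio_mean = 1.7,
                                      ratio_sd = 0.5))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_identical(nrow(back), 9L * 2L)
  expect_equal(back, sim$truth, tolerance = 0) # exact, incl. doubles

  empty <- sim$truth[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_truth(empty, path2)
  expect_identical(readLines(path2),
                   paste(names(empty), collapse = ","))
})

test_that("image stacks round-trip through 16-bit TIFF plus sidecar", {
  sim <- sim_3x3()
  dir <- withr::local_tempdir()
  write_field_images(sim, dir)
  back <- read_field_images(dir)
  expect_identical(length(back$images), length(sim$images))
  expect_equal(back$meta$microns_per_pixel, sim$config$microns_per_pixel)
  for (k in seq_along(sim$images)) {
    expect_identical(back$images[[k]]$channel, sim$images[[k]]$channel)
    expect_lt(max(abs(back$images[[k]]$pixels - round(sim$images[[k]]$pixels))),
              0.51) # 16-bit quantization only
  }
})
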