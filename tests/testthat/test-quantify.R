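# Fixture: a 3x3 array with one channel of each signal model, reused across
# the quantification tests.
quant_sim <- function() cached("sim_quant", function()
  simulate_array(sim_config(
    grid_rows = 3, grid_cols = 3, occupancy = 1, rng_seed = 31,
    channel_specs = list(
      channel_spec("ann", "fraction", frac_mean = 0.558, frac_sd = 0,
                   fg = 5000, bg = 400, noise_sd = 120),
      channel_spec("tmrm", "ratio", intensity_mean = 5000,
                   intensity_sd = 800, ratio_mean = 1.72, ratio_sd = 0,
                   bg = 400, noise_sd = 120)))))

test_that("background estimation uses only inter-ROI pixels", {
  # no ROIs: whole-field mean
  img <- field_image(matrix(c(10, 20, 30, 40), 2, 2), "fluor", 0, 2)
  expect_equal(estimate_background(img)$mean, 25)
  # constant field with one ROI: still the constant
  flat <- field_image(matrix(7, 50, 50), "fluor", 0, 2)
  set <- fake_roi_set(10, 10)
  set$labels <- matrix(0L, 50, 50); set$labels[1:10, 1:10] <- 1L
  expect_equal(estimate_background(flat, set)$mean, 7)
  # ROIs covering everything leave no background
  set$labels[] <- 1L
  expect_error(estimate_background(flat, set), "entire field")
  # CLT bound on a synthetic plane with known background and noise
  sim <- quant_sim()
  rois <- seg_assigned(sim, 48)
  ann <- get_plane(sim, "ann", 48)
  bg <- estimate_background(ann, rois)
  expect_gt(bg$n_pixels, 1e4)
  expect_lt(abs(bg$mean - 400), 3 * 120 / sqrt(bg$n_pixels) + 0.5)
  # (+0.5 allows for clipping of rare negative noise excursions at 0)
})

test_that("per-ROI metrics follow their definitions on constructed ROIs", {
  px <- matrix(0, 20, 20)
  px[5:10, 5:10] <- 80
  mask <- px > 0
  m <- measure_roi(px, mask, background = 0, threshold = 50)
  expect_equal(m$mean_fi, 80)
  expect_equal(m$area_fraction, 100)
  expect_equal(m$pixel_cv, 0)
  # all pixels below threshold
  m2 <- measure_roi(px, mask, background = 0, threshold = 100)
  expect_equal(m2$mean_fi, 0)
  expect_equal(m2$area_fraction, 0)
  # empty mask is an error
  expect_error(measure_roi(px, matrix(FALSE, 20, 20)), "empty ROI")
})

test_that("planted positive-area fractions are recovered", {
  sim <- quant_sim()
  rois <- seg_assigned(sim, 48)
  q <- quantify_rois(get_plane(sim, "ann", 48), rois)
  expect_identical(nrow(q), 9L)
  # every spheroid was planted with a 55.8% positive fraction
  expect_true(all(abs(q$area_fraction - 55.8) <= 2))
})

test_that("metrics are invariant to a constant plane offset", {
  sim <- quant_sim()
  rois <- seg_assigned(sim, 48)
  ann <- get_plane(sim, "ann", 48)
  q1 <- quantify_rois(ann, rois)
  shifted <- field_image(ann$pixels + 500, ann$channel, ann$timepoint,
                         ann$microns_per_pixel, ann$field_id)
  q2 <- quantify_rois(shifted, rois)
  expect_equal(q2$mean_fi, q1$mean_fi, tolerance = 1e-10)
  expect_equal(q2$area_fraction, q1$area_fraction, tolerance = 1e-10)
  expect_equal(q2$pixel_cv, q1$pixel_cv, tolerance = 1e-10)
})

test_that("area fraction is monotone non-increasing in the threshold", {
  sim <- quant_sim()
  rois <- seg_assigned(sim, 48)
  ann <- get_plane(sim, "ann", 48)
  bg <- estimate_background(ann, rois)
  idx <- roi_indices(rois, 1)
  fracs <- vapply(seq(0, 6000, by = 500), function(th)
    measure_roi(ann, idx, bg$mean, th)$area_fraction, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("two-timepoint intensity ratios recover planted factors", {
  # identities
  expect_equal(tmrm_ratio(5, 5)$ratio, 1)
  expect_equal(tmrm_ratio(5, 10)$ratio, 2)
  expect_false(tmrm_ratio(0, 10)$defined)
  # a plane multiplied by k between timepoints gives exactly k at zero bg
  px <- matrix(200, 30, 30); mask <- disk_mask(8, 30)
  f1 <- measure_roi(px, mask, 0, 0)$mean_fi
  f2 <- measure_roi(px * 3, mask, 0, 0)$mean_fi
  expect_equal(tmrm_ratio(f1, f2)$ratio, 3, tolerance = 1e-12)
  # planted multiplicative factor 1.72 on the synthetic TMRM channel
  sim <- quant_sim()
  r1 <- seg_assigned(sim, 48)
  r2 <- seg_assigned(sim, 72)
  tracks <- track_rois(r1, r2)
  q1 <- quantify_rois(get_plane(sim, "tmrm", 48), r1, threshold = 0)
  q2 <- quantify_rois(get_plane(sim, "tmrm", 72), r2, threshold = 0)
  i1 <- match(tracks$tracks$id_t1, q1$id)
  i2 <- match(tracks$tracks$id_t2, q2$id)
  rat <- tmrm_ratio(q1$mean_fi[i1], q2$mean_fi[i2])
  expect_true(all(rat$defined))
  expect_lt(abs(mean(rat$ratio) - 1.72), 0.05)
})

test_that("cutoff rules reproduce closed forms and sampled references", {
  r <- make_cutoff(c(1, 1, 1))
  expect_equal(c(r$lower, r$upper), c(1, 1))
  r2 <- make_cutoff(c(0, 2))
  expect_equal(r2$upper, 1 + sqrt(2))
  expect_equal(r2$lower, 1 - sqrt(2))
  expect_error(make_cutoff(3), "at least 2")
  # control population with mean 1.23, SD 0.20 (n = 400): cutoffs land near
  # 1.43 / 1.03 within sampling error of mean +/- SD
  set.seed(400)
  ctrl <- rnorm(400, 1.23, 0.20)
  rule <- make_cutoff(ctrl)
  se_upper <- 0.20 * sqrt(1 / 400 + 1 / (2 * 399))
  expect_lt(abs(rule$upper - 1.43), 3 * se_upper)
  expect_lt(abs(rule$lower - 1.03), 3 * se_upper)
})

test_that("positivity classification is strict and recovers planted mixtures", {
  rule <- make_cutoff(c(0.8, 1.0, 1.2))
  expect_false(classify_positive(rule$upper, rule))    # boundary: negative
  expect_true(classify_positive(rule$upper + 1e-9, rule))
  # planted mixture: 79% of spheroids well above the cutoff
  set.seed(79)
  n <- 400; n_pos <- round(0.79 * n)
  values <- c(rule$upper + abs(rnorm(n_pos, 2, 0.5)),
              rule$lower + runif(n - n_pos, 0, rule$sd))
  frac <- mean(classify_positive(values, rule))
  expect_lt(abs(frac - 0.79), 3 * sqrt(0.79 * 0.21 / n))
})

test_that("z-stack staining homogeneity QC computes the per-plane CV", {
  expect_equal(staining_homogeneity(c(5, 5, 5))$cv, 0)
  expect_true(staining_homogeneity(c(5, 5, 5))$pass)
  h <- staining_homogeneity(c(1, 3))
  expect_equal(h$cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_false(h$pass)
  expect_error(staining_homogeneity(5), "2 focal planes")
  # multiplicative per-plane jitter of 5% gives CV ~ 0.05: passes at 0.08
  set.seed(12)
  planes <- 1000 * rnorm(12, 1, 0.05)
  expect_true(staining_homogeneity(planes)$pass)
})
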