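test_that("config validation names the offending field", {
  expect_error(scene_config(0, 40, 5), "width")
  expect_error(scene_config(40, 40, 1), "n_frames")
  expect_error(scene_config(40, 40, 5, noise_sd = -1), "noise_sd")
  # separability: base colors too close for the noise level
  bc <- rbind(c(10, 10, 10), c(12, 12, 12), c(200, 200, 200))
  expect_error(scene_config(40, 40, 5, base_colors = bc, noise_sd = 5),
               "base_colors")
  expect_error(polyp_config(c(5, 5), 0, 10), "radius")
  expect_error(polyp_config(c(5, 5), 3, 1), "oscillation_period")
  # change_day beyond the series span
  p <- polyp_config(c(20, 20), 4, 10, change_day = 99)
  expect_error(scene_config(40, 40, 5, minutes_per_frame = 60,
                            polyps = list(p)), "change_day")
})

test_that("degenerate flat schedule with no noise gives identical frames", {
  g <- generate_series(clean_scene(n_frames = 4))
  for (t in 2:4)
    expect_identical(g$series$pixels[[t]], g$series$pixels[[1]])
  expect_true(all(g$ground_truth$fractions ==
                    matrix(c(0.5, 0.3, 0.2), 4, 3, byrow = TRUE)))
})

test_that("planted shares are rendered exactly (largest-remainder allocation)", {
  g <- generate_series(clean_scene(n_frames = 2, trip = c(0.5, 0.3, 0.2)))
  mask <- g$ground_truth$roi_mask
  n_roi <- sum(mask)
  px <- g$series$pixels[[1]]
  bc <- default_base_colors()
  counts <- sapply(1:3, function(k) {
    sum(px[, , 1][mask] == bc[k, 1] & px[, , 2][mask] == bc[k, 2] &
          px[, , 3][mask] == bc[k, 3])
  })
  expect_equal(sum(counts), n_roi)            # every ROI pixel is a base color
  expect_true(all(abs(counts - c(0.5, 0.3, 0.2) * n_roi) <= 1))
})

test_that("seed contract: different seeds differ pixelwise, same ground truth", {
  g1 <- generate_series(clean_scene(seed = 1))
  g2 <- generate_series(clean_scene(seed = 2))
  expect_false(identical(g1$series$pixels[[1]], g2$series$pixels[[1]]))
  expect_identical(g1$ground_truth$fractions, g2$ground_truth$fractions)
  expect_identical(g1$ground_truth$stage, g2$ground_truth$stage)
  # fixed seed: bit-identical series
  g1b <- generate_series(clean_scene(seed = 1))
  expect_identical(g1$series$pixels, g1b$series$pixels)
})

test_that("noise level does not change ground truth", {
  g0 <- generate_series(clean_scene(seed = 5, noise_sd = 0))
  g1 <- generate_series(clean_scene(seed = 5, noise_sd = 6))
  expect_identical(g0$ground_truth$fractions, g1$ground_truth$fractions)
  expect_identical(g0$ground_truth$change_days, g1$ground_truth$change_days)
})

test_that("rendered shares track a time-varying schedule within 1 pixel", {
  sc <- scene_config(48, 48, 12, minutes_per_frame = 12 * 60,
                     schedule = stage_schedule(c(1, 2, 3, 4),
                                               default_shade_fractions(), 0.5),
                     blue_cast_gain = c(1, 1, 1), brightness_drift = 0,
                     noise_sd = 0, seed = 11)
  g <- generate_series(sc)
  mask <- g$ground_truth$roi_mask
  bc <- default_base_colors()
  n_roi <- sum(mask)
  for (t in c(1, 4, 8, 12)) {
    px <- g$series$pixels[[t]]
    counts <- sapply(1:3, function(k)
      sum(px[, , 1][mask] == bc[k, 1] & px[, , 2][mask] == bc[k, 2] &
            px[, , 3][mask] == bc[k, 3]))
    expect_true(all(abs(counts / n_roi - g$ground_truth$fractions[t, ]) <=
                      1 / n_roi + 1e-12),
                info = paste("frame", t))
  }
})

test_that("polyp dynamics: oscillation before the change day, drift after", {
  p <- polyp_config(c(24, 24), 8, oscillation_period = 10,
                    oscillation_amplitude = 0.4, change_day = 5,
                    post_change_drift = 5)
  sc <- scene_config(48, 48, 240, minutes_per_frame = 60, noise_sd = 0,
                     schedule = flat_schedule(), blue_cast_gain = c(1, 1, 1),
                     brightness_drift = 0, polyps = list(p), seed = 3)
  g <- generate_series(sc)
  roi <- roi_rect("p", 13, 13, 35, 35)
  cs <- correlation_series(g$series, roi)
  pre <- cs$r[cs$days < 5]
  # quasi-periodic: autocorrelation of the pre-change r series peaks at the lag
  # equal to the oscillation period (10 frames)
  ac <- stats::acf(pre, lag.max = 15, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[5:15]) + 4L, 10L)
  # post-change drift decorrelates from the reference
  expect_gt(mean(pre), mean(cs$r[cs$days >= 6]))
})

test_that("ground-truth writer emits valid JSON", {
  g <- generate_series(clean_scene(n_frames = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(g$ground_truth, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(dim(x$fractions), c(2, 3))
  expect_equal(x$boundaries, c(10, 20, 30, 40))
})
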