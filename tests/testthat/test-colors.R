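test_that("noiseless planted mixture is recovered exactly", {
  g <- generate_series(clean_scene(n_frames = 2, trip = c(0.5, 0.3, 0.2)))
  mask <- g$ground_truth$roi_mask
  dc <- extract_dominant_colors(g$series$pixels[[1]], mask, seed = 9)
  expect_equal(unname(dc$colors), unname(default_base_colors()))
  n_roi <- sum(mask)
  expect_true(all(abs(dc$percentages - c(50, 30, 20)) <= 100 / n_roi))
  expect_equal(sum(dc$percentages), 100, tolerance = 1e-6)
  expect_equal(dc$shade_labels, c("dark", "medium", "light"))
})

test_that("degenerate ROIs warn and merge", {
  px <- array(100, dim = c(6, 6, 3))
  mask <- matrix(TRUE, 6, 6)
  expect_warning(dc <- extract_dominant_colors(px, mask), "degenerate")
  expect_equal(nrow(dc$colors), 1)
  expect_equal(dc$percentages, 100)
  expect_error(extract_dominant_colors(px, matrix(FALSE, 6, 6)), "empty ROI")
})

test_that("extraction is invariant to pixel order", {
  set.seed(33)
  px <- array(sample(0:255, 14 * 14 * 3, replace = TRUE), dim = c(14, 14, 3))
  mask <- matrix(TRUE, 14, 14)
  dc1 <- extract_dominant_colors(px, mask, seed = 5)
  # permute pixels spatially (a pure relabeling of locations)
  perm <- sample(196)
  px2 <- px
  for (ch in 1:3) px2[, , ch] <- matrix(px[, , ch][perm], 14, 14)
  dc2 <- extract_dominant_colors(px2, mask, seed = 5)
  expect_equal(dc1$colors, dc2$colors)
  expect_equal(dc1$percentages, dc2$percentages)
})

test_that("label_shades ranks by luminance with deterministic ties", {
  expect_equal(label_shades(rbind(c(20, 20, 20), c(120, 120, 120),
                                  c(230, 230, 230))),
               c("dark", "medium", "light"))
  # ties: same luminance, break by G then R then B
  a <- c(100, 100, 100)
  expect_equal(label_shades(rbind(a, a, c(0, 0, 0))),
               c("medium", "light", "dark"))
  # random triplets match an exhaustive sort oracle
  set.seed(12)
  for (i in 1:50) {
    cols <- matrix(runif(9, 0, 255), 3)
    lum <- cols %*% c(0.2126, 0.7152, 0.0722)
    o <- order(lum, cols[, 2], cols[, 1], cols[, 3])
    want <- character(3); want[o] <- c("dark", "medium", "light")
    expect_equal(label_shades(cols), want)
  }
})

test_that("smoothing matches a direct truncated moving average and renormalizes", {
  pct <- cbind(c(rep(60, 5), rep(20, 5)), c(rep(30, 5), rep(50, 5)),
               c(rep(10, 5), rep(30, 5)))
  sm <- smooth_percentages(pct, 3)
  for (ch in 1:3) {
    direct <- oracle_moving_average(pct[, ch], 3)
    # rows already sum to 100 so renormalization is a no-op here
    expect_equal(sm[, ch], direct, tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(sm) - 100) < 1e-9))
  # window 1 = identity; constant series unchanged
  expect_equal(smooth_percentages(pct, 1), pct)
  const <- matrix(rep(c(40, 40, 20), each = 6), ncol = 3)
  expect_equal(smooth_percentages(const, 5), const)
  expect_error(smooth_percentages(pct, 4), "window")
  expect_error(smooth_percentages(pct, 99), "window")
})

test_that("DP segmentation equals exhaustive search for 2 breakpoints", {
  set.seed(8)
  x <- seq(0, 29)
  y1 <- c(seq(50, 40, length.out = 10), seq(40, 60, length.out = 10),
          seq(60, 45, length.out = 10)) + rnorm(30, 0, 0.8)
  y2 <- 100 - y1 - 20
  Y <- cbind(y1, y2, rep(20, 30))
  dcs <- structure(list(days = x, percentages = Y,
                        smoothing = list(method = "none")),
                   class = "dominant_color_series")
  seg <- detect_stage_boundaries(dcs, n_boundaries = 2, min_seg = 3)
  oracle <- oracle_best_2breaks(x, Y, min_seg = 3)
  want_days <- (x[oracle$cuts] + x[oracle$cuts + 1]) / 2
  expect_equal(seg$boundaries, want_days)
  expect_equal(seg$sse, oracle$sse, tolerance = 1e-9)
})

test_that("perfectly linear series is flagged as having no strong inflections", {
  x <- seq(0, 49)
  Y <- cbind(50 - 0.2 * x, 30 + 0.1 * x, 20 + 0.1 * x)
  dcs <- structure(list(days = x, percentages = Y,
                        smoothing = list(method = "none")),
                   class = "dominant_color_series")
  seg <- detect_stage_boundaries(dcs, n_boundaries = 4)
  expect_true(seg$no_strong_inflections)
  expect_lt(seg$improvement, 0.25)
  expect_length(seg$boundaries, 4)
  expect_false(is.unsorted(seg$boundaries, strictly = TRUE))
})

test_that("ternary trajectory projects to the simplex and finds the center", {
  const <- matrix(rep(c(40, 40, 20), each = 8), ncol = 3)
  dcs <- structure(list(days = 0:7, percentages = const,
                        smoothing = list(method = "none")),
                   class = "dominant_color_series")
  seg <- structure(list(boundaries = c(1.5, 3.5, 4.5, 5.5),
                        stages = data.frame(stage = 1:5,
                                            start_day = c(0, 2, 4, 5, 6),
                                            end_day = c(1, 3, 4, 5, 7))),
                   class = "stage_segmentation")
  tr <- ternary_trajectory(dcs, seg)
  expect_true(all(abs(rowSums(tr$points) - 100) < 1e-9))
  expect_equal(max(dist(tr$xy)), 0)
  expect_equal(unname(tr$convergence_center), c(40, 40, 20))
  expect_error(ternary_trajectory(dcs, center = TRUE), "segmentation")
})

test_that("percentages sum to 100 across the full color pipeline", {
  g <- generate_series(clean_scene(n_frames = 4, noise_sd = 3))
  dcs <- dominant_color_series(g$series, g$ground_truth$roi_mask, seed = 2)
  expect_true(all(abs(rowSums(dcs$percentages) - 100) < 1e-6))
  sm <- smooth_percentages(dcs, 3)
  expect_true(all(abs(rowSums(sm$percentages) - 100) < 1e-6))
})
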