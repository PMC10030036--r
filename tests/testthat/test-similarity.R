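test_that("pearson_correlation: identity, affine invariance, formula oracle", {
  set.seed(14)
  px <- gradient_frame(6, 6)
  mask <- matrix(TRUE, 6, 6)
  expect_equal(pearson_correlation(px, px, mask), 1)
  # positive/negative affine transforms of the current frame
  for (i in 1:10) {
    a <- runif(1, 0.2, 1.5) * sample(c(-1, 1), 1)
    b <- runif(1, -20, 20)
    cur <- px
    cur[, , 2] <- pmin(255, pmax(0, a * px[, , 2] + b))
    # avoid clipping distorting the affine map
    if (any(cur[, , 2] %in% c(0, 255))) next
    expect_equal(pearson_correlation(px, cur, mask), sign(a),
                 tolerance = 1e-12)
  }
  # 3x3 hand-written patches vs the scalar formula oracle
  for (i in 1:20) {
    p1 <- array(sample(0:255, 27, replace = TRUE), dim = c(3, 3, 3))
    p2 <- array(sample(0:255, 27, replace = TRUE), dim = c(3, 3, 3))
    m3 <- matrix(TRUE, 3, 3)
    want <- oracle_pearson(as.numeric(p1[, , 2]), as.numeric(p2[, , 2]))
    expect_equal(pearson_correlation(p1, p2, m3, "G"), want,
                 tolerance = 1e-12)
  }
})

test_that("pearson errors on zero variance and shape mismatch", {
  flat <- array(7, dim = c(4, 4, 3))
  varying <- gradient_frame(4, 4)
  m <- matrix(TRUE, 4, 4)
  expect_error(pearson_correlation(flat, varying, m), "zero intensity variance")
  expect_error(pearson_correlation(varying, gradient_frame(5, 5), m), "shape")
  expect_error(pearson_correlation(varying, varying, m, channel = "X"), "channel")
})

test_that("correlation_series: reference r = 1, static scene stays at 1", {
  p <- polyp_config(c(24, 24), 8, oscillation_period = 12,
                    oscillation_amplitude = 0)  # static polyp, no change
  sc <- scene_config(48, 48, 20, minutes_per_frame = 60, noise_sd = 0,
                     schedule = flat_schedule(), blue_cast_gain = c(1, 1, 1),
                     brightness_drift = 0, polyps = list(p), seed = 2)
  g <- generate_series(sc)
  cs <- correlation_series(g$series, roi_rect("p", 14, 14, 34, 34))
  expect_equal(cs$r[1], 1)
  expect_true(all(cs$r > 0.999999))
  expect_equal(cs$normalization, "zscore_roi")
  # frame index is attached to propagated errors
  flat <- image_series(list(array(5, c(4, 4, 3)), array(5, c(4, 4, 3))))
  expect_error(correlation_series(flat, matrix(TRUE, 4, 4)), "frame 1")
})

test_that("global brightness drift barely shifts the correlation series", {
  p <- test_polyp(change_day = 5, period = 12, center = c(24, 24), radius = 8)
  mk <- function(drift, seed) {
    sc <- scene_config(48, 48, 240, minutes_per_frame = 60, noise_sd = 0,
                       schedule = flat_schedule(),
                       blue_cast_gain = c(1, 1, 1),
                       brightness_drift = drift, polyps = list(p), seed = seed)
    correlation_series(generate_series(sc)$series,
                       roi_rect("p", 14, 14, 34, 34))
  }
  cs0 <- mk(0, 7); cs1 <- mk(0.15, 7)
  d0 <- detect_change_point(cs0, window = 24)
  d1 <- detect_change_point(cs1, window = 24)
  expect_lte(abs(d0$day - d1$day), 1)
})

test_that("intensity_plot counts are exact and diagonal for identical frames", {
  px <- gradient_frame(8, 8)
  m <- matrix(TRUE, 8, 8)
  h <- intensity_plot(px, px, m, bins = 64)
  expect_equal(sum(h$joint_counts), 64)           # ROI pixel count
  expect_equal(sum(diag(h$joint_counts)), 64)     # all mass on the diagonal
  expect_equal(h$marginals$ref, rowSums(h$joint_counts))
  expect_equal(h$marginals$cur, colSums(h$joint_counts))
  expect_error(intensity_plot(px, px, m, bins = 1), "bins")

  # hand-built 4-pixel ROI: enumerable counts
  p1 <- array(0, dim = c(2, 2, 3)); p2 <- p1
  p1[, , 2] <- c(0, 0, 128, 128)   # column-major: (1,1),(2,1),(1,2),(2,2)
  p2[, , 2] <- c(0, 128, 0, 128)
  h2 <- intensity_plot(p1, p2, matrix(TRUE, 2, 2), bins = 2)
  expect_equal(unname(h2$joint_counts), rbind(c(1, 1), c(1, 1)))
})

test_that("independent noise gives no intensity association", {
  # chi-square independence on the joint histogram of iid uniform images:
  # not significant at alpha = 0.01 in at least 18/20 seeds
  n_ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    a <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), dim = c(40, 40, 3))
    b <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), dim = c(40, 40, 3))
    h <- intensity_plot(a, b, matrix(TRUE, 40, 40), bins = 4)
    p <- suppressWarnings(stats::chisq.test(h$joint_counts))$p.value
    if (p > 0.01) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 18)
})

test_that("change-point scan finds steps and flags flat/gentle series", {
  days <- (0:99) / 10
  step <- structure(list(r = c(rep(1, 50), rep(0.2, 50)), days = days,
                         reference_index = 1L, roi_name = NULL, channel = "G",
                         normalization = "zscore_roi"),
                    class = "correlation_series")
  cp <- detect_change_point(step, window = 10)
  expect_equal(cp$index, 51)
  expect_equal(cp$magnitude, 0.8, tolerance = 1e-12)
  expect_false(cp$no_change)

  const <- step; const$r <- rep(0.9, 100)
  cc <- detect_change_point(const, window = 10)
  expect_equal(cc$magnitude, 0)
  expect_true(cc$no_change)

  # gentle monotone ramp: drop well below the step-equivalent magnitude
  ramp <- step; ramp$r <- seq(1, 0.2, length.out = 100)
  cr <- detect_change_point(ramp, window = 10)
  expect_lt(cr$magnitude, 0.8 / 4)
  expect_error(detect_change_point(step, window = 200), "window")
})
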