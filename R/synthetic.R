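#' Polyp dynamics configuration
#'
#' A polyp is rendered as a disk whose radius and brightness oscillate
#' sinusoidally (quasi-periodic regime) until `change_day`, after which both
#' follow reflected Gaussian random walks and a per-pixel texture field
#' drifts (nonstationary regime). This reproduces the two regimes seen in
#' real polyp correlation series: near-periodic recurrence before a drastic
#' morphology change, drifting non-recurrent behavior after it.
#'
#' @param center `(row, col)` disk center in pixels
#' @param radius disk radius in pixels, `> 0`
#' @param oscillation_period oscillation period in frames, `>= 2`
#' @param oscillation_amplitude radius modulation as a fraction of `radius`,
#'   in `[0, 1]`
#' @param change_day day of the drastic morphology change
#' @param post_change_drift random-walk step (intensity units / frame)
#' @param color RGB triplet of the polyp body
#' @return an object of class `polyp_config`
#' @export
polyp_config <- function(center, radius, oscillation_period,
                         oscillation_amplitude = 0.3, change_day = Inf,
                         post_change_drift = 3, color = c(150, 140, 110)) {
  if (length(center) != 2L || any(!is.finite(center)))
    .fail_field("center", "need finite (row, col)")
  if (!.is_num1(radius) || radius <= 0) .fail_field("radius", "must be > 0")
  if (!.is_num1(oscillation_period) || oscillation_period < 2)
    .fail_field("oscillation_period", "must be >= 2 frames")
  if (!.is_num1(oscillation_amplitude) ||
      oscillation_amplitude < 0 || oscillation_amplitude > 1)
    .fail_field("oscillation_amplitude", "must be in [0, 1]")
  if (!is.numeric(change_day) || length(change_day) != 1L || is.na(change_day))
    .fail_field("change_day", "must be a day value (Inf = never)")
  if (!.is_num1(post_change_drift) || post_change_drift < 0)
    .fail_field("post_change_drift", "must be >= 0")
  structure(list(center = as.numeric(center), radius = radius,
                 oscillation_period = oscillation_period,
                 oscillation_amplitude = oscillation_amplitude,
                 change_day = change_day, post_change_drift = post_change_drift,
                 color = as.numeric(color)),
            class = "polyp_config")
}

#' Scene configuration for the synthetic time-lapse generator
#'
#' Describes the stated world the generator renders: a coral region (the ROI
#' polygon) whose pixels are an exact mixture of three base shades following
#' a [stage_schedule()], polyp disks with their own dynamics, a blue-tinted
#' illumination cast (per-channel gains, blue above red/green), a slow
#' multiplicative brightness drift, and additive Gaussian sensor noise.
#'
#' @param width,height frame size in pixels
#' @param n_frames number of frames, `>= 2`
#' @param minutes_per_frame sampling cadence in minutes (default 2, the
#'   cadence matched to coral tissue motion frequencies)
#' @param base_colors `3 x 3` matrix, rows = dark/medium/light RGB in
#'   `[0, 255]`; rows must be separated by more than `3 * noise_sd` in
#'   Euclidean distance so clusters stay identifiable
#' @param schedule a [stage_schedule()]
#' @param blue_cast_gain per-channel multiplicative gains (R, G, B), all `> 0`
#' @param brightness_drift total multiplicative gain change across the series
#'   (0.1 = +10 percent by the last frame)
#' @param noise_sd additive Gaussian noise standard deviation (intensity units)
#' @param roi_polygon coral-region `coral_roi` (default: centered rectangle
#'   covering ~55 percent of the frame)
#' @param polyps list of [polyp_config()]
#' @param background RGB triplet outside the ROI
#' @param seed integer seed; fixed seed gives a bit-identical series
#' @return an object of class `scene_config`
#' @export
scene_config <- function(width, height, n_frames, minutes_per_frame = 2,
                         base_colors = default_base_colors(),
                         schedule = stage_schedule(c(9, 46, 56, 70),
                                                   default_shade_fractions(), 2),
                         blue_cast_gain = c(0.85, 1.0, 1.35),
                         brightness_drift = 0.1, noise_sd = 4,
                         roi_polygon = NULL, polyps = list(),
                         background = c(18, 22, 30), seed = 1L) {
  if (!.is_count(width) || !.is_count(height))
    .fail_field("width/height", "must be positive integers")
  if (!.is_count(n_frames, min = 2L)) .fail_field("n_frames", "must be >= 2")
  if (!.is_num1(minutes_per_frame) || minutes_per_frame <= 0)
    .fail_field("minutes_per_frame", "must be > 0")
  bc <- as.matrix(base_colors)
  if (!all(dim(bc) == c(3L, 3L)) || any(bc < 0 | bc > 255))
    .fail_field("base_colors", "need a 3 x 3 RGB matrix in [0, 255]")
  if (!.is_num1(noise_sd) || noise_sd < 0) .fail_field("noise_sd", "must be >= 0")
  dmin <- min(stats::dist(bc))
  if (dmin <= 3 * noise_sd)
    .fail_field("base_colors",
                sprintf("pairwise distance %.2f must exceed 3*noise_sd = %.2f",
                        dmin, 3 * noise_sd))
  stopifnot(inherits(schedule, "stage_schedule"))
  if (length(blue_cast_gain) != 3L || any(blue_cast_gain <= 0))
    .fail_field("blue_cast_gain", "need 3 gains > 0")
  if (!.is_num1(brightness_drift) || 1 + brightness_drift <= 0)
    .fail_field("brightness_drift", "final gain must remain > 0")
  T_span <- (n_frames - 1) * minutes_per_frame / 1440
  if (is.null(roi_polygon)) {
    m_r <- round(height * 0.15); m_c <- round(width * 0.15)
    roi_polygon <- roi_rect("colony", m_r, m_c, height - m_r, width - m_c)
  }
  stopifnot(inherits(roi_polygon, "coral_roi"))
  for (p in polyps) {
    stopifnot(inherits(p, "polyp_config"))
    if (is.finite(p$change_day) && (p$change_day < 0 || p$change_day > T_span))
      .fail_field("polyps", sprintf("change_day %.2f outside series span [0, %.2f]",
                                    p$change_day, T_span))
  }
  if (!.is_count(seed, min = 0L)) .fail_field("seed", "must be a nonnegative integer")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_frames = as.integer(n_frames),
                 minutes_per_frame = minutes_per_frame,
                 base_colors = bc, schedule = schedule,
                 blue_cast_gain = as.numeric(blue_cast_gain),
                 brightness_drift = brightness_drift, noise_sd = noise_sd,
                 roi_polygon = roi_polygon, polyps = polyps,
                 background = as.numeric(background),
                 seed = as.integer(seed), T_span = T_span),
            class = "scene_config")
}

#' Default dark/medium/light base colors (coral-brown shades)
#' @export
default_base_colors <- function() {
  m <- rbind(dark = c(60, 45, 35), medium = c(130, 105, 80),
             light = c(205, 190, 170))
  colnames(m) <- c("R", "G", "B")
  m
}

# exact integer allocation of n pixels to fractions (largest remainder)
.largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# reflect a scalar random-walk proposal into [lo, hi]
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  if (span <= 0) return(lo)
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate a synthetic coral time-lapse with ground truth
#'
#' Renders the scene described by a [scene_config()]. Inside the ROI each
#' pixel takes one of the three base colors; the per-frame allocation is
#' exact (largest-remainder rounding of the scheduled fractions) and pixels
#' are ordered by a fixed seeded permutation, so a constant schedule yields
#' bit-identical frames and shade shares always match the schedule to within
#' one pixel. Polyp disks are drawn on top, then the blue cast, brightness
#' drift and sensor noise are applied and intensities clipped to `[0, 255]`.
#'
#' @param config a `scene_config`
#' @return list with `series` (a `coral_series`) and `ground_truth` (class
#'   `coral_ground_truth`: per-frame scheduled shade fractions, stage labels,
#'   per-polyp change days, base colors, `roi_mask` for the full colony and
#'   `color_mask` = colony minus polyp boxes, the region the schedule governs)
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$height; w <- config$width; n <- config$n_frames
  days <- (seq_len(n) - 1) * config$minutes_per_frame / 1440
  mask <- rasterize_roi(config$roi_polygon, c(h, w))
  roi_idx <- which(mask)            # column-major linear indices
  n_roi <- length(roi_idx)
  if (n_roi < 3L) .fail_field("roi_polygon", "ROI must contain >= 3 pixels")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  # fixed random ordering of ROI pixels: the allocation frontier moves along
  # this order as fractions change, keeping frames temporally coherent
  pix_order <- sample.int(n_roi)

  fractions <- schedule_fraction_at(config$schedule, days)
  stages <- schedule_stage_at(config$schedule, days)

  # per-polyp precomputation and state
  npoly <- length(config$polyps)
  pstate <- vector("list", npoly)
  for (k in seq_len(npoly)) {
    p <- config$polyps[[k]]
    rmax <- ceiling(p$radius * 1.6)
    rr <- pmax(1L, floor(p$center[1] - rmax)):pmin(h, ceiling(p$center[1] + rmax) + 1L)
    cc <- pmax(1L, floor(p$center[2] - rmax)):pmin(w, ceiling(p$center[2] + rmax) + 1L)
    dr <- (rr - 0.5) - p$center[1]
    dc <- (cc - 0.5) - p$center[2]
    dist <- sqrt(outer(dr^2, dc^2, `+`))
    pstate[[k]] <- list(cfg = p, rows = rr, cols = cc, dist = dist,
                        radius = p$radius, walk = 0,
                        texture = matrix(0, length(rr), length(cc)))
  }
  # colony mask minus polyp bounding boxes: the region whose composition is
  # governed by the schedule (polyp crops are analyzed separately)
  color_mask <- mask
  for (st in pstate) color_mask[st$rows, st$cols] <- FALSE

  # static background canvas
  canvas0 <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) canvas0[, , ch] <- config$background[ch]

  frames <- vector("list", n)
  drift_gain <- 1 + config$brightness_drift * (seq_len(n) - 1) / max(1, n - 1)
  for (t in seq_len(n)) {
    px <- canvas0
    counts <- .largest_remainder(fractions[t, ], n_roi)
    cat_by_order <- rep.int(1:3, counts)
    cats <- integer(n_roi)
    cats[pix_order] <- cat_by_order
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[roi_idx] <- config$base_colors[cats, ch]
      px[, , ch] <- plane
    }
    # polyp disks
    for (k in seq_len(npoly)) {
      st <- pstate[[k]]
      p <- st$cfg
      if (days[t] < p$change_day) {
        # quasi-periodic regime: sinusoidal radius + brightness modulation
        phase <- sin(2 * pi * (t - 1) / p$oscillation_period)
        st$radius <- p$radius * (1 + p$oscillation_amplitude * phase)
        gain <- 1 + 0.5 * p$oscillation_amplitude * phase
        beta <- 0
      } else {
        # nonstationary regime: the tissue collapses onto a skeleton-like
        # random texture at the change day, which then drifts (reflected
        # random walk) with an erratic per-frame component on top — detached
        # tissue swinging in the flow
        step <- p$post_change_drift
        if (is.null(st$collapsed)) {
          st$collapsed <- TRUE
          st$radius <- p$radius
          st$texture <- matrix(stats::rnorm(length(st$texture), 0, 45),
                               nrow = nrow(st$texture))
        }
        st$radius <- .reflect(st$radius + stats::rnorm(1, 0, step * p$radius / 150),
                              0.8 * p$radius, 1.2 * p$radius)
        st$walk <- .reflect(st$walk + stats::rnorm(1, 0, step / 100), 0, 0.15)
        st$texture <- matrix(.reflect(st$texture +
                                        stats::rnorm(length(st$texture), 0, step / 2),
                                      -70, 70),
                             nrow = nrow(st$texture))
        gain <- 1
        beta <- min(1, 0.85 * min(1, 2 * (days[t] - p$change_day)) + st$walk)
      }
      inside <- st$dist <= st$radius
      if (any(inside)) {
        prof <- 0.35 + 0.65 * cos(pi / 2 * pmin(1, st$dist / st$radius))
        skeleton <- c(205, 195, 180)
        fresh <- if (beta > 0)
          matrix(stats::rnorm(length(st$texture), 0, 2 * p$post_change_drift),
                 nrow = nrow(st$texture))
        else 0
        for (ch in 1:3) {
          sub <- px[st$rows, st$cols, ch]
          body <- p$color[ch] * gain * prof
          val <- if (beta > 0)
            (1 - beta) * body + beta * (skeleton[ch] + st$texture + fresh)
          else body
          sub[inside] <- val[inside]
          px[st$rows, st$cols, ch] <- sub
        }
      }
      pstate[[k]] <- st
    }
    # illumination cast + brightness drift
    for (ch in 1:3)
      px[, , ch] <- px[, , ch] * (config$blue_cast_gain[ch] * drift_gain[t])
    if (config$noise_sd > 0)
      px <- px + stats::rnorm(length(px), 0, config$noise_sd)
    px[px < 0] <- 0; px[px > 255] <- 255
    storage_px <- array(as.integer(round(px)), dim = dim(px))
    frames[[t]] <- storage_px
  }

  series <- image_series(frames, days = days,
                         minutes_per_frame = config$minutes_per_frame)
  gt <- structure(list(days = days, fractions = fractions,
                       stage = stages,
                       boundaries = config$schedule$boundaries,
                       change_days = vapply(config$polyps,
                                            function(p) p$change_day, numeric(1)),
                       base_colors = config$base_colors,
                       roi_mask = mask, color_mask = color_mask),
                  class = "coral_ground_truth")
  list(series = series, ground_truth = gt)
}

#' Write ground truth as JSON
#'
#' @param gt a `coral_ground_truth`
#' @param path output path
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "coral_ground_truth"))
  jsonlite::write_json(list(days = gt$days,
                            fractions = gt$fractions,
                            stage = gt$stage,
                            boundaries = gt$boundaries,
                            change_days = gt$change_days,
                            base_colors = gt$base_colors),
                       path, digits = NA)
  invisible(path)
}
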