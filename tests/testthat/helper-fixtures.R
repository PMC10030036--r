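# Shared fixture builders (all programmatic; no stored binaries).

# flat schedule: the same triplet in all five stages
flat_schedule <- function(trip = c(0.5, 0.3, 0.2)) {
  stage_schedule(c(10, 20, 30, 40),
                 matrix(rep(trip, 5), ncol = 3, byrow = TRUE),
                 transition_width = 0)
}

# minimal clean scene: no cast, no drift, no noise, no polyps
clean_scene <- function(n_frames = 3, trip = c(0.5, 0.3, 0.2), seed = 1,
                        size = 40, noise_sd = 0, ...) {
  scene_config(width = size, height = size, n_frames = n_frames,
               minutes_per_frame = 60,
               schedule = flat_schedule(trip),
               blue_cast_gain = c(1, 1, 1), brightness_drift = 0,
               noise_sd = noise_sd, seed = seed, ...)
}

# paper-like 105-day scene at reduced scale; cadence in frames per day
paper_scene <- function(seed, frames_per_day = 12, size = 96,
                        noise_sd = 4, polyps = list(), ...) {
  n <- as.integer(105 * frames_per_day + 1)
  scene_config(width = size, height = size, n_frames = n,
               minutes_per_frame = 1440 / frames_per_day,
               schedule = stage_schedule(c(9, 46, 56, 70),
                                         default_shade_fractions(), 2),
               noise_sd = noise_sd, polyps = polyps, seed = seed, ...)
}

# standard test polyp for a 96x96 scene, change at day 50
test_polyp <- function(change_day = 50, period = 48, amplitude = 0.3,
                       drift = 4, center = c(48, 48), radius = 14) {
  polyp_config(center = center, radius = radius, oscillation_period = period,
               oscillation_amplitude = amplitude, change_day = change_day,
               post_change_drift = drift)
}

# analysis crop inscribed in a polyp disk (all tissue, no static background)
polyp_crop <- function(p) {
  half <- max(3, floor(p$radius * 0.45))
  roi_rect("polyp", p$center[1] - half, p$center[2] - half,
           p$center[1] + half, p$center[2] + half)
}

# gradient frame: distinct values everywhere, useful for roundtrips
gradient_frame <- function(h = 8, w = 8) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    px[, , ch] <- (outer(seq_len(h), seq_len(w)) * ch * 7) %% 256
  px
}
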