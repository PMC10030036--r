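#' Pearson correlation between two frames over an ROI
#'
#' Computes the product-moment correlation between the chosen channel's
#' intensities of a reference frame and a current frame at identical pixel
#' locations inside the ROI:
#' `r = sum((I_ref - mean)(I_cur - mean)) / sqrt(sum((I_ref - mean)^2) sum((I_cur - mean)^2))`.
#' Each frame's ROI intensities are z-scored first; this leaves `r`
#' unchanged (Pearson is invariant to positive affine transforms) but is
#' recorded because it standardizes the joint histograms and suppresses the
#' slow brightness increase that water-level drop causes in long recordings.
#'
#' @param ref,cur `coral_frame`s or `H x W x 3` arrays of identical shape
#' @param roi a `coral_roi` or logical mask with >= 2 pixels
#' @param channel `"R"`, `"G"` or `"B"`; default `"G"` — the green channel is
#'   the most stable across the three dominant shades, so it tracks
#'   morphology rather than lighting
#' @return the scalar correlation in `[-1, 1]`
#' @export
pearson_correlation <- function(ref, cur, roi, channel = "G") {
  pr <- .frame_pixels(ref); pc <- .frame_pixels(cur)
  if (!all(dim(pr) == dim(pc)))
    .fail_field("cur", "frames must have identical shape")
  ch <- .channel_index(channel)
  mask <- rasterize_roi(roi, dim(pr)[1:2])
  idx <- which(mask)
  if (length(idx) < 2L) .fail_field("roi", "ROI must contain >= 2 pixels")
  a <- as.numeric(pr[, , ch][idx])
  b <- as.numeric(pc[, , ch][idx])
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0)
    stop("undefined correlation: zero intensity variance in ROI", call. = FALSE)
  a <- (a - mean(a)) / sa
  b <- (b - mean(b)) / sb
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  max(-1, min(1, r))
}

.channel_index <- function(channel) {
  ch <- match(toupper(channel), c("R", "G", "B"))
  if (is.na(ch)) .fail_field("channel", "must be one of R, G, B")
  ch
}

#' Pearson correlation time series for one polyp ROI
#'
#' `r_t` between every frame and the reference frame (default: the first),
#' over the given ROI and channel. `r` at the reference index is exactly 1.
#'
#' @param series a `coral_series` with >= 2 frames
#' @param roi polyp ROI (`coral_roi` or logical mask)
#' @param reference_index index of the reference frame (default 1)
#' @param channel intensity channel, default `"G"`
#' @param roi_name label stored with the result
#' @return class `correlation_series`: `r`, `days`, `reference_index`,
#'   `roi_name`, `channel`, `normalization`
#' @export
correlation_series <- function(series, roi, reference_index = 1L,
                               channel = "G", roi_name = NULL) {
  stopifnot(inherits(series, "coral_series"))
  n <- length(series)
  if (n < 2L) .fail_field("series", "need >= 2 frames")
  if (!.is_count(reference_index) || reference_index > n)
    .fail_field("reference_index", "out of range")
  mask <- rasterize_roi(roi, dim(series$pixels[[1]])[1:2])
  ref <- series$pixels[[reference_index]]
  r <- numeric(n)
  for (t in seq_len(n)) {
    r[t] <- tryCatch(
      pearson_correlation(ref, series$pixels[[t]], mask, channel),
      error = function(e)
        stop(sprintf("frame %d: %s", t, conditionMessage(e)), call. = FALSE))
  }
  structure(list(r = r, days = series$days,
                 reference_index = as.integer(reference_index),
                 roi_name = if (is.null(roi_name) && inherits(roi, "coral_roi"))
                   roi$name else roi_name,
                 channel = toupper(channel), normalization = "zscore_roi"),
            class = "correlation_series")
}

#' Joint intensity histogram between reference and current frame
#'
#' The intensity plot: a bivariate histogram of (reference intensity,
#' current intensity) at identical ROI pixel locations, with equal-width
#' bins on `[0, 255]`. A tight diagonal means high similarity; dispersion
#' means morphology change.
#'
#' @inheritParams pearson_correlation
#' @param bins number of bins per axis (default 64)
#' @return class `intensity_histogram`: `joint_counts` (`bins x bins`,
#'   reference bins in rows), `marginals` (list `ref`, `cur`), `bins`,
#'   `channel`
#' @export
intensity_plot <- function(ref, cur, roi, bins = 64L, channel = "G") {
  if (!.is_count(bins, min = 2L)) .fail_field("bins", "must be an integer >= 2")
  pr <- .frame_pixels(ref); pc <- .frame_pixels(cur)
  if (!all(dim(pr) == dim(pc)))
    .fail_field("cur", "frames must have identical shape")
  ch <- .channel_index(channel)
  mask <- rasterize_roi(roi, dim(pr)[1:2])
  idx <- which(mask)
  if (length(idx) < 1L) .fail_field("roi", "empty ROI")
  bin_of <- function(v) pmin(bins, floor(v / 256 * bins) + 1L)
  br <- bin_of(as.numeric(pr[, , ch][idx]))
  bc <- bin_of(as.numeric(pc[, , ch][idx]))
  joint <- matrix(0L, bins, bins)
  tab <- table(factor(br, levels = seq_len(bins)),
               factor(bc, levels = seq_len(bins)))
  joint[] <- as.integer(tab)
  structure(list(joint_counts = joint,
                 marginals = list(ref = rowSums(joint), cur = colSums(joint)),
                 bins = as.integer(bins), channel = toupper(channel)),
            class = "intensity_histogram")
}

#' Detect the drastic morphology change in a correlation series
#'
#' Two-window mean-difference scan: at each interior index the drop is the
#' mean of `r` over the `window` frames before minus the mean over the
#' `window` frames after; the change point is the index maximizing the drop.
#' A drop not exceeding `min_magnitude` yields a "no change detected" flag.
#'
#' @param cs a `correlation_series`
#' @param window scan window in frames (default: one day of frames given the
#'   series cadence, minimum 1)
#' @param min_magnitude smallest drop counted as a change (default 0)
#' @return class `change_point`: `day`, `index`, `magnitude` (r units),
#'   `window`, `no_change` flag
#' @export
detect_change_point <- function(cs, window = NULL, min_magnitude = 0) {
  stopifnot(inherits(cs, "correlation_series"))
  n <- length(cs$r)
  if (is.null(window)) {
    spacing <- if (n > 1) stats::median(diff(cs$days)) else 1
    window <- max(1L, min(n %/% 2L, round(1 / max(spacing, 1e-9))))
  }
  if (!.is_count(window) || n <= window)
    .fail_field("window", "series must be longer than the window")
  cs_sum <- c(0, cumsum(cs$r))
  drops <- rep(-Inf, n)
  for (t in (window + 1L):(n - window + 1L)) {
    before <- (cs_sum[t] - cs_sum[t - window]) / window
    after <- (cs_sum[t + window] - cs_sum[t]) / window
    drops[t] <- before - after
  }
  t_star <- which.max(drops)
  mag <- drops[t_star]
  no_change <- !is.finite(mag) || mag <= min_magnitude + 1e-12
  if (!is.finite(mag)) mag <- 0
  structure(list(day = cs$days[t_star], index = t_star,
                 magnitude = max(0, mag), window = as.integer(window),
                 no_change = no_change),
            class = "change_point")
}
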