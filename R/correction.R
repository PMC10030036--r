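#' White-balance correction models
#'
#' Aquarium lighting imposes a strong blue cast on raw frames; downstream
#' color clustering needs an approximately neutral baseline. Correction is a
#' per-channel multiplicative gain model fitted by one of three methods:
#'
#' * `gray_world` (default): gains scale each channel mean to the mean of the
#'   three channel means — exact inverse of a multiplicative cast on a scene
#'   whose true channel means are equal;
#' * `white_patch`: gains scale each channel's 99th percentile to 255;
#' * `fixed_gains`: user-supplied gains, for exact reproducibility.
#'
#' @param frame a `coral_frame` or `H x W x 3` array
#' @param method one of `"gray_world"`, `"white_patch"`, `"fixed_gains"`
#' @param gains required for `fixed_gains`: length-3 positive gains
#' @return an object of class `correction_model` with fields `method`,
#'   `gains`, `clip_policy`
#' @examples
#' f <- array(rep(c(120, 100, 80), each = 4), dim = c(2, 2, 3))
#' fit_correction(f, "gray_world")$gains  # (100/120, 1, 100/80)
#' @export
fit_correction <- function(frame, method = c("gray_world", "white_patch",
                                             "fixed_gains"), gains = NULL) {
  method <- match.arg(method)
  if (method == "fixed_gains") {
    if (is.null(gains) || length(gains) != 3L || any(gains <= 0))
      .fail_field("gains", "fixed_gains needs 3 positive gains")
    return(structure(list(method = method, gains = as.numeric(gains),
                          clip_policy = "saturate_255"),
                     class = "correction_model"))
  }
  px <- .frame_pixels(frame)
  if (method == "gray_world") {
    mu <- vapply(1:3, function(ch) mean(px[, , ch]), numeric(1))
    if (any(mu <= 0))
      stop("degenerate input: zero-mean channel, cannot fit gray_world",
           call. = FALSE)
    g <- mean(mu) / mu
  } else {
    q <- vapply(1:3, function(ch)
      stats::quantile(px[, , ch], 0.99, names = FALSE), numeric(1))
    if (any(q <= 0))
      stop("degenerate input: empty bright tail, cannot fit white_patch",
           call. = FALSE)
    g <- 255 / q
  }
  structure(list(method = method, gains = as.numeric(g),
                 clip_policy = "saturate_255"),
            class = "correction_model")
}

#' Apply a correction model to a frame
#'
#' Per-pixel per-channel multiply, then clip to `[0, 255]`. Dimensions and
#' hence any ROI geometry are unchanged.
#'
#' @param frame a `coral_frame` or `H x W x 3` array
#' @param model a fitted `correction_model`
#' @return corrected pixels, same shape and range as the input
#' @export
apply_correction <- function(frame, model) {
  stopifnot(inherits(model, "correction_model"))
  px <- .frame_pixels(frame)
  out <- px
  for (ch in 1:3) out[, , ch] <- px[, , ch] * model$gains[ch]
  out[out < 0] <- 0
  out[out > 255] <- 255
  if (is.integer(px)) out <- array(as.integer(round(out)), dim = dim(out))
  if (inherits(frame, "coral_frame")) {
    frame$pixels <- out
    frame
  } else out
}

#' Correct a whole series
#'
#' @param series a `coral_series`
#' @param method correction method, see [fit_correction()]
#' @param per_frame refit gains on every frame (default; robust to brightness
#'   drift) or fit once on the first frame
#' @param gains for `fixed_gains`
#' @return a corrected `coral_series`; attribute `"correction"` records the
#'   method and per-frame flag
#' @export
correct_series <- function(series, method = "gray_world", per_frame = TRUE,
                           gains = NULL) {
  stopifnot(inherits(series, "coral_series"))
  model <- NULL
  out <- series
  for (i in seq_len(length(series))) {
    if (is.null(model) || (per_frame && method != "fixed_gains"))
      model <- fit_correction(series$pixels[[i]], method, gains = gains)
    out$pixels[[i]] <- apply_correction(series$pixels[[i]], model)
  }
  attr(out, "correction") <- list(method = method, per_frame = per_frame)
  out
}
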