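#' Stage schedule for shade mixture fractions
#'
#' Describes how the coral surface's pixel population, a mixture of three
#' shade clusters (dark, medium, light), evolves through five stages
#' separated by four transition days. Between stages the mixture ramps
#' linearly over `transition_width` days centered on each boundary; with
#' width 0 the schedule is a step function (right-continuous at the
#' boundary).
#'
#' @param boundaries four strictly increasing day values, interior to `(0, T)`
#' @param shade_fractions `5 x 3` matrix; row s is the (dark, medium, light)
#'   mixture of stage s, nonnegative, each row summing to 1
#' @param transition_width ramp width in days, `>= 0`
#' @return an object of class `stage_schedule`
#' @examples
#' sch <- stage_schedule(c(9, 46, 56, 70), default_shade_fractions(), 2)
#' schedule_fraction_at(sch, 30)
#' @export
stage_schedule <- function(boundaries, shade_fractions, transition_width = 0) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 4L || any(!is.finite(boundaries)))
    .fail_field("boundaries", "need exactly 4 finite day values")
  if (any(diff(boundaries) <= 0))
    .fail_field("boundaries", "must be strictly increasing")
  if (any(boundaries <= 0))
    .fail_field("boundaries", "must be positive")
  sf <- as.matrix(shade_fractions)
  if (!all(dim(sf) == c(5L, 3L)))
    .fail_field("shade_fractions", "need a 5 x 3 matrix (5 stages x 3 shades)")
  if (any(sf < 0)) .fail_field("shade_fractions", "must be nonnegative")
  if (any(abs(rowSums(sf) - 1) > 1e-9))
    .fail_field("shade_fractions", "each stage triplet must sum to 1 (tol 1e-9)")
  if (!.is_num1(transition_width) || transition_width < 0)
    .fail_field("transition_width", "must be a nonnegative number")
  structure(list(boundaries = boundaries, shade_fractions = sf,
                 transition_width = transition_width),
            class = "stage_schedule")
}

#' Paper-like default stage mixtures
#'
#' Five (dark, medium, light) triplets tracing the canonical tissue-loss
#' phenomenology: a dark-dominated healthy stage, progressive paling with a
#' light-share peak at the second boundary, a medium-dominated pale stage,
#' re-darkening under algal overgrowth, and a stable terminal composition
#' near (0.39, 0.40, 0.21).
#'
#' @return a `5 x 3` matrix of mixture fractions
#' @export
default_shade_fractions <- function() {
  m <- rbind(c(0.52, 0.34, 0.14),
             c(0.37, 0.33, 0.30),
             c(0.33, 0.43, 0.24),
             c(0.41, 0.39, 0.20),
             c(0.39, 0.40, 0.21))
  dimnames(m) <- list(paste0("stage", 1:5), c("dark", "medium", "light"))
  m
}

#' Evaluate the scheduled shade mixture at a given day
#'
#' @param schedule a `stage_schedule`
#' @param day day value(s) in `[0, T]`; `T` caps the valid range when given
#' @param T optional series span used for range checking
#' @return for scalar `day`, a length-3 (dark, medium, light) triplet summing
#'   to 1; for vector `day`, an `n x 3` matrix
#' @export
schedule_fraction_at <- function(schedule, day, T = NULL) {
  stopifnot(inherits(schedule, "stage_schedule"))
  if (any(!is.finite(day)) || any(day < 0))
    .fail_field("day", "must be finite and >= 0")
  if (!is.null(T) && any(day > T))
    .fail_field("day", sprintf("beyond the series span T = %g", T))
  b <- schedule$boundaries
  sf <- schedule$shade_fractions
  w <- schedule$transition_width
  one <- function(d) {
    # stage index if no transitions: right-continuous step
    s <- 1L + sum(d >= b)
    if (w > 0) {
      for (k in seq_along(b)) {
        lo <- b[k] - w / 2; hi <- b[k] + w / 2
        if (d >= lo && d < hi) {
          a <- (d - lo) / w
          return((1 - a) * sf[k, ] + a * sf[k + 1L, ])
        }
      }
    }
    sf[s, ]
  }
  if (length(day) == 1L) {
    out <- one(day)
    names(out) <- c("dark", "medium", "light")
    out
  } else {
    out <- t(vapply(day, one, numeric(3)))
    colnames(out) <- c("dark", "medium", "light")
    out
  }
}

#' Stage label (1..5) at a given day
#'
#' The label follows the plateau the day belongs to; inside a transition
#' window the nearer stage wins (midpoint goes to the later stage).
#' @inheritParams schedule_fraction_at
#' @export
schedule_stage_at <- function(schedule, day) {
  stopifnot(inherits(schedule, "stage_schedule"))
  vapply(day, function(d) 1L + sum(d >= schedule$boundaries), integer(1))
}
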