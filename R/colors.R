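#' Dominant-color extraction by k-means in RGB space
#'
#' Pixels inside the ROI are clustered in RGB space (Euclidean distance,
#' k = 3 by default) and each cluster's membership share becomes a dominant
#' color percentage. Clustering runs on the frame's unique-color table with
#' pixel counts as case weights, with seeded k-means++ initialisation and at
#' least 10 restarts; because the unique-color table is sorted before
#' sampling, the result is invariant to pixel order. Clusters are labelled
#' dark/medium/light by centroid luminance (see [label_shades()]); the rank
#' by percentage is kept as metadata since it can swap between stages.
#'
#' @param frame a `coral_frame` or `H x W x 3` array (color-corrected)
#' @param roi a `coral_roi` or logical mask
#' @param k number of clusters (default 3: dark, medium, light)
#' @param seed integer seed for the k-means++ restarts
#' @param restarts number of k-means++ restarts (>= 10 recommended)
#' @return an object of class `dominant_color_set`: `colors` (`m x 3` RGB
#'   centroids, `m <= k`), `percentages` (length `m`, summing to 100),
#'   `shade_labels`, `percentage_rank`, `degenerate` flag
#' @export
extract_dominant_colors <- function(frame, roi, k = 3, seed = 1L,
                                    restarts = 10L) {
  px <- .frame_pixels(frame)
  mask <- rasterize_roi(roi, dim(px)[1:2])
  idx <- which(mask)
  if (!length(idx)) stop("empty ROI", call. = FALSE)
  X <- cbind(px[, , 1][idx], px[, , 2][idx], px[, , 3][idx])
  if (nrow(X) < k)
    stop("ROI has fewer pixels than clusters", call. = FALSE)

  # unique-color table with counts, sorted for permutation invariance
  key <- paste(X[, 1], X[, 2], X[, 3])
  ord <- order(X[, 1], X[, 2], X[, 3])
  ux_keys <- unique(key[ord])
  map <- match(key, ux_keys)
  counts <- tabulate(map, nbins = length(ux_keys))
  ux <- X[ord[!duplicated(key[ord])], , drop = FALSE]

  m <- nrow(ux)
  degenerate <- m < k
  if (degenerate) {
    warning(sprintf("ROI has only %d distinct color(s) < k = %d: degenerate clusters merged",
                    m, k), call. = FALSE)
    centers <- ux
    assign <- seq_len(m)
    shares <- counts / sum(counts)
  } else {
    fit <- .weighted_kmeans(ux, counts, k, seed = seed, restarts = restarts)
    centers <- fit$centers
    # merge duplicate centroids (within tiny tolerance)
    keep <- rep(TRUE, nrow(centers))
    for (i in seq_len(nrow(centers))) {
      if (!keep[i]) next
      for (j in seq_len(i - 1L)) {
        if (keep[j] && sqrt(sum((centers[i, ] - centers[j, ])^2)) < 1e-9) {
          keep[i] <- FALSE
          fit$cluster[fit$cluster == i] <- j
          break
        }
      }
    }
    if (!all(keep)) {
      warning("duplicate centroids merged into surviving cluster", call. = FALSE)
      degenerate <- TRUE
    }
    relab <- cumsum(keep)
    centers <- centers[keep, , drop = FALSE]
    cl <- relab[fit$cluster]
    shares <- vapply(seq_len(nrow(centers)),
                     function(j) sum(counts[cl == j]), numeric(1)) / sum(counts)
  }
  lab <- label_shades(centers)
  o <- order(match(lab, c("dark", "medium", "light")))
  centers <- centers[o, , drop = FALSE]
  shares <- shares[o]
  lab <- lab[o]
  structure(list(colors = centers, percentages = 100 * shares,
                 shade_labels = lab,
                 percentage_rank = rank(-shares, ties.method = "first"),
                 degenerate = degenerate),
            class = "dominant_color_set")
}

# weighted Lloyd k-means with k-means++ init over rows of X (weights w)
.weighted_kmeans <- function(X, w, k, seed, restarts = 10L, iter_max = 100L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  best <- NULL
  m <- nrow(X)
  for (r in seq_len(max(1L, restarts))) {
    # k-means++ seeding (weighted)
    cidx <- integer(k)
    cidx[1] <- sample.int(m, 1L, prob = w)
    d2 <- rowSums((X - matrix(X[cidx[1], ], m, 3, byrow = TRUE))^2)
    for (j in 2:k) {
      p <- w * d2
      if (sum(p) <= 0) {
        cidx[j] <- sample.int(m, 1L, prob = w)
      } else {
        cidx[j] <- sample.int(m, 1L, prob = p)
      }
      d2 <- pmin(d2, rowSums((X - matrix(X[cidx[j], ], m, 3, byrow = TRUE))^2))
    }
    centers <- X[cidx, , drop = FALSE]
    cl_prev <- integer(m)
    for (it in seq_len(iter_max)) {
      D <- .dist2_to_centers(X, centers)
      cl <- max.col(-D, ties.method = "first")
      if (identical(cl, cl_prev)) break
      cl_prev <- cl
      for (j in seq_len(k)) {
        sel <- cl == j
        if (any(sel)) {
          wj <- w[sel]
          centers[j, ] <- colSums(X[sel, , drop = FALSE] * wj) / sum(wj)
        }
        # empty cluster: reseed at the point with largest weighted distance
        else {
          D <- .dist2_to_centers(X, centers)
          dd <- w * apply(D, 1, min)
          centers[j, ] <- X[which.max(dd), ]
        }
      }
    }
    D <- .dist2_to_centers(X, centers)
    cl <- max.col(-D, ties.method = "first")
    wss <- sum(w * D[cbind(seq_len(m), cl)])
    if (is.null(best) || wss < best$wss - 1e-12)
      best <- list(centers = centers, cluster = cl, wss = wss)
  }
  best
}

.dist2_to_centers <- function(X, centers) {
  k <- nrow(centers)
  D <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    D[, j] <- (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2 +
      (X[, 3] - centers[j, 3])^2
  }
  D
}

#' Label centroids as dark / medium / light by luminance
#'
#' Luminance is `0.2126 R + 0.7152 G + 0.0722 B`; centroids are ranked
#' ascending, ties broken by G then R then B ascending. Luminance rank (not
#' percentage rank) is the canonical cluster identity across frames, because
#' the percentage ordering swaps between stages while the centroids stay in
#' a narrow region of RGB space.
#'
#' @param colors `m x 3` RGB centroid matrix (`m <= 3`)
#' @return character vector of labels from `c("dark", "medium", "light")`
#' @export
label_shades <- function(colors) {
  colors <- as.matrix(colors)
  m <- nrow(colors)
  if (m < 1L || m > 3L || ncol(colors) != 3L)
    .fail_field("colors", "need an m x 3 matrix with 1 <= m <= 3")
  lum <- colors %*% c(0.2126, 0.7152, 0.0722)
  o <- order(lum, colors[, 2], colors[, 1], colors[, 3])
  lab <- character(m)
  lab[o] <- c("dark", "medium", "light")[seq_len(m)]
  lab
}

#' Dominant-color time series over an image series
#'
#' Runs [extract_dominant_colors()] on every `decimate`-th frame. Hourly
#' cadence (every 30th frame at the default 2-minute sampling) is plenty for
#' stage analysis; the decimation factor is recorded in the result.
#'
#' @param series a `coral_series` (color-corrected)
#' @param roi colony ROI
#' @param k,seed,restarts passed to [extract_dominant_colors()]
#' @param decimate analyze every `decimate`-th frame (default 1)
#' @return class `dominant_color_series`: `days`, `percentages` (`n x 3`,
#'   columns dark/medium/light), `colors` (`n x 3 x 3` centroids), metadata
#' @export
dominant_color_series <- function(series, roi, k = 3, seed = 1L,
                                  restarts = 10L, decimate = 1L) {
  stopifnot(inherits(series, "coral_series"))
  sel <- seq(1L, length(series), by = max(1L, as.integer(decimate)))
  mask <- rasterize_roi(roi, dim(series$pixels[[1]])[1:2])
  n <- length(sel)
  pct <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("dark", "medium", "light")))
  cols <- array(NA_real_, dim = c(n, 3, 3))
  for (i in seq_len(n)) {
    dc <- extract_dominant_colors(series$pixels[[sel[i]]], mask, k = k,
                                  seed = seed, restarts = restarts)
    j <- match(dc$shade_labels, c("dark", "medium", "light"))
    pct[i, j] <- dc$percentages
    cols[i, j, ] <- dc$colors
    pct[i, is.na(pct[i, ])] <- 0
  }
  structure(list(days = series$days[sel], percentages = pct, colors = cols,
                 smoothing = list(method = "none"),
                 decimate = as.integer(decimate), k = k, seed = seed),
            class = "dominant_color_series")
}

#' Smooth dominant-color percentages
#'
#' Centered moving average per shade channel with window truncation at the
#' edges; each smoothed triplet is renormalized to sum to 100.
#'
#' @param series a `dominant_color_series` (or bare `n x 3` matrix)
#' @param window odd window length in analyzed frames, `1 <= window <= n`
#' @return same class as input with smoothed percentages; smoothing metadata
#'   updated
#' @export
smooth_percentages <- function(series, window) {
  mat <- if (inherits(series, "dominant_color_series")) series$percentages
         else as.matrix(series)
  n <- nrow(mat)
  if (!.is_count(window) || window %% 2 == 0 || window > n)
    .fail_field("window", "must be odd, >= 1 and <= series length")
  hw <- (window - 1L) %/% 2L
  sm <- mat
  if (hw > 0L) {
    cs <- rbind(0, apply(mat, 2, cumsum))
    for (i in seq_len(n)) {
      a <- max(1L, i - hw); b <- min(n, i + hw)
      sm[i, ] <- (cs[b + 1L, ] - cs[a, ]) / (b - a + 1L)
    }
  }
  sm <- sm / rowSums(sm) * 100
  if (inherits(series, "dominant_color_series")) {
    series$percentages <- sm
    series$smoothing <- list(method = "moving_average", window = window)
    series
  } else sm
}

#' Detect stage boundaries by segmented linear fitting
#'
#' Finds the `n_boundaries` breakpoints that minimize the total squared
#' error of independent per-segment linear fits to the three shade series
#' jointly (segmented least squares, solved exactly by dynamic programming
#' over the analyzed time grid). This is a reproducible surrogate for
#' reading inflection points off the smoothed percentage curves by eye.
#'
#' Because each segment is fit independently, a steep smoothed transition
#' ramp could otherwise attract two breakpoints; `min_days` enforces a
#' minimum stage duration (default 6 days — every documented stage of the
#' tissue-loss process lasts at least 8) so each transition receives exactly
#' one breakpoint.
#'
#' @param series a `dominant_color_series` (ideally smoothed)
#' @param n_boundaries number of breakpoints (default 4, giving 5 stages)
#' @param min_seg minimum points per segment; default derived from `min_days`
#' @param min_days minimum stage duration in days used to derive `min_seg`
#'   when the latter is not given
#' @return class `stage_segmentation`: `boundaries` (day values, length
#'   `n_boundaries`), `stages` (data frame: stage, start_day, end_day, mean
#'   shade triplet), `sse`, `improvement` (relative SSE drop vs a single
#'   segment), `no_strong_inflections` flag (improvement < 0.25)
#' @export
detect_stage_boundaries <- function(series, n_boundaries = 4, min_seg = NULL,
                                    min_days = 6) {
  stopifnot(inherits(series, "dominant_color_series"))
  x <- series$days
  Y <- series$percentages
  n <- length(x)
  kseg <- n_boundaries + 1L
  if (n <= 2L * kseg)
    stop("series too short for ", n_boundaries, " boundaries", call. = FALSE)
  if (is.null(min_seg)) {
    spacing <- if (n > 1) stats::median(diff(x)) else 1
    min_seg <- max(3L, min(as.integer(ceiling(min_days / max(spacing, 1e-9))),
                           n %/% (kseg + 1L)))
  }
  cost <- .segment_cost_fun(x, Y)
  dp <- .segmented_ls_dp(n, kseg, cost, min_seg)
  cuts <- dp$cuts  # indices ending each of the first kseg-1 segments
  bdays <- (x[cuts] + x[cuts + 1L]) / 2
  sse1 <- cost(1L, n)
  improvement <- if (sse1 > 0) 1 - dp$sse / sse1 else 0
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  stages <- data.frame(stage = seq_len(kseg),
                       start_day = x[starts], end_day = x[ends])
  mean_trip <- t(vapply(seq_len(kseg), function(s)
    colMeans(Y[starts[s]:ends[s], , drop = FALSE]), numeric(3)))
  colnames(mean_trip) <- c("dark", "medium", "light")
  structure(list(boundaries = bdays, stages = cbind(stages, mean_trip),
                 sse = dp$sse, improvement = improvement,
                 no_strong_inflections = improvement < 0.25),
            class = "stage_segmentation")
}

# closure returning joint linear-fit SSE of points a..b via prefix sums
.segment_cost_fun <- function(x, Y) {
  n <- length(x)
  Sx <- cumsum(x); Sxx <- cumsum(x^2)
  Sy <- apply(Y, 2, cumsum)
  Syy <- apply(Y^2, 2, cumsum)
  Sxy <- apply(Y * x, 2, cumsum)
  pre <- function(S, a, b) if (a > 1L) S[b] - S[a - 1L] else S[b]
  preM <- function(S, a, b) if (a > 1L) S[b, ] - S[a - 1L, ] else S[b, ]
  function(a, b) {
    m <- b - a + 1L
    if (m < 2L) return(0)
    sx <- pre(Sx, a, b); sxx <- pre(Sxx, a, b)
    sy <- preM(Sy, a, b); syy <- preM(Syy, a, b); sxy <- preM(Sxy, a, b)
    sxx_c <- sxx - sx^2 / m
    sxy_c <- sxy - sx * sy / m
    syy_c <- syy - sy^2 / m
    if (sxx_c <= 1e-12) return(sum(pmax(0, syy_c)))
    sum(pmax(0, syy_c - sxy_c^2 / sxx_c))
  }
}

# exact Bellman DP for segmented least squares
.segmented_ls_dp <- function(n, kseg, cost, min_seg) {
  # C[j] for current layer: best SSE of first j points using s segments
  INF <- Inf
  C_prev <- rep(INF, n)
  for (j in seq_len(n)) if (j >= min_seg) C_prev[j] <- cost(1L, j)
  back <- matrix(NA_integer_, kseg, n)
  for (s in 2:kseg) {
    C_cur <- rep(INF, n)
    for (j in seq_len(n)) {
      if (j < s * min_seg) next
      lo <- (s - 1L) * min_seg
      hi <- j - min_seg
      if (hi < lo) next
      vals <- vapply(lo:hi, function(i) C_prev[i] + cost(i + 1L, j), numeric(1))
      w <- which.min(vals)
      C_cur[j] <- vals[w]
      back[s, j] <- (lo:hi)[w]
    }
    C_prev <- C_cur
  }
  if (!is.finite(C_prev[n])) stop("no feasible segmentation", call. = FALSE)
  cuts <- integer(kseg - 1L)
  j <- n
  for (s in kseg:2) {
    cuts[s - 1L] <- back[s, j]
    j <- back[s, j]
  }
  list(cuts = cuts, sse = C_prev[n])
}

#' Ternary trajectory of the shade composition
#'
#' Projects each frame's (dark, medium, light) triplet onto the 2-simplex
#' and, given a stage segmentation, summarizes the terminal stage by its
#' mean triplet (the convergence center of the trajectory's ring).
#'
#' @param series a `dominant_color_series`
#' @param segmentation optional `stage_segmentation`; required when `center`
#' @param center compute the convergence center (default: whenever a
#'   segmentation is supplied)
#' @return class `ternary_trajectory`: `points` (`n x 3`, rows sum to 100),
#'   `xy` (`n x 2` simplex plot coordinates), `convergence_center`
#' @export
ternary_trajectory <- function(series, segmentation = NULL,
                               center = !is.null(segmentation)) {
  stopifnot(inherits(series, "dominant_color_series"))
  pts <- series$percentages
  pts <- pts / rowSums(pts) * 100
  # equilateral-triangle coordinates (dark at left, medium right, light top)
  xy <- cbind(x = (pts[, 2] + 0.5 * pts[, 3]) / 100,
              y = (sqrt(3) / 2) * pts[, 3] / 100)
  cc <- NULL
  if (center) {
    if (is.null(segmentation))
      stop("convergence center requested but no stage segmentation given",
           call. = FALSE)
    stopifnot(inherits(segmentation, "stage_segmentation"))
    st <- segmentation$stages
    last <- st[nrow(st), ]
    sel <- series$days >= last$start_day & series$days <= last$end_day
    cc <- colMeans(pts[sel, , drop = FALSE])
    cc <- cc / sum(cc) * 100
  }
  structure(list(points = pts, xy = xy, convergence_center = cc),
            class = "ternary_trajectory")
}
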