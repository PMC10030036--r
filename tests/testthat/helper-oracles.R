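# Independent brute-force oracles. These deliberately share no code with the
# package: plain double loops and scalar arithmetic only.

# ---- RQA oracle ----------------------------------------------------------

oracle_recurrence <- function(r, eps) {
  n <- length(r)
  R <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) if (abs(r[i] - r[j]) <= eps) R[i, j] <- 1L
  R
}

# run lengths of ones in an integer vector, scalar scan
oracle_runs <- function(v) {
  out <- integer(0)
  cur <- 0L
  for (x in c(v, 0L)) {
    if (x == 1L) cur <- cur + 1L
    else { if (cur > 0L) out <- c(out, cur); cur <- 0L }
  }
  out
}

oracle_diag_lengths <- function(R, theiler = 1L) {
  n <- nrow(R)
  lens <- integer(0)
  for (d in -(n - 1L):(n - 1L)) {
    if (abs(d) < theiler) next
    v <- integer(0)
    for (i in 1:n) {
      j <- i + d
      if (j >= 1L && j <= n) v <- c(v, R[i, j])
    }
    lens <- c(lens, oracle_runs(v))
  }
  lens
}

oracle_vert_lengths <- function(R) {
  lens <- integer(0)
  for (j in seq_len(ncol(R))) lens <- c(lens, oracle_runs(R[, j]))
  lens
}

oracle_rqa <- function(R, l_min = 2L, v_min = 2L, theiler = 1L) {
  n <- nrow(R)
  RR <- 0
  for (i in 1:n) for (j in 1:n) RR <- RR + R[i, j]
  RR <- RR / n^2
  dl <- oracle_diag_lengths(R, theiler)
  det_den <- sum(dl)
  det_num <- sum(dl[dl >= l_min])
  DET <- if (det_den > 0) det_num / det_den else 0
  LMAX <- if (length(dl)) max(dl) else 0L
  keep <- dl[dl >= l_min]
  ENT <- 0
  if (length(keep)) {
    tab <- table(keep)
    p <- as.numeric(tab) / sum(tab)
    ENT <- -sum(p * log(p))
  }
  vl <- oracle_vert_lengths(R)
  lam_den <- sum(vl)
  vv <- vl[vl >= v_min]
  LAM <- if (lam_den > 0) sum(vv) / lam_den else 0
  TT <- if (length(vv)) sum(vv) / length(vv) else 0
  list(RR = RR, DET = DET, LMAX = as.integer(LMAX), ENT = ENT,
       LAM = LAM, TT = TT)
}

expect_rqa_equal <- function(q, o) {
  expect_equal(q$RR, o$RR, tolerance = 1e-12)
  expect_equal(q$DET, o$DET, tolerance = 1e-12)
  expect_identical(as.integer(q$LMAX), o$LMAX)
  expect_equal(q$ENT, o$ENT, tolerance = 1e-12)
  expect_equal(q$LAM, o$LAM, tolerance = 1e-12)
  expect_equal(q$TT, o$TT, tolerance = 1e-12)
}

# random symmetric 0/1 matrix with unit diagonal (a valid recurrence plot)
random_rp <- function(n, p = 0.4) {
  M <- matrix(0L, n, n)
  for (i in 1:n) for (j in i:n) {
    v <- if (i == j) 1L else rbinom(1, 1, p)
    M[i, j] <- v; M[j, i] <- v
  }
  M
}

# ---- Pearson scalar oracle ----------------------------------------------

oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

# ---- point-in-polygon oracle --------------------------------------------
# winding-number test (different algorithm from the package's even-odd ray
# crossing; they agree for simple polygons)

oracle_point_in_polygon <- function(pr, pc, verts) {
  n <- nrow(verts)
  wn <- 0
  for (i in 1:n) {
    j <- if (i == n) 1L else i + 1L
    y1 <- verts[i, 1]; x1 <- verts[i, 2]
    y2 <- verts[j, 1]; x2 <- verts[j, 2]
    if (y1 <= pr) {
      if (y2 > pr && (x2 - x1) * (pr - y1) - (pc - x1) * (y2 - y1) > 0)
        wn <- wn + 1
    } else {
      if (y2 <= pr && (x2 - x1) * (pr - y1) - (pc - x1) * (y2 - y1) < 0)
        wn <- wn - 1
    }
  }
  wn != 0
}

# ---- piecewise-linear schedule oracle -----------------------------------

oracle_schedule_at <- function(boundaries, fractions, width, day) {
  knots_x <- c(0)
  knots_y <- list(fractions[1, ])
  for (k in seq_along(boundaries)) {
    knots_x <- c(knots_x, boundaries[k] - width / 2, boundaries[k] + width / 2)
    knots_y <- c(knots_y, list(fractions[k, ]), list(fractions[k + 1, ]))
  }
  knots_x <- c(knots_x, 1e9)
  knots_y <- c(knots_y, list(fractions[5, ]))
  for (i in seq_len(length(knots_x) - 1)) {
    if (day >= knots_x[i] && day < knots_x[i + 1]) {
      x0 <- knots_x[i]; x1 <- knots_x[i + 1]
      y0 <- knots_y[[i]]; y1 <- knots_y[[i + 1]]
      if (!identical(y0, y1) && x1 > x0) {
        a <- (day - x0) / (x1 - x0)
        return((1 - a) * y0 + a * y1)
      }
      return(y0)
    }
  }
  fractions[5, ]
}

# ---- exhaustive segmented least squares ---------------------------------

oracle_segment_sse <- function(x, Y, a, b) {
  sse <- 0
  for (ch in seq_len(ncol(Y))) {
    xs <- x[a:b]; ys <- Y[a:b, ch]
    if (length(xs) < 2 || stats::var(xs) == 0) {
      sse <- sse + sum((ys - mean(ys))^2)
    } else {
      fit <- stats::lm.fit(cbind(1, xs), ys)
      sse <- sse + sum(fit$residuals^2)
    }
  }
  sse
}

oracle_best_2breaks <- function(x, Y, min_seg = 3) {
  n <- length(x)
  best <- list(sse = Inf, cuts = NULL)
  for (c1 in min_seg:(n - 2 * min_seg)) {
    for (c2 in (c1 + min_seg):(n - min_seg)) {
      sse <- oracle_segment_sse(x, Y, 1, c1) +
        oracle_segment_sse(x, Y, c1 + 1, c2) +
        oracle_segment_sse(x, Y, c2 + 1, n)
      if (sse < best$sse - 1e-12) best <- list(sse = sse, cuts = c(c1, c2))
    }
  }
  best
}

# ---- misc ---------------------------------------------------------------

oracle_moving_average <- function(v, window) {
  hw <- (window - 1) / 2
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    a <- max(1, i - hw); b <- min(length(v), i + hw)
    out[i] <- mean(v[a:b])
  }
  out
}
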