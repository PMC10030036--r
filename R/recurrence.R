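#' Recurrence matrix of a correlation series
#'
#' `R[i, j] = 1` iff `|r_i - r_j| <= epsilon` (Heaviside with the boundary
#' counted as recurrent). States are the scalar Pearson coefficients
#' themselves — no delay embedding — so the norm is the absolute difference.
#' The matrix is symmetric with a unit main diagonal.
#'
#' @param series a `correlation_series` or bare numeric vector of states
#' @param epsilon threshold distance (default 0.02)
#' @return class `recurrence_matrix`: `R` (`N x N` 0/1 integer matrix),
#'   `epsilon`
#' @examples
#' rm <- recurrence_matrix(c(0, 1, 0, 1), epsilon = 0.02)
#' rm$R
#' @export
recurrence_matrix <- function(series, epsilon = 0.02) {
  r <- if (inherits(series, "correlation_series")) series$r else as.numeric(series)
  if (length(r) < 2L) .fail_field("series", "need N >= 2 states")
  if (!.is_num1(epsilon) || epsilon <= 0)
    .fail_field("epsilon", "must be > 0")
  D <- abs(outer(r, r, `-`))
  R <- matrix(0L, length(r), length(r))
  R[D <= epsilon] <- 1L
  structure(list(R = R, epsilon = epsilon), class = "recurrence_matrix")
}

.rp_matrix <- function(R) {
  if (inherits(R, "recurrence_matrix")) R$R else {
    M <- as.matrix(R)
    storage.mode(M) <- "integer"
    M
  }
}

# run lengths of 1s in a 0/1 vector
.runs_of_ones <- function(v) {
  if (!length(v)) return(integer(0))
  rl <- rle(v)
  rl$lengths[rl$values == 1L]
}

#' Histogram of diagonal line lengths
#'
#' Counts maximal runs of recurrence points along every diagonal with offset
#' `|i - j| >= theiler`; at the default Theiler window 1 the main diagonal
#' is excluded and both triangles are counted.
#'
#' @param R a `recurrence_matrix` or 0/1 matrix
#' @param theiler half-width of the excluded band around the main diagonal
#' @return class `line_histogram` (`kind = "diagonal"`): `counts`, a named
#'   integer vector `P(l)` indexed by length
#' @export
diagonal_histogram <- function(R, theiler = 1L) {
  M <- .rp_matrix(R)
  n <- nrow(M)
  if (!.is_count(theiler, min = 0L)) .fail_field("theiler", "must be >= 0")
  lens <- integer(0)
  offs <- seq(-(n - 1L), n - 1L)
  offs <- offs[abs(offs) >= theiler]
  for (d in offs) {
    i <- if (d >= 0) seq_len(n - d) else seq(1 - d, n)
    j <- i + d
    lens <- c(lens, .runs_of_ones(M[cbind(i, j)]))
  }
  .line_histogram(lens, "diagonal", theiler = theiler)
}

#' Histogram of vertical line lengths
#'
#' Maximal vertical runs of recurrence points per column; the main diagonal
#' is included (no exclusion is conventional for vertical structures).
#'
#' @param R a `recurrence_matrix` or 0/1 matrix
#' @return class `line_histogram` (`kind = "vertical"`)
#' @export
vertical_histogram <- function(R) {
  M <- .rp_matrix(R)
  lens <- unlist(lapply(seq_len(ncol(M)), function(j) .runs_of_ones(M[, j])))
  .line_histogram(lens, "vertical", theiler = NULL)
}

.line_histogram <- function(lens, kind, theiler = NULL) {
  counts <- if (length(lens)) {
    tab <- tabulate(lens)
    stats::setNames(as.integer(tab), seq_along(tab))[tab > 0]
  } else stats::setNames(integer(0), character(0))
  structure(list(kind = kind, counts = counts, theiler = theiler),
            class = "line_histogram")
}

# sum of l * P(l) for l in [lo, hi]
.hist_moment <- function(hist, lo = 1L, power = 1L) {
  l <- as.integer(names(hist$counts))
  sel <- l >= lo
  sum((l[sel]^power) * hist$counts[sel])
}

#' Recurrence quantification analysis
#'
#' The six standard RQA measures of a recurrence plot:
#' * `RR` — recurrence rate, `sum(R) / N^2` over the full matrix (main
#'   diagonal included, as in the defining double sum);
#' * `DET` — fraction of recurrence points on diagonal lines of length
#'   `>= l_min` (diagonal histogram with Theiler exclusion; denominator sums
#'   from `l = 1`);
#' * `LMAX` — longest diagonal line excluding the main diagonal (0 if none);
#' * `ENT` — Shannon entropy (natural log) of the diagonal length
#'   distribution `p(l)` for `l >= l_min`;
#' * `LAM` — fraction of recurrence points on vertical lines of length
#'   `>= v_min`;
#' * `TT` — trapping time, mean vertical line length for `v >= v_min`
#'   (0 with a flag when no such line exists).
#'
#' @param R a `recurrence_matrix` or 0/1 matrix
#' @param l_min minimum diagonal line length (default 2)
#' @param v_min minimum vertical line length (default 2)
#' @param theiler Theiler window for diagonal measures (default 1)
#' @return class `rqa_metrics`: `RR`, `DET`, `LMAX`, `ENT`, `LAM`, `TT`,
#'   plus `tt_defined`
#' @examples
#' rqa(matrix(1L, 4, 4))  # RR 1, DET 10/12, LMAX 3, ENT ln 2, LAM 1, TT 4
#' @export
rqa <- function(R, l_min = 2L, v_min = 2L, theiler = 1L) {
  M <- .rp_matrix(R)
  n <- nrow(M)
  if (!.is_count(l_min) || !.is_count(v_min))
    .fail_field("l_min/v_min", "must be positive integers")
  RR <- sum(M) / n^2
  dh <- diagonal_histogram(M, theiler = theiler)
  denom <- .hist_moment(dh, lo = 1L)
  num <- .hist_moment(dh, lo = l_min)
  DET <- if (denom > 0) num / denom else 0
  l <- as.integer(names(dh$counts))
  LMAX <- if (length(l)) max(l) else 0L
  Pl <- dh$counts[l >= l_min]
  ENT <- if (sum(Pl) > 0) {
    p <- Pl / sum(Pl)
    -sum(p * log(p))
  } else 0
  vh <- vertical_histogram(M)
  vdenom <- .hist_moment(vh, lo = 1L)
  vnum <- .hist_moment(vh, lo = v_min)
  LAM <- if (vdenom > 0) vnum / vdenom else 0
  v <- as.integer(names(vh$counts))
  nv <- sum(vh$counts[v >= v_min])
  tt_defined <- nv > 0
  TT <- if (tt_defined) vnum / nv else 0
  structure(list(RR = RR, DET = DET, LMAX = as.integer(LMAX), ENT = ENT,
                 LAM = LAM, TT = TT, tt_defined = tt_defined,
                 l_min = as.integer(l_min), v_min = as.integer(v_min),
                 theiler = as.integer(theiler)),
            class = "rqa_metrics")
}

#' @export
print.rqa_metrics <- function(x, ...) {
  cat(sprintf("RR %.4f  DET %.4f  LMAX %d  ENT %.4f  LAM %.4f  TT %.4f\n",
              x$RR, x$DET, x$LMAX, x$ENT, x$LAM, x$TT))
  invisible(x)
}

#' Segmented RQA before and after a change point
#'
#' Splits the correlation series at the change point and, within each
#' segment, computes RQA over sliding windows (length `window`, step
#' `stride`) of the series, reporting the per-metric mean and standard
#' deviation across windows plus the whole-segment value. This is the
#' windowed summary behind before/after comparisons with error bars.
#'
#' @param series a `correlation_series` or numeric vector
#' @param change_point a `change_point`, or a frame index
#' @param window sliding-window length in frames
#' @param stride window step (default `window %/% 2`)
#' @param epsilon,l_min,v_min,theiler recurrence parameters
#' @return class `segmented_rqa`: list with `before` and `after`, each
#'   holding `whole` (an `rqa_metrics`), `mean`, `sd` (named vectors over
#'   the six metrics), `n_windows`, `available`
#' @export
segmented_rqa <- function(series, change_point, window, stride = NULL,
                          epsilon = 0.02, l_min = 2L, v_min = 2L,
                          theiler = 1L) {
  r <- if (inherits(series, "correlation_series")) series$r else as.numeric(series)
  cut <- if (inherits(change_point, "change_point")) change_point$index
         else as.integer(change_point)
  n <- length(r)
  if (cut < 2L || cut > n - 1L)
    .fail_field("change_point", "must split the series into two nonempty parts")
  if (is.null(stride)) stride <- max(1L, window %/% 2L)
  if (!.is_count(window, min = 2L) || !.is_count(stride))
    .fail_field("window/stride", "must be positive integers (window >= 2)")
  seg <- function(rs) {
    len <- length(rs)
    whole <- if (len >= 2L)
      rqa(recurrence_matrix(rs, epsilon), l_min, v_min, theiler) else NULL
    if (len < window) {
      return(list(whole = whole, mean = NULL, sd = NULL, n_windows = 0L,
                  available = FALSE))
    }
    starts <- seq(1L, len - window + 1L, by = stride)
    mets <- c("RR", "DET", "LMAX", "ENT", "LAM", "TT")
    vals <- matrix(NA_real_, length(starts), length(mets),
                   dimnames = list(NULL, mets))
    for (i in seq_along(starts)) {
      sub <- rs[starts[i]:(starts[i] + window - 1L)]
      q <- rqa(recurrence_matrix(sub, epsilon), l_min, v_min, theiler)
      vals[i, ] <- c(q$RR, q$DET, q$LMAX, q$ENT, q$LAM, q$TT)
    }
    list(whole = whole,
         mean = colMeans(vals),
         sd = apply(vals, 2, function(col) if (length(col) > 1) stats::sd(col) else 0),
         n_windows = length(starts), available = TRUE)
  }
  structure(list(before = seg(r[seq_len(cut)]),
                 after = seg(r[(cut + 1L):n]),
                 window = as.integer(window), stride = as.integer(stride),
                 epsilon = epsilon, change_index = cut),
            class = "segmented_rqa")
}
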