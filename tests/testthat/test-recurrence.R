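test_that("recurrence_matrix: structure, boundary rule, brute-force oracle", {
  # constant series: all ones
  expect_true(all(recurrence_matrix(rep(0.5, 5))$R == 1L))
  # alternating series: parity structure
  R <- recurrence_matrix(rep(c(0, 1), 3), epsilon = 0.02)$R
  idx <- expand.grid(i = 1:6, j = 1:6)
  expect_true(all(R[cbind(idx$i, idx$j)] ==
                    as.integer((idx$i - idx$j) %% 2 == 0)))
  # boundary inclusive: distance exactly epsilon recurs
  expect_equal(recurrence_matrix(c(0, 0.02), epsilon = 0.02)$R,
               matrix(1L, 2, 2))
  expect_error(recurrence_matrix(c(0, 1), epsilon = 0), "epsilon")
  # random series vs O(N^2) double loop
  set.seed(31)
  for (i in 1:10) {
    r <- runif(12)
    eps <- runif(1, 0.01, 0.5)
    expect_identical(recurrence_matrix(r, eps)$R, oracle_recurrence(r, eps))
  }
})

test_that("line histograms match hand enumeration and run-length oracle", {
  # all-ones 4x4, theiler 1: six off-diagonals of lengths 3,3,2,2,1,1
  dh <- diagonal_histogram(matrix(1L, 4, 4), theiler = 1)
  expect_equal(dh$counts, c(`1` = 2L, `2` = 2L, `3` = 2L))
  # identity matrix: no off-diagonal lines at all
  expect_length(diagonal_histogram(diag(1L, 5), theiler = 1)$counts, 0)
  # vertical: all-ones N x N -> N columns of length N; identity -> N singles
  vh <- vertical_histogram(matrix(1L, 5, 5))
  expect_equal(vh$counts, c(`5` = 5L))
  expect_equal(vertical_histogram(diag(1L, 5))$counts, c(`1` = 5L))
  # random symmetric matrices vs the run-length oracle
  set.seed(55)
  for (i in 1:10) {
    M <- random_rp(10)
    dl <- oracle_diag_lengths(M, 1)
    got <- diagonal_histogram(M, theiler = 1)$counts
    want <- table(dl)
    expect_equal(as.integer(got), as.integer(want))
    expect_equal(names(got), names(want))
    vl <- oracle_vert_lengths(M)
    gotv <- vertical_histogram(M)$counts
    expect_equal(as.integer(gotv), as.integer(table(vl)))
  }
})

test_that("epsilon limits and monotonicity of RR", {
  set.seed(77)
  r <- runif(15)
  eps_grid <- sort(runif(8, 0.01, 1.2))
  rr <- vapply(eps_grid, function(e) rqa(recurrence_matrix(r, e)$R)$RR,
               numeric(1))
  expect_true(all(diff(rr) >= 0))
  # epsilon -> Inf limit (all-ones matrix). Note DET cannot reach 1 exactly:
  # the two corner diagonals always have length 1, so the supremum is
  # (n(n-1) - 2) / (n(n-1)); LAM does reach 1.
  q <- rqa(recurrence_matrix(r, 10)$R)
  n <- length(r)
  expect_equal(q$RR, 1)
  expect_equal(q$DET, (n * (n - 1) - 2) / (n * (n - 1)))
  expect_equal(q$LAM, 1)
  expect_identical(q$LMAX, n - 1L)
  expect_equal(q$TT, n)
})

test_that("periodic series put diagonal lines only at multiples of the period", {
  p <- 4; k <- 5
  r <- rep(seq(0, 0.9, length.out = p), k)  # exact period p, N = 20
  R <- recurrence_matrix(r, epsilon = 0.01)$R
  n <- length(r)
  for (d in 1:(n - 1)) {
    on_diag <- sum(R[cbind(1:(n - d), (1 + d):n)])
    if (d %% p == 0) expect_gt(on_diag, 0) else expect_equal(on_diag, 0)
  }
})

test_that("shuffling a periodic series decreases DET", {
  r <- rep(seq(0, 0.9, length.out = 5), 6)
  det0 <- rqa(recurrence_matrix(r, 0.05)$R)$DET
  n_lower <- 0
  for (seed in 1:20) {
    set.seed(seed)
    dets <- rqa(recurrence_matrix(sample(r), 0.05)$R)$DET
    if (dets < det0) n_lower <- n_lower + 1
  }
  expect_gte(n_lower, 18)
})

test_that("segmented_rqa contracts: null case and window collapse", {
  set.seed(90)
  r <- rep(c(0.8, 0.82, 0.84, 0.82), 20) + rnorm(80, 0, 0.002)
  # identical halves, no change injected: means differ < 1 within-segment sd
  sr <- segmented_rqa(r, change_point = 40L, window = 16, stride = 8)
  for (m in c("RR", "DET", "LAM")) {
    sdm <- max(sr$before$sd[m], sr$after$sd[m], 1e-6)
    expect_lt(abs(sr$before$mean[m] - sr$after$mean[m]), max(1e-6, sdm) * 1 +
                1e-9, label = m)
  }
  # window = segment length: stats collapse to whole-segment value, sd 0
  sr2 <- segmented_rqa(r, change_point = 40L, window = 40, stride = 5)
  expect_equal(sr2$before$n_windows, 1L)
  expect_equal(unname(sr2$before$sd), rep(0, 6))
  expect_equal(unname(sr2$before$mean["DET"]), sr2$before$whole$DET)
  # segment shorter than window: flagged unavailable
  sr3 <- segmented_rqa(r, change_point = 10L, window = 30)
  expect_false(sr3$before$available)
  expect_true(sr3$after$available)
})
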