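test_that("FC recovers exact correlations and flags degenerate rows", {
  t <- seq(0, 1, length.out = 50)
  x <- rbind(sin(2 * pi * t), sin(2 * pi * t), -sin(2 * pi * t))
  fc <- compute_fc(x)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_error(compute_fc(rbind(x, 0 * t)), "region\\(s\\) 4")
  expect_error(compute_fc(x[, 1:2]), "3 frames")
})

test_that("FC matches a brute-force pairwise covariance oracle", {
  set.seed(11)
  x <- matrix(rnorm(4 * 50), 4, 50)
  fc <- compute_fc(x)
  for (i in 1:4) for (j in 1:4) {
    mi <- mean(x[i, ]); mj <- mean(x[j, ])
    cov_ij <- sum((x[i, ] - mi) * (x[j, ] - mj)) / 49
    sd_i <- sqrt(sum((x[i, ] - mi)^2) / 49)
    sd_j <- sqrt(sum((x[j, ] - mj)^2) / 49)
    expect_equal(fc[i, j], cov_ij / (sd_i * sd_j), tolerance = 1e-12)
  }
})

test_that("FC is invariant to affine rescaling of a region's time course", {
  set.seed(12)
  x <- matrix(rnorm(5 * 60), 5, 60)
  y <- x; y[2, ] <- 3.7 * y[2, ] + 10
  expect_equal(unclass(compute_fc(x)), unclass(compute_fc(y)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("window length conversion floors seconds over TR", {
  expect_identical(window_len_from_seconds(60, 0.72), 83L)
  expect_identical(window_len_from_seconds(60, 3), 20L)
  expect_identical(window_len_from_seconds(60, 60), 1L)
  expect_error(window_len_from_seconds(0, 1), "positive")
})

test_that("FCD bookkeeping: 1200 frames with an 83-TR window give 1118 windows", {
  set.seed(13)
  fcd <- compute_fcd(matrix(rnorm(3 * 1200), 3), 83)
  expect_equal(dim(fcd), c(1118L, 1118L))
  expect_equal(diag(fcd), rep(1, 1118))
})

test_that("FCD matches a naive two-loop window oracle", {
  set.seed(7)
  x <- matrix(rnorm(5 * 40), 5, 40)
  fcd <- compute_fcd(x, 10)
  vecs <- sapply(1:31, function(s) {
    m <- cor(t(x[, s:(s + 9)]))
    v <- numeric(0)                               # row-major upper triangle
    for (i in 1:4) for (j in (i + 1):5) v <- c(v, m[i, j])
    v
  })
  oracle <- matrix(NA_real_, 31, 31)
  for (a in 1:31) for (b in 1:31) oracle[a, b] <- cor(vecs[, a], vecs[, b])
  expect_equal(unclass(fcd), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("windows identical up to the stride give an all-ones FCD", {
  period <- 5L
  base <- matrix(rnorm(3 * period), 3, period)
  x <- base[, rep(1:period, 8)]                   # periodic signal
  fcd <- compute_fcd(x, 10, stride = period)
  expect_equal(unclass(fcd), matrix(1, nrow(fcd), ncol(fcd)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("KS distance agrees with ECDF enumeration and stats::ks.test", {
  expect_equal(ks_distance(1:5, 1:5), 0)
  expect_equal(ks_distance(runif(1000), runif(1000, 2, 3)), 1)

  a <- c(0.1, 0.5, 0.9); b <- c(0.2, 0.6)
  # oracle: exhaustive sup over the 5 breakpoints
  breaks <- sort(c(a, b))
  sup <- max(sapply(breaks, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }))
  expect_equal(ks_distance(a, b), sup)

  set.seed(21)
  s1 <- rnorm(400); s2 <- rnorm(300, 0.3)
  expect_equal(ks_distance(s1, s2),
               unname(stats::ks.test(s1, s2)$statistic), tolerance = 1e-12)
})

test_that("KS distance is symmetric and bounded on random samples", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(5:50, 1)); b <- rnorm(sample(5:50, 1), sd = runif(1, 0.5, 2))
    d1 <- ks_distance(a, b); d2 <- ks_distance(b, a)
    expect_identical(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("realism cost components match independent single-purpose oracles", {
  set.seed(5)
  n <- 6
  mk_sym <- function() {
    m <- matrix(rnorm(n * n), n); m <- (m + t(m)) / 2; diag(m) <- 1; m
  }
  fc_s <- mk_sym(); fc_e <- mk_sym()
  fcd_s <- mk_sym(); fcd_e <- mk_sym()
  rc <- realism_cost(fc_s, fc_e, fcd_s, fcd_e)

  ut <- function(m) {                             # row-major upper triangle
    v <- numeric(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) v <- c(v, m[i, j])
    v
  }
  expect_equal(rc$corr_cost, 1 - cor(ut(fc_s), ut(fc_e)), tolerance = 1e-12)
  expect_equal(rc$mean_abs_diff, abs(mean(ut(fc_e)) - mean(ut(fc_s))),
               tolerance = 1e-12)
  expect_equal(rc$ks_cost, ks_distance(ut(fcd_s), ut(fcd_e)), tolerance = 1e-12)
  expect_equal(rc$total, rc$corr_cost + rc$mean_abs_diff + rc$ks_cost,
               tolerance = 1e-12)

  # self-comparison is exactly free; anticorrelation saturates the FC cost
  self <- realism_cost(fc_e, fc_e, fcd_e, fcd_e)
  expect_equal(self$total, 0)
  anti <- realism_cost(-fc_e, fc_e, fcd_e, fcd_e)
  expect_equal(anti$corr_cost, 2, tolerance = 1e-12)
})
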