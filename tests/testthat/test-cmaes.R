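test_that("child sampling honors shape, determinism and the degenerate limit", {
  st <- cma_init(rep(0, 10), 0.3, lambda = 100, mu = 10, seed = 4)
  ch <- sample_children(st)
  expect_equal(dim(ch), c(10L, 100L))
  expect_identical(ch, sample_children(st))

  tiny <- cma_init(rep(1, 6), 1e-12, lambda = 20, mu = 5, seed = 4)
  expect_lt(max(abs(sample_children(tiny) - 1)), 1e-9)
})

test_that("sampled children realize the requested covariance", {
  D <- 4
  A <- matrix(rnorm(D * D), D); C <- crossprod(A) / D + diag(D)
  st <- cma_init(rep(0, D), 0.5, lambda = 1e5, mu = 10, C = C, seed = 9)
  ch <- sample_children(st)
  emp <- tcrossprod(ch) / ncol(ch)
  target <- 0.25 * C
  expect_lt(norm(emp - target, "F") / norm(target, "F"), 0.05)
})

test_that("the distribution update is deterministic and contracts on the sphere", {
  f <- function(th) sum((th - 2)^2)
  st <- cma_init(rep(0, 10), 0.3, lambda = 100, mu = 10, seed = 1)
  d0 <- sqrt(sum((st$mean - 2)^2))
  for (e in 1:20) {
    ch <- sample_children(st)
    st <- update_distribution(st, ch, apply(ch, 2, f))
  }
  expect_lt(sqrt(sum((st$mean - 2)^2)), d0)

  st1 <- cma_init(rep(0, 3), 0.3, lambda = 30, mu = 5, seed = 2)
  ch <- sample_children(st1)
  costs <- apply(ch, 2, f <- function(th) sum(th^2))
  u1 <- update_distribution(st1, ch, costs)
  u2 <- update_distribution(st1, ch, costs)
  expect_identical(u1, u2)
})

test_that("the sphere optimum is recovered to 1e-3 within 200 epochs (D=10)", {
  set.seed(99)
  th_star <- rnorm(10)
  res <- cma_optimize(function(th) sum((th - th_star)^2), rep(0, 10),
                      step_size = 0.3, lambda = 100, mu = 10, epochs = 200,
                      seed = 1)
  expect_lt(sqrt(sum((res$best - th_star)^2)), 1e-3)
})

test_that("invalid children trigger the documented fallback rules", {
  st <- cma_init(rep(0, 4), 0.3, lambda = 12, mu = 6, seed = 3)
  ch <- sample_children(st)
  # fewer valid children than mu: all valid ones are used
  costs <- rep(Inf, 12); costs[c(2, 5)] <- c(1, 2)
  up <- update_distribution(st, ch, costs)
  expect_true(all(is.finite(up$mean)))
  expect_equal(up$epoch, 1L)
  # zero valid children: distribution kept, step size shrunk by 0.7
  up0 <- update_distribution(st, ch, rep(NA_real_, 12))
  expect_identical(up0$mean, st$mean)
  expect_identical(up0$C, st$C)
  expect_equal(up0$step_size, st$step_size * 0.7)
})
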