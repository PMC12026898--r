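test_that("coefficient expansion reduces to the homogeneous model without maps", {
  sc <- matrix(c(0, 1, 1, 0), 2)
  cn <- connectome(sc)                            # K = 0
  expect_equal(n_coefficients(0), 4L)
  p <- expand_coefficients(c(0.2, 0.15, 0.005, 1.2), cn)
  expect_equal(p$w_ee, rep(0.2, 2))
  expect_equal(p$w_ei, rep(0.15, 2))
  expect_equal(p$sigma, rep(0.005, 2))
  expect_equal(p$g, 1.2)
})

test_that("zero slopes give spatially uniform fields regardless of the maps", {
  cn <- fx_conn()                                 # K = 2
  theta <- rep(0, 10); theta[1] <- 1; theta[4] <- 0.1; theta[7] <- 0.01
  p <- expand_coefficients(theta, cn)
  expect_equal(p$w_ee, rep(1, 5))
})

test_that("the affine expansion matches an element-wise oracle", {
  cn <- fx_conn()
  set.seed(7)
  theta <- runif(10, -0.5, 0.5)
  p <- expand_coefficients(theta, cn, clamp = c(-1e6, 1e6),
                           g_clamp = c(-1e6, 1e6))
  # independent element-wise evaluation of the affine rule
  for (k in 1:5) {
    expect_equal(p$w_ee[k],
                 theta[1] + theta[2] * cn$covariates[k, 1] +
                   theta[3] * cn$covariates[k, 2], tolerance = 1e-14)
    expect_equal(p$w_ei[k],
                 theta[4] + theta[5] * cn$covariates[k, 1] +
                   theta[6] * cn$covariates[k, 2], tolerance = 1e-14)
    expect_equal(p$sigma[k],
                 theta[7] + theta[8] * cn$covariates[k, 1] +
                   theta[9] * cn$covariates[k, 2], tolerance = 1e-14)
  }
  expect_equal(p$g, theta[10])
})

test_that("length mismatches and clamping are reported", {
  cn <- fx_conn()
  expect_error(expand_coefficients(rep(0.1, 7), cn), "10 coefficients")
  p <- expand_coefficients(c(-5, 0, 0, 0.15, 0, 0, 0.005, 0, 0, -2), cn)
  expect_true(p$clamped)
  expect_true(p$degenerate)                       # whole w_EE field clamped
  expect_equal(p$w_ee, rep(1e-4, 5))
  expect_equal(p$g, 0)                            # G clamped to be non-negative
})
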