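consts <- fic_constants()

make_traj <- function(rates) {
  # minimal trajectory stub: constant rates, no burn-in
  structure(list(r_e = matrix(rates, nrow = length(rates), ncol = 4),
                 s_e = matrix(0.2, length(rates), 4),
                 s_i = matrix(0.1, length(rates), 4),
                 dt = 0.006, burn_in_steps = 0L),
            class = "neural_trajectory")
}

test_that("integration is deterministic under a seed and requires one", {
  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  t1 <- integrate_neural(p, cn, 5, burn_in_s = 1, seed = 11)
  t2 <- integrate_neural(p, cn, 5, burn_in_s = 1, seed = 11)
  t3 <- integrate_neural(p, cn, 5, burn_in_s = 1, seed = 12)
  expect_identical(t1$r_e, t2$r_e)
  expect_false(identical(t1$r_e, t3$r_e))
  expect_error(integrate_neural(p, cn, 5), "seed")
})

test_that("a noiseless trajectory started at the fixed point stays constant", {
  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  settle <- integrate_neural(p, cn, 50, burn_in_s = 0, seed = 1,
                             noise = FALSE)
  fp <- list(s_e = settle$s_e[, ncol(settle$s_e)],
             s_i = settle$s_i[, ncol(settle$s_i)])
  traj <- integrate_neural(p, cn, 10, burn_in_s = 0, seed = 1,
                           noise = FALSE, init = fp)
  expect_lt(max(abs(traj$s_e - fp$s_e)), 1e-9)
  expect_lt(max(abs(traj$s_i - fp$s_i)), 1e-9)
})

test_that("noiseless Euler error shrinks linearly with the step (order 1)", {
  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  init <- ficsurr:::default_initial_state(p, consts)
  init$s_e <- init$s_e + 0.03                    # start off equilibrium
  term <- function(dt) {
    tr <- integrate_neural(p, cn, 2, dt_s = dt, burn_in_s = 0, seed = 1,
                           noise = FALSE, init = init)
    c(tr$s_e[, ncol(tr$s_e)], tr$s_i[, ncol(tr$s_i)])
  }
  ref <- term(0.000075)
  err <- vapply(c(0.006, 0.003, 0.0015), function(dt) max(abs(term(dt) - ref)),
                numeric(1))
  expect_gt(err[1] / err[2], 1.5)                 # halving dt ~halves the error
  expect_lt(err[1] / err[2], 2.8)
  expect_gt(err[2] / err[3], 1.5)
  expect_lt(err[2] / err[3], 2.8)
})

test_that("gating variables never leave [0, 1] even under strong noise", {
  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  p$sigma <- rep(0.3, 5)                          # extreme noise amplitude
  traj <- integrate_neural(p, cn, 10, burn_in_s = 0, seed = 8)
  expect_true(all(traj$s_e >= 0 & traj$s_e <= 1))
  expect_true(all(traj$s_i >= 0 & traj$s_i <= 1))
})

test_that("calibration matches a brute-force bisection on w_IE (1-region)", {
  cn <- connectome(matrix(0, 2, 2))               # uncoupled = 1-region twice
  p <- expand_coefficients(c(0.21, 0.15, 0.005, 0), cn)
  cal <- calibrate_fic(p, cn, target_rate_hz = 3, tol = 1e-6)

  steady_rate <- function(w_ie) {
    q <- p; q$w_ie <- rep(w_ie, 2)
    tr <- integrate_neural(q, cn, 20, burn_in_s = 0, seed = 1, noise = FALSE)
    tr$r_e[1, ncol(tr$r_e)]
  }
  lo <- 0.1; hi <- 3
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (steady_rate(mid) > 3) lo <- mid else hi <- mid
  }
  expect_equal(cal$w_ie[1], (lo + hi) / 2, tolerance = 1e-4)
})

test_that("re-calibration restores the firing-rate band after a coupling change", {
  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  p$g <- p$g * 2                                  # perturb after calibration
  rates_off <- integrate_neural(p, cn, 10, burn_in_s = 2, seed = 2,
                                noise = FALSE)
  off <- mean_firing_rates(rates_off)
  expect_gt(max(abs(off - 3)), 0.05)              # rates moved off target
  p2 <- calibrate_fic(p, cn)
  rates_on <- mean_firing_rates(
    integrate_neural(p2, cn, 10, burn_in_s = 2, seed = 2, noise = FALSE))
  expect_true(all(rates_on >= 2.7 & rates_on <= 3.3))
})

test_that("the within-range gate implements the all-region band rule", {
  expect_true(check_within_range(make_traj(rep(3, 4)))$within)
  expect_false(check_within_range(make_traj(c(3, 3, 3, 3.4)))$within)
  set.seed(1)
  expect_true(check_within_range(make_traj(runif(6, 2.8, 3.2)))$within)
  # the mean rule tolerates single-region violations
  expect_true(check_within_range(make_traj(c(3, 3, 3, 3.4)),
                                 rule = "mean")$within)
})

test_that("E/I ratio is the ratio of temporal-mean gating variables", {
  tr <- make_traj(rep(3, 4))
  tr$s_i <- tr$s_e                                # identical signals
  expect_equal(compute_ei_ratio(tr)$ei, rep(1, 4))
  tr$s_e[] <- 0.2; tr$s_i[] <- 0.1
  expect_equal(compute_ei_ratio(tr)$ei, rep(2, 4))

  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  traj <- integrate_neural(p, cn, 5, burn_in_s = 1, seed = 3)
  ei <- compute_ei_ratio(traj)
  cols <- (traj$burn_in_steps + 2):ncol(traj$s_e)
  for (k in 1:5) {                                # two-pass oracle
    expect_equal(ei$ei[k],
                 (sum(traj$s_e[k, cols]) / length(cols)) /
                   (sum(traj$s_i[k, cols]) / length(cols)),
                 tolerance = 1e-12)
  }
  expect_equal(ei$cortical_mean, mean(ei$ei), tolerance = 1e-15)
})
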