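consts <- fic_constants()

test_that("regions decouple in the drift when global coupling is zero", {
  cn <- fx_conn()
  p <- expand_coefficients(default_true_theta(2), cn)
  p$g <- 0
  s_e <- runif(5, 0.1, 0.3); s_i <- runif(5, 0.02, 0.1)
  d0 <- fic_drift(s_e, s_i, p, cn, consts)
  s_e2 <- s_e; s_e2[3] <- s_e2[3] + 0.05          # perturb another region
  d1 <- fic_drift(s_e2, s_i, p, cn, consts)
  expect_equal(d1$ds_e[1], d0$ds_e[1], tolerance = 1e-15)
  expect_equal(d1$r_e[-3], d0$r_e[-3], tolerance = 1e-15)
})

test_that("drift vanishes at the fixed point located by a 1-region root-finder", {
  cn <- connectome(matrix(0, 2, 2))               # two disconnected regions
  theta <- c(0.21, 0.15, 0.005, 0)                # K = 0, G = 0
  p <- expand_coefficients(theta, cn)
  p$w_ie <- rep(0.7, 2)

  # oracle: bisection on S_E. At a fixed point, dS_E = 0 forces
  # r_E = S_E / (tau_E gamma (1 - S_E)); invert the f-I curve for the
  # required current and compare with the current implied by (S_E, S_I*),
  # where S_I* solves the inhibitory fixed point for that S_E.
  resid <- function(se) {
    r_needed <- se / (consts$tau_E * consts$gamma * (1 - se))
    I_needed <- uniroot(function(I) fi_rate(I, consts$a_E, consts$b_E,
                                            consts$d_E) - r_needed,
                        c(-1, 2), tol = 1e-15)$root
    si <- uniroot(function(s) {
      consts$tau_I * fi_rate(consts$W_I * consts$I_0 + 0.15 * se - s,
                             consts$a_I, consts$b_I, consts$d_I) - s
    }, c(0, 1), tol = 1e-15)$root
    I_actual <- consts$W_E * consts$I_0 + 0.21 * se - 0.7 * si
    I_actual - I_needed
  }
  se_star <- uniroot(resid, c(0.05, 0.5), tol = 1e-15)$root
  si_star <- uniroot(function(s) {
    consts$tau_I * fi_rate(consts$W_I * consts$I_0 + 0.15 * se_star - s,
                           consts$a_I, consts$b_I, consts$d_I) - s
  }, c(0, 1), tol = 1e-15)$root

  d <- fic_drift(rep(se_star, 2), rep(si_star, 2), p, cn, consts)
  expect_lt(max(abs(c(d$ds_e, d$ds_i))), 1e-10)
})

test_that("stronger feedback inhibition lowers the excitatory rate", {
  cn <- fx_conn()
  p <- expand_coefficients(default_true_theta(2), cn)
  s_e <- rep(0.16, 5); s_i <- rep(0.05, 5)
  p1 <- p; p1$w_ie <- rep(0.5, 5)
  p2 <- p; p2$w_ie <- rep(0.8, 5)
  r1 <- fic_drift(s_e, s_i, p1, cn, consts)$r_e
  r2 <- fic_drift(s_e, s_i, p2, cn, consts)$r_e
  expect_true(all(r2 < r1))
})

test_that("the compiled Euler step matches the R drift", {
  cn <- fx_conn()
  p <- calibrate_fic(expand_coefficients(default_true_theta(2), cn), cn)
  init <- ficsurr:::default_initial_state(p, consts)
  dt <- 0.006
  traj <- integrate_neural(p, cn, duration_s = dt * 3, dt_s = dt,
                           burn_in_s = 0, seed = 1, noise = FALSE,
                           init = init)
  d <- fic_drift(traj$s_e[, 1], traj$s_i[, 1], p, cn, consts)
  expect_equal(traj$s_e[, 2], pmin(1, pmax(0, traj$s_e[, 1] + d$ds_e * dt)),
               tolerance = 1e-14)
  expect_equal(traj$s_i[, 2], pmin(1, pmax(0, traj$s_i[, 1] + d$ds_i * dt)),
               tolerance = 1e-14)
  expect_equal(traj$r_e[, 1], d$r_e, tolerance = 1e-14)
})

test_that("non-finite states are rejected with the offending region", {
  cn <- fx_conn()
  p <- expand_coefficients(default_true_theta(2), cn)
  expect_error(fic_drift(c(0.1, NaN, 0.1, 0.1, 0.1), rep(0.05, 5), p, cn,
                         consts),
               "region\\(s\\) 2")
})
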