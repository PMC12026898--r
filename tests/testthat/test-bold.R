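test_that("constant neural drive yields a constant BOLD signal", {
  traj <- structure(list(
    s_e = matrix(0.16, 2, 20001), s_i = matrix(0.05, 2, 20001),
    r_e = matrix(3, 2, 20001), dt = 0.006, burn_in_steps = 0L),
    class = "neural_trajectory")
  bold <- neural_to_bold(traj, tr_s = 0.72)
  late <- bold$bold[, ceiling(0.8 * bold$n_frames):bold$n_frames]
  expect_lt(max(apply(late, 1, var)), 1e-8)
})

test_that("hemodynamics are regionally local", {
  base <- matrix(0.16, 3, 8001)
  pert <- base; pert[2, 3000:3500] <- 0.3         # impulse in region 2 only
  mk <- function(se) structure(list(s_e = se, dt = 0.006, burn_in_steps = 0L),
                               class = "neural_trajectory")
  b0 <- neural_to_bold(mk(base), 0.72)
  b1 <- neural_to_bold(mk(pert), 0.72)
  expect_identical(b0$bold[c(1, 3), ], b1$bold[c(1, 3), ])
  expect_gt(max(abs(b0$bold[2, ] - b1$bold[2, ])), 1e-4)
})

test_that("a 14.4-minute scan at TR 0.72 s yields 1200 frames", {
  n_steps <- as.integer(864 / 0.006)
  traj <- structure(list(s_e = matrix(0.16, 1, n_steps + 1), dt = 0.006,
                         burn_in_steps = 0L),
                    class = "neural_trajectory")
  bold <- neural_to_bold(traj, tr_s = 0.72)
  expect_equal(bold$n_frames, 1200L)
})

test_that("halving the integration step barely changes the BOLD frames", {
  t_end <- 24; f <- function(t) 0.16 + 0.02 * sin(2 * pi * t / 8)
  mk <- function(dt) {
    tt <- seq(0, t_end, by = dt)
    structure(list(s_e = matrix(f(tt), 1), dt = dt, burn_in_steps = 0L),
              class = "neural_trajectory")
  }
  b1 <- neural_to_bold(mk(0.006), 0.72)$bold
  b2 <- neural_to_bold(mk(0.003), 0.72)$bold
  expect_lt(max(abs(b1 - b2)) / max(abs(b1)), 1e-3)
})

test_that("a TR finer than the neural step is rejected", {
  traj <- structure(list(s_e = matrix(0.16, 1, 101), dt = 0.006,
                         burn_in_steps = 0L),
                    class = "neural_trajectory")
  expect_error(neural_to_bold(traj, tr_s = 0.001), "dt")
})
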