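# default initial state: noiseless operating point near the target rate
default_initial_state <- function(params, consts, target_rate = 3) {
  se <- consts$gamma * target_rate * consts$tau_E /
    (1 + consts$gamma * target_rate * consts$tau_E)
  si <- vapply(seq_len(params$n_regions), function(k) {
    inh_fixed_point(params$w_ei[k], params$w_ii[k], se, consts)
  }, numeric(1))
  list(s_e = rep(se, params$n_regions), s_i = si)
}

# inhibitory gating fixed point for a frozen excitatory gating value
inh_fixed_point <- function(w_ei, w_ii, s_e, consts) {
  f <- function(s) {
    consts$tau_I * fi_rate(consts$W_I * consts$I_0 + w_ei * s_e - w_ii * s,
                           consts$a_I, consts$b_I, consts$d_I) - s
  }
  uniroot(f, lower = 0, upper = 1, tol = 1e-12)$root
}

#' Integrate the stochastic neural dynamics
#'
#' Euler-Maruyama integration of the coupled gating equations:
#' `state <- state + drift * dt + sigma * sqrt(dt) * xi` with independent
#' standard-normal increments per region and population, gating clamped to
#' `[0, 1]` after every step. The trajectory includes the burn-in prefix
#' (flagged via `burn_in_steps`); statistics helpers ignore it. Identical
#' inputs and seed give a bit-identical trajectory.
#'
#' @param params `"fic_parameters"` (w_IE should come from [calibrate_fic()]).
#' @param conn A [connectome()].
#' @param duration_s Post-burn-in duration to simulate, seconds.
#' @param dt_s Euler step, seconds (default 0.006).
#' @param burn_in_s Burn-in discarded from statistics, seconds.
#' @param seed Integer seed (required: reproducibility contract).
#' @param consts Model constants.
#' @param noise If `FALSE`, integrate the deterministic drift only.
#' @param init Optional list(s_e, s_i) initial state; defaults to the
#'   noiseless operating point near 3 Hz.
#' @return Object of class `"neural_trajectory"`: matrices `s_e`, `s_i`,
#'   `r_e` (N x (steps+1), column 1 = initial state), `dt`, `burn_in_steps`.
#' @export
integrate_neural <- function(params, conn, duration_s, dt_s = 0.006,
                             burn_in_s = 60, seed, consts = fic_constants(),
                             noise = TRUE, init = NULL) {
  if (missing(seed)) abort("`seed` is required (reproducibility contract)")
  assert_scalar_number(dt_s, "dt_s"); assert_scalar_number(duration_s, "duration_s")
  if (dt_s <= 0) abort("`dt_s` must be positive")
  if (duration_s <= 0) abort("`duration_s` must be positive")
  n_steps <- as.integer(round((duration_s + burn_in_s) / dt_s))
  burn_in_steps <- as.integer(round(burn_in_s / dt_s))
  init <- init %||% default_initial_state(params, consts)
  sim <- cpp_integrate_neural(conn$sc, params$w_ee, params$w_ei, params$w_ie,
                              params$w_ii, params$sigma, params$g,
                              unclass(consts), dt_s, n_steps,
                              init$s_e, init$s_i, isTRUE(noise),
                              as.integer(seed))
  structure(
    list(s_e = sim$s_e, s_i = sim$s_i, r_e = sim$r_e,
         dt = dt_s, burn_in_steps = burn_in_steps,
         duration_s = duration_s, seed = seed),
    class = "neural_trajectory"
  )
}

# columns of the trajectory matrices after the burn-in prefix
post_burn_in_cols <- function(traj) {
  (traj$burn_in_steps + 2L):ncol(traj$r_e)
}

#' Per-region temporal-mean excitatory firing rates (post burn-in)
#' @param traj A `"neural_trajectory"`.
#' @return Length-N numeric vector, Hz.
#' @export
mean_firing_rates <- function(traj) {
  rowMeans(traj$r_e[, post_burn_in_cols(traj), drop = FALSE])
}

#' Physiological firing-rate gate
#'
#' A parameter set is "within range" when the simulated excitatory firing
#' rates lie inside the physiologically plausible band (default 2.7-3.3 Hz).
#' The default aggregation rule requires every region's temporal-mean rate to
#' lie in the band (`rule = "all"`); `rule = "mean"` gates on the
#' across-region mean instead.
#'
#' @param traj A `"neural_trajectory"`.
#' @param lo_hz,hi_hz Band edges, Hz.
#' @param rule `"all"` (default) or `"mean"`.
#' @return List with `within` (logical) and `mean_rates` (length-N, Hz).
#' @export
check_within_range <- function(traj, lo_hz = 2.7, hi_hz = 3.3,
                               rule = c("all", "mean")) {
  rule <- match.arg(rule)
  rates <- mean_firing_rates(traj)
  list(within = rates_within(rates, lo_hz, hi_hz, rule), mean_rates = rates)
}

#' Excitation/inhibition ratio map
#'
#' The regional E/I ratio is the ratio of the temporal average of the
#' excitatory gating variable S_E to that of the inhibitory gating variable
#' S_I, computed over the post-burn-in trajectory; `cortical_mean` is the
#' unweighted mean across regions.
#'
#' @param traj A `"neural_trajectory"`.
#' @return Object of class `"ei_ratio_map"`: list(`ei`, `cortical_mean`).
#' @export
compute_ei_ratio <- function(traj) {
  cols <- post_burn_in_cols(traj)
  me <- rowMeans(traj$s_e[, cols, drop = FALSE])
  mi <- rowMeans(traj$s_i[, cols, drop = FALSE])
  zero <- which(mi <= 0)
  if (length(zero)) {
    abort(sprintf("temporal-mean S_I is zero in region(s) %s",
                  paste(zero, collapse = ", ")))
  }
  structure(list(ei = me / mi, cortical_mean = mean(me / mi)),
            class = "ei_ratio_map")
}

#' @export
tidy.ei_ratio_map <- function(x, ...) {
  tibble(region = seq_along(x$ei), ei_ratio = x$ei)
}

#' Feedback inhibition control: calibrate w_IE to a target firing rate
#'
#' Sets the inhibitory-to-excitatory weights so that every region's
#' noiseless temporal-mean excitatory rate sits at `target_rate_hz`
#' (the defining property of the FIC model). w_IE is initialized from the
#' analytic current balance at the homogeneous target operating point, then
#' refined by damped fixed-point sweeps: integrate the noiseless dynamics,
#' measure the tail-mean rate of each sweep, and update
#' `w_ie <- w_ie + eta * (mean_rate - target)` per region.
#'
#' @param params `"fic_parameters"` from [expand_coefficients()].
#' @param conn A [connectome()].
#' @param target_rate_hz Target excitatory rate, Hz, inside (0, 50).
#' @param consts Model constants.
#' @param dt_s Euler step for the calibration sweeps, seconds.
#' @param eta Damping gain of the w_IE update (nA s).
#' @param tol Convergence tolerance on |mean rate - target|, Hz.
#' @param max_sweeps Sweep budget before declaring non-convergence.
#' @param sweep_s Length of each noiseless sweep, seconds (the second half
#'   is the measurement window).
#' @param confirm_s Length of the confirmation integration run once the
#'   sweep residual meets `tol`, seconds. Short sweeps can sit on an
#'   unstable operating point without leaving it; convergence is only
#'   declared if the rates also hold the target over this longer horizon.
#' @return `params` with calibrated `w_ie` and `calibrated = TRUE`; the
#'   sweep diagnostics are attached as attribute `"calibration"`.
#'   Non-convergence raises a condition of class
#'   `"ficsurr_calibration_error"` carrying the per-region rate residuals.
#' @export
calibrate_fic <- function(params, conn, target_rate_hz = 3,
                          consts = fic_constants(), dt_s = 0.006,
                          eta = 0.05, tol = 0.05, max_sweeps = 200,
                          sweep_s = 2, confirm_s = 12) {
  if (target_rate_hz <= 0 || target_rate_hz >= 50) {
    abort("`target_rate_hz` must lie in (0, 50) Hz")
  }
  se_star <- consts$gamma * target_rate_hz * consts$tau_E /
    (1 + consts$gamma * target_rate_hz * consts$tau_E)
  I_E_star <- fi_rate_inverse(target_rate_hz, consts$a_E, consts$b_E, consts$d_E)
  si_star <- vapply(seq_len(params$n_regions), function(k) {
    inh_fixed_point(params$w_ei[k], params$w_ii[k], se_star, consts)
  }, numeric(1))
  w_ie0 <- (consts$W_E * consts$I_0 + params$w_ee * se_star +
              params$g * consts$J_NMDA * rowSums(conn$sc) * se_star -
              I_E_star) / si_star
  w_ie0 <- pmax(w_ie0, 1e-4)
  res <- cpp_calibrate_fic(conn$sc, params$w_ee, params$w_ei, w_ie0,
                           params$w_ii, params$g, unclass(consts), dt_s,
                           as.integer(round(sweep_s / dt_s)),
                           eta, target_rate_hz, tol, as.integer(max_sweeps),
                           rep(se_star, params$n_regions), si_star,
                           as.integer(round(confirm_s / dt_s)))
  if (!res$converged) {
    abort(
      sprintf("FIC calibration did not converge within %d sweeps (worst residual %.3g Hz)",
              max_sweeps, max(abs(res$residuals))),
      class = "ficsurr_calibration_error",
      residuals = res$residuals
    )
  }
  params$w_ie <- as.numeric(res$w_ie)
  params$calibrated <- TRUE
  attr(params, "calibration") <- list(sweeps = res$sweeps,
                                      mean_rates = as.numeric(res$mean_rates),
                                      residuals = as.numeric(res$residuals))
  params
}
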