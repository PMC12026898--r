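#' Run configuration
#'
#' Collects every tunable of the simulation/evaluation pipeline in one
#' validated document. Unknown keys are rejected; the content hash is
#' recorded in output artifacts so a run can be re-created bit-identically.
#'
#' @param dt_s Euler step of the neural (and hemodynamic) integration, s.
#' @param burn_in_s Discarded initial segment, s.
#' @param duration_s Post-burn-in simulated scan length, s.
#' @param tr_s BOLD repetition time, s.
#' @param window_s FCD sliding-window length, s.
#' @param rate_lo_hz,rate_hi_hz Physiological firing-rate band, Hz.
#' @param target_rate_hz FIC calibration target rate, Hz.
#' @param range_rule Within-range aggregation rule, `"all"` or `"mean"`.
#' @param calib_eta,calib_tol,calib_max_sweeps,calib_sweep_s Calibration
#'   scheme tunables (see [calibrate_fic()]).
#' @param lambda,mu CMA-ES population and parent sizes.
#' @param cma_step_size Initial CMA-ES step size as a fraction of each
#'   coefficient's box range.
#' @param gate_threshold Surrogate classifier decision threshold.
#' @param fcd_quantiles Length of the FCD quantile featurization.
#' @return Named list of class `"run_config"` with attribute `"hash"`.
#' @export
run_config <- function(dt_s = 0.006, burn_in_s = 60, duration_s = 864,
                       tr_s = 0.72, window_s = 60,
                       rate_lo_hz = 2.7, rate_hi_hz = 3.3,
                       target_rate_hz = 3, range_rule = "all",
                       calib_eta = 0.05, calib_tol = 0.05,
                       calib_max_sweeps = 200, calib_sweep_s = 2,
                       lambda = 100L, mu = 10L, cma_step_size = 0.3,
                       gate_threshold = 0.5, fcd_quantiles = 100L) {
  cfg <- list(dt_s = dt_s, burn_in_s = burn_in_s, duration_s = duration_s,
              tr_s = tr_s, window_s = window_s,
              rate_lo_hz = rate_lo_hz, rate_hi_hz = rate_hi_hz,
              target_rate_hz = target_rate_hz, range_rule = range_rule,
              calib_eta = calib_eta, calib_tol = calib_tol,
              calib_max_sweeps = calib_max_sweeps, calib_sweep_s = calib_sweep_s,
              lambda = as.integer(lambda), mu = as.integer(mu),
              cma_step_size = cma_step_size,
              gate_threshold = gate_threshold,
              fcd_quantiles = as.integer(fcd_quantiles))
  for (nm in c("dt_s", "duration_s", "tr_s", "window_s", "target_rate_hz")) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be positive", nm))
  }
  if (cfg$rate_lo_hz >= cfg$rate_hi_hz) abort("rate band is empty")
  structure(cfg, class = c("run_config", "list"),
            hash = rlang::hash(cfg))
}

# rebuild a config with some fields replaced (revalidates and rehashes)
config_update <- function(config, ...) {
  args <- utils::modifyList(unclass(config), list(...))
  do.call(run_config, args)
}

#' Micro-benchmark configuration
#'
#' The study conditions used for the package's synthetic micro experiments
#' (documented in the methods vignette): 5-10 region connectomes, 259.2 s
#' scans at TR 0.72 s (360 frames), a 30 s FCD window (41 TRs), 20 s
#' burn-in, 6 ms Euler step. The scan length keeps the finite-sample cost
#' noise floor (same coefficients, different noise realizations) below 0.5.
#'
#' @param ... Overrides passed on to [run_config()].
#' @return A `"run_config"`.
#' @export
micro_config <- function(...) {
  defaults <- list(duration_s = 259.2, burn_in_s = 20, window_s = 30,
                   tr_s = 0.72, dt_s = 0.006)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(run_config, defaults)
}
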