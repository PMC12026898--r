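#' Simulate a full scan in one fused pass
#'
#' Runs the stochastic neural integration and the hemodynamic forward model
#' together, returning the BOLD series plus the post-burn-in trajectory
#' means (firing rates for the physiological gate, gating means for the E/I
#' ratio) without materializing the full neural trajectory. The path is
#' step-for-step identical to [integrate_neural()] followed by
#' [neural_to_bold()] under the same seed; this entry point simply avoids
#' the trajectory storage, which matters inside optimization loops
#' evaluating thousands of candidates.
#'
#' @param params Calibrated `"fic_parameters"`.
#' @param conn A [connectome()].
#' @param config A [run_config()] (supplies duration, burn-in, dt, TR).
#' @param seed Integer seed.
#' @param consts,hconsts Model and hemodynamic constants.
#' @param noise If `FALSE`, integrate the deterministic drift only.
#' @return List with `bold` (a `"bold_series"`), `mean_rates`, `mean_se`,
#'   `mean_si` (length-N post-burn-in temporal means).
#' @export
simulate_scan <- function(params, conn, config = run_config(), seed,
                          consts = fic_constants(),
                          hconsts = hemo_constants(), noise = TRUE) {
  if (missing(seed)) abort("`seed` is required (reproducibility contract)")
  n_steps <- as.integer(round((config$duration_s + config$burn_in_s) / config$dt_s))
  burn_in_steps <- as.integer(round(config$burn_in_s / config$dt_s))
  init <- default_initial_state(params, consts)
  sim <- cpp_simulate_scan(conn$sc, params$w_ee, params$w_ei, params$w_ie,
                           params$w_ii, params$sigma, params$g,
                           unclass(consts), config$dt_s, n_steps,
                           burn_in_steps, init$s_e, init$s_i, isTRUE(noise),
                           as.integer(seed),
                           config$tr_s, hconsts$kappa, hconsts$gamma_h,
                           hconsts$tau_h, hconsts$alpha, hconsts$rho,
                           hconsts$V0, hconsts$k1, hconsts$k2, hconsts$k3)
  list(
    bold = structure(list(bold = sim$bold, tr_s = config$tr_s,
                          n_frames = ncol(sim$bold)),
                     class = "bold_series"),
    mean_rates = as.numeric(sim$mean_r),
    mean_se = as.numeric(sim$mean_se),
    mean_si = as.numeric(sim$mean_si)
  )
}

# gate rule shared by check_within_range() and the evaluators
rates_within <- function(rates, lo_hz, hi_hz, rule = "all") {
  switch(rule,
    all = all(rates >= lo_hz & rates <= hi_hz),
    mean = mean(rates) >= lo_hz && mean(rates) <= hi_hz,
    abort(sprintf("unknown within-range rule: %s", rule))
  )
}
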