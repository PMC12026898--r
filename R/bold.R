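#' Hemodynamic forward model: neural activity to BOLD
#'
#' Drives a per-region Balloon-Windkessel model (vasodilatory signal, blood
#' inflow, venous volume, deoxyhemoglobin content) with the excitatory
#' synaptic gating variable S_E, Euler-integrated at the neural step, then
#' applies the nonlinear BOLD readout
#' `y = 100 V0 (k1(1-q) + k2(1-q/v) + k3(1-v))` and decimates to one frame
#' per TR. Hemodynamics are regionally local and deterministic given the
#' trajectory; the neural burn-in is discarded and no additional frames are
#' dropped.
#'
#' @param traj A `"neural_trajectory"` from [integrate_neural()].
#' @param tr_s Repetition time, seconds (must be >= the neural step).
#' @param hconsts Hemodynamic constants ([hemo_constants()]).
#' @return Object of class `"bold_series"`: `bold` (N x T_bold matrix, %
#'   signal change), `tr_s`, `n_frames` = `floor(duration_s / tr_s)`.
#' @export
neural_to_bold <- function(traj, tr_s, hconsts = hemo_constants()) {
  assert_scalar_number(tr_s, "tr_s")
  if (traj$dt > tr_s) abort("the neural step `dt` must not exceed `tr_s`")
  bold <- cpp_balloon_bold(traj$s_e, traj$dt, traj$burn_in_steps, tr_s,
                           hconsts$kappa, hconsts$gamma_h, hconsts$tau_h,
                           hconsts$alpha, hconsts$rho, hconsts$V0,
                           hconsts$k1, hconsts$k2, hconsts$k3)
  if (any(!is.finite(bold))) abort("non-finite BOLD signal")
  structure(list(bold = bold, tr_s = tr_s, n_frames = ncol(bold)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d regions x %d frames, TR %.3g s\n",
              nrow(x$bold), x$n_frames, x$tr_s))
  invisible(x)
}

# accept a bold_series or a plain regions-x-time matrix
as_bold_matrix <- function(bold) {
  if (inherits(bold, "bold_series")) bold$bold
  else if (is.matrix(bold)) bold
  else abort("expected a `bold_series` or a regions x time matrix")
}
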