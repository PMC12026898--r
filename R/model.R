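#' Population transfer function of the mean-field reduction
#'
#' The sigmoidal frequency-current curve `r(I) = (aI - b) / (1 - exp(-d(aI - b)))`
#' mapping input current (nA) to population firing rate (Hz). The removable
#' singularity at `aI = b` is evaluated as its limit `1/d`.
#'
#' @param I Input current(s), nA.
#' @param a Gain (nC^-1).
#' @param b Threshold (Hz).
#' @param d Curvature (s).
#' @return Firing rate(s), Hz.
#' @export
fi_rate <- function(I, a, b, d) {
  x <- a * I - b
  out <- x / (1 - exp(-d * x))
  out[abs(x) < 1e-9] <- 1 / d
  out
}

# inverse of fi_rate on the increasing branch (scalar), via root finding
fi_rate_inverse <- function(r, a, b, d) {
  uniroot(function(I) fi_rate(I, a, b, d) - r,
          lower = -2, upper = 4, tol = 1e-12)$root
}

#' Deterministic drift of the FIC gating equations
#'
#' Evaluates the noiseless right-hand side of the coupled excitatory and
#' inhibitory gating equations at a given state. Per region k:
#' \deqn{I_E = W_E I_0 + w_{EE} S_E + G J_{NMDA} \sum_j SC_{kj} S_{E,j} - w_{IE} S_I}
#' \deqn{I_I = W_I I_0 + w_{EI} S_E - w_{II} S_I}
#' \deqn{dS_E/dt = -S_E/\tau_E + (1 - S_E)\gamma\, r_E(I_E)}
#' \deqn{dS_I/dt = -S_I/\tau_I + r_I(I_I)}
#' Inter-regional input enters only the excitatory current (regions are
#' coupled through excitatory connections).
#'
#' @param s_e,s_i Length-N state vectors of gating variables in `[0, 1]`.
#' @param params [expand_coefficients()] output (w_IE must be set for a
#'   calibrated model, but any positive placeholder is accepted).
#' @param conn A [connectome()].
#' @param consts Model constants ([fic_constants()]).
#' @return List with `ds_e`, `ds_i` (gating derivatives, s^-1) and the
#'   instantaneous population rates `r_e`, `r_i` (Hz).
#' @export
fic_drift <- function(s_e, s_i, params, conn, consts = fic_constants()) {
  n <- conn$n_regions
  if (length(s_e) != n || length(s_i) != n) abort("state vectors must have length N")
  bad <- which(!is.finite(s_e) | !is.finite(s_i))
  if (length(bad)) {
    abort(sprintf("non-finite state in region(s) %s",
                  paste(bad, collapse = ", ")))
  }
  coupling <- as.vector(conn$sc %*% s_e)
  I_E <- consts$W_E * consts$I_0 + params$w_ee * s_e +
    params$g * consts$J_NMDA * coupling - params$w_ie * s_i
  I_I <- consts$W_I * consts$I_0 + params$w_ei * s_e - params$w_ii * s_i
  r_e <- fi_rate(I_E, consts$a_E, consts$b_E, consts$d_E)
  r_i <- fi_rate(I_I, consts$a_I, consts$b_I, consts$d_I)
  list(
    ds_e = -s_e / consts$tau_E + (1 - s_e) * consts$gamma * r_e,
    ds_i = -s_i / consts$tau_I + r_i,
    r_e = r_e, r_i = r_i
  )
}
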