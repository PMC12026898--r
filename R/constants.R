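#' Biophysical constants of the FIC mean-field model
#'
#' Loads the fixed constants of the reduced Wong-Wang excitatory/inhibitory
#' mean-field model (transfer-function parameters, synaptic time constants,
#' kinetic rate, NMDA coupling, background currents) from a versioned YAML
#' file. The defaults are the Deco-2014 feedback-inhibition-control values;
#' an alternative transcription can be supplied via `file` without touching
#' any model code.
#'
#' @param file Path to a YAML constants file. Defaults to the file shipped
#'   with the package.
#' @return A named list of class `"fic_constants"`. Units: currents nA,
#'   rates Hz, times s.
#' @export
fic_constants <- function(file = NULL) {
  file <- file %||% system.file("extdata", "fic_constants.yaml", package = "ficsurr")
  vals <- yaml::read_yaml(file)
  needed <- c("a_E", "b_E", "d_E", "a_I", "b_I", "d_I", "tau_E", "tau_I",
              "gamma", "J_NMDA", "I_0", "W_E", "W_I", "w_II")
  missing <- setdiff(needed, names(vals))
  if (length(missing)) {
    abort(paste0("constants file lacks: ", paste(missing, collapse = ", ")))
  }
  structure(vals, class = c("fic_constants", "list"))
}

#' Balloon-Windkessel hemodynamic constants
#'
#' Loads the hemodynamic forward-model constants (vasodilatory decay, flow
#' feedback, transit time, stiffness exponent, resting oxygen extraction and
#' volume fraction, BOLD readout weights) from a versioned YAML file; the
#' defaults are the classical Friston-2003 values.
#'
#' @param file Path to a YAML constants file (default: shipped file).
#' @return A named list of class `"hemo_constants"`.
#' @export
hemo_constants <- function(file = NULL) {
  file <- file %||% system.file("extdata", "hemo_constants.yaml", package = "ficsurr")
  vals <- yaml::read_yaml(file)
  needed <- c("kappa", "gamma_h", "tau_h", "alpha", "rho", "V0", "k1", "k2", "k3")
  missing <- setdiff(needed, names(vals))
  if (length(missing)) {
    abort(paste0("constants file lacks: ", paste(missing, collapse = ", ")))
  }
  if (vals$alpha <= 0 || vals$alpha > 1) abort("alpha must lie in (0, 1]")
  structure(vals, class = c("hemo_constants", "list"))
}
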