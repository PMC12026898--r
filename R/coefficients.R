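#' Number of heterogeneous coefficients for K covariate maps
#'
#' The three spatially heterogeneous parameter fields (w_EE, w_EI, sigma)
#' each take an intercept plus one slope per covariate map, and the global
#' coupling G adds one more: `3 * (K + 1) + 1` coefficients in total
#' (K = 2 gives the 10-dimensional search space).
#'
#' @param n_covariates Number of covariate maps K.
#' @return Integer coefficient count.
#' @export
n_coefficients <- function(n_covariates) {
  3L * (as.integer(n_covariates) + 1L) + 1L
}

# names for a coefficient vector, e.g. wEE_0, wEE_1, ..., G
coef_names <- function(n_covariates) {
  K <- n_covariates
  blk <- function(p) paste0(p, "_", 0:K)
  c(blk("wEE"), blk("wEI"), blk("sigma"), "G")
}

#' Default search bounds for the heterogeneous coefficients
#'
#' Box bounds used to initialize the CMA-ES search distribution (mean drawn
#' uniformly inside the box, per-coordinate scale 0.3 of the box range) and
#' to document the plausible coefficient ranges. Intercept ranges span the
#' stable low-recurrence regime up to strengths where feedback inhibition is
#' required to hold the excitatory population near its target rate; the
#' noise-amplitude range spans quiet to strongly fluctuating dynamics.
#' Covariate maps are z-scored, so slope bounds are a +/-30% fraction of the
#' corresponding intercept range.
#'
#' @param n_covariates Number of covariate maps K.
#' @param w_ee_range,w_ei_range,sigma_range,g_range Length-2 numeric ranges
#'   for the intercepts and for G (model units: nA, nA, nA s^-1/2, unitless).
#' @return List with numeric vectors `lower`, `upper` (named, length
#'   `n_coefficients(K)`).
#' @export
default_coef_bounds <- function(n_covariates = 2,
                                w_ee_range = c(0.05, 0.6),
                                w_ei_range = c(0.05, 0.4),
                                sigma_range = c(5e-4, 0.05),
                                g_range = c(0, 3)) {
  K <- n_covariates
  blk <- function(rng) {
    slope <- 0.3 * diff(rng)
    list(lower = c(rng[1], rep(-slope, K)), upper = c(rng[2], rep(slope, K)))
  }
  b1 <- blk(w_ee_range); b2 <- blk(w_ei_range); b3 <- blk(sigma_range)
  lower <- c(b1$lower, b2$lower, b3$lower, g_range[1])
  upper <- c(b1$upper, b2$upper, b3$upper, g_range[2])
  names(lower) <- names(upper) <- coef_names(K)
  list(lower = lower, upper = upper)
}

#' Expand heterogeneous coefficients into per-region model parameters
#'
#' Maps the coefficient vector theta = (a_wEE, b_wEE 1..K, a_wEI, b_wEI 1..K,
#' a_sigma, b_sigma 1..K, G) onto per-region parameter vectors through the
#' affine rule `w[k] = a + sum_j b_j * covariate_j[k]`, then clamps each
#' per-region value into `clamp` and G into `g_clamp` (CMA-ES proposals are
#' unbounded Gaussians, so clamping keeps candidates in the model's domain).
#' The inhibitory-to-excitatory weight w_IE is not part of theta: it is set
#' later by [calibrate_fic()] and initialized to 1 here; w_II is the fixed
#' constant from the model constants file.
#'
#' @param theta Numeric coefficient vector of length `3 * (K + 1) + 1`.
#' @param conn A [connectome()].
#' @param consts Model constants ([fic_constants()]); supplies w_II.
#' @param clamp Length-2 range for per-region w_EE, w_EI, sigma values.
#' @param g_clamp Length-2 range for G.
#' @return An object of class `"fic_parameters"`: list with length-N vectors
#'   `w_ee`, `w_ei`, `w_ie`, `w_ii`, `sigma`, scalar `g`, `n_regions`, flags
#'   `clamped` (any value hit a bound) and `calibrated`.
#' @export
expand_coefficients <- function(theta, conn, consts = fic_constants(),
                                clamp = c(1e-4, 10), g_clamp = c(0, 10)) {
  K <- ncol(conn$covariates)
  D <- n_coefficients(K)
  if (length(theta) != D) {
    abort(sprintf("theta has length %d but %d coefficients are required for K=%d covariate maps",
                  length(theta), D, K))
  }
  n <- conn$n_regions
  X <- cbind(1, conn$covariates)           # N x (K+1) design of the affine rule
  field <- function(i0) as.vector(X %*% theta[i0 + 0:K])
  w_ee_raw <- field(1L)
  w_ei_raw <- field(K + 2L)
  sigma_raw <- field(2L * K + 3L)
  g_raw <- theta[D]
  cl <- function(v, r) pmin(r[2], pmax(r[1], v))
  w_ee <- cl(w_ee_raw, clamp); w_ei <- cl(w_ei_raw, clamp)
  sigma <- cl(sigma_raw, clamp); g <- cl(g_raw, g_clamp)
  clamped_frac <- mean(c(w_ee != w_ee_raw, w_ei != w_ei_raw,
                         sigma != sigma_raw, g != g_raw))
  degenerate <- all(w_ee != w_ee_raw) || all(w_ei != w_ei_raw) ||
    all(sigma != sigma_raw)
  structure(
    list(w_ee = w_ee, w_ei = w_ei, w_ie = rep(1, n),
         w_ii = rep(consts$w_II, n), sigma = sigma, g = g,
         n_regions = n, theta = as.numeric(theta),
         clamped = clamped_frac > 0, degenerate = degenerate,
         calibrated = FALSE),
    class = "fic_parameters"
  )
}

#' @export
print.fic_parameters <- function(x, ...) {
  cat(sprintf("<fic_parameters> N=%d, G=%.3f, %scalibrated\n",
              x$n_regions, x$g, if (x$calibrated) "" else "not "))
  cat(sprintf("  w_EE %.3g..%.3g  w_EI %.3g..%.3g  sigma %.3g..%.3g  w_IE %.3g..%.3g\n",
              min(x$w_ee), max(x$w_ee), min(x$w_ei), max(x$w_ei),
              min(x$sigma), max(x$sigma), min(x$w_ie), max(x$w_ie)))
  invisible(x)
}
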