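#' Construct a connectome
#'
#' Bundles a structural connectivity (SC) matrix with optional per-region
#' spatial covariate maps used by the heterogeneous parameterization. The SC
#' must be symmetric (tolerance 1e-10), non-negative, with a zero diagonal.
#'
#' @param sc N x N numeric matrix of structural connection weights
#'   (arbitrary streamline-weight units).
#' @param covariates Optional N x K matrix (or length-N vector) of spatial
#'   covariate maps, one column per map. `NULL` means no maps (homogeneous
#'   parameterization).
#' @param region_labels Optional character vector of length N.
#' @return An object of class `"connectome"` with fields `sc`, `n_regions`,
#'   `covariates` (N x K matrix, K possibly 0) and `region_labels`.
#' @export
connectome <- function(sc, covariates = NULL, region_labels = NULL) {
  if (!is.matrix(sc) || !is.numeric(sc)) abort("`sc` must be a numeric matrix")
  n <- nrow(sc)
  if (ncol(sc) != n) abort("`sc` must be square")
  if (n < 2) abort("a connectome needs at least 2 regions")
  if (anyNA(sc) || any(!is.finite(sc))) abort("`sc` must be finite")
  if (max(abs(sc - t(sc))) > 1e-10) abort("`sc` must be symmetric (tolerance 1e-10)")
  if (any(diag(sc) != 0)) abort("`sc` must have a zero diagonal")
  if (any(sc < 0)) abort("`sc` entries must be non-negative")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    if (is.vector(covariates)) covariates <- matrix(covariates, ncol = 1)
    if (nrow(covariates) != n) {
      abort(sprintf("covariate maps have %d rows but the SC has %d regions",
                    nrow(covariates), n))
    }
    if (anyNA(covariates) || any(!is.finite(covariates))) {
      abort("covariate maps must be finite")
    }
  }
  if (!is.null(region_labels) && length(region_labels) != n) {
    abort("`region_labels` must have one entry per region")
  }
  structure(
    list(sc = sc, n_regions = n, covariates = covariates,
         region_labels = region_labels),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d regions, %d covariate map(s)\n",
              x$n_regions, ncol(x$covariates)))
  cat(sprintf("  SC weights: [%.3g, %.3g], density %.2f\n",
              min(x$sc), max(x$sc),
              mean(x$sc[upper.tri(x$sc)] > 0)))
  invisible(x)
}
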