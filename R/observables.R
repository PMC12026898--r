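#' Static functional connectivity
#'
#' Pairwise Pearson correlation of regional BOLD time courses over all
#' frames.
#'
#' @param bold A `"bold_series"` or a regions x time numeric matrix.
#' @return N x N correlation matrix of class `"fc_matrix"` with attribute
#'   `n_frames_used`.
#' @export
compute_fc <- function(bold) {
  x <- as_bold_matrix(bold)
  if (ncol(x) < 3) abort("need at least 3 frames to compute FC")
  v <- apply(x, 1, var)
  flat <- which(v == 0)
  if (length(flat)) {
    abort(sprintf("zero-variance time course in region(s) %s",
                  paste(flat, collapse = ", ")))
  }
  fc <- cor(t(x))
  attr(fc, "n_frames_used") <- ncol(x)
  class(fc) <- c("fc_matrix", class(fc))
  fc
}

#' Sliding-window length in TRs for a window given in seconds
#'
#' `floor(window_s / tr_s)`: a 60-second window is 83 TRs at TR 0.72 s and
#' 20 TRs at TR 3.0 s.
#'
#' @param window_s Window length, seconds.
#' @param tr_s Repetition time, seconds.
#' @return Integer number of TRs.
#' @export
window_len_from_seconds <- function(window_s, tr_s) {
  if (window_s <= 0 || tr_s <= 0) abort("window and TR must be positive")
  as.integer(floor(window_s / tr_s + 1e-9))
}

#' Functional connectivity dynamics
#'
#' Slides a window of `window_len_tr` frames along the scan (stride 1 frame
#' by default), computes the FC matrix within each window, vectorizes its
#' strictly-upper-triangular entries in fixed row-major order, and correlates
#' the window vectors pairwise. With stride 1 a scan of T frames yields
#' `W = T - w + 1` windows (1200 frames, w = 83: 1118 windows).
#'
#' @param bold A `"bold_series"` or regions x time matrix.
#' @param window_len_tr Window length in frames.
#' @param stride Window stride in frames (default 1).
#' @return W x W correlation matrix of class `"fcd_matrix"` with attributes
#'   `window_len_tr` and `stride`.
#' @export
compute_fcd <- function(bold, window_len_tr, stride = 1L) {
  x <- as_bold_matrix(bold)
  n <- nrow(x)
  Tt <- ncol(x)
  w <- as.integer(window_len_tr)
  if (Tt < w) abort("scan shorter than the FCD window")
  starts <- seq.int(1L, Tt - w + 1L, by = as.integer(stride))
  # windowed correlations via rolling sums; centering each series first
  # keeps the cumulative sums well conditioned (correlations are
  # shift-invariant, so this changes nothing mathematically)
  x <- x - rowMeans(x)
  roll <- function(M) {
    C <- cbind(0, t(apply(M, 1, cumsum)))
    C[, starts + w, drop = FALSE] - C[, starts, drop = FALSE]
  }
  idx <- t(utils::combn(n, 2L))       # pair order (i,j), i<j: row-major
  S1 <- roll(x)
  S2 <- roll(x^2)
  P <- roll(x[idx[, 1], , drop = FALSE] * x[idx[, 2], , drop = FALSE])
  m <- S1 / w
  v <- S2 / w - m^2
  covw <- P / w - m[idx[, 1], , drop = FALSE] * m[idx[, 2], , drop = FALSE]
  vecs <- covw / sqrt(v[idx[, 1], , drop = FALSE] * v[idx[, 2], , drop = FALSE])
  fcd <- cor(vecs)
  attr(fcd, "window_len_tr") <- w
  attr(fcd, "stride") <- as.integer(stride)
  class(fcd) <- c("fcd_matrix", class(fcd))
  fcd
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' The supremum over x of the absolute difference between the two empirical
#' cumulative distribution functions. Used on the pooled upper-triangular
#' FCD entries of simulated and empirical scans.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return KS distance in `[0, 1]`.
#' @export
ks_distance <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) abort("samples must be non-empty")
  ks_sorted(sort(sample_a), sort(sample_b))
}

# KS distance for pre-sorted samples (hot path in candidate evaluation)
ks_sorted <- function(sa, sb) {
  v <- c(sa, sb)                      # ECDF jumps only occur at sample points
  Fa <- findInterval(v, sa) / length(sa)
  Fb <- findInterval(v, sb) / length(sb)
  max(abs(Fa - Fb))
}

#' FC/FCD realism cost of a simulated scan against an empirical target
#'
#' Three components, each computed on strictly-upper-triangular entries in
#' the package's fixed row-major order:
#' * `corr_cost = 1 - r`, r the Pearson correlation between the vectorized
#'   simulated and empirical FC matrices;
#' * `mean_abs_diff = d`, the absolute difference between the mean empirical
#'   and mean simulated FC entry;
#' * `ks_cost`, the KS distance between the distributions of simulated and
#'   empirical FCD entries.
#' The total cost is their sum, `(1 - r) + d + KS`; lower is more realistic.
#'
#' @param fc_sim,fc_emp FC matrices (same dimension).
#' @param fcd_sim,fcd_emp FCD matrices (dimensions may differ; only their
#'   entry distributions are compared).
#' @return Object of class `"realism_cost"`: list(`corr_cost`,
#'   `mean_abs_diff`, `ks_cost`, `total`).
#' @export
realism_cost <- function(fc_sim, fc_emp, fcd_sim, fcd_emp) {
  if (!all(dim(fc_sim) == dim(fc_emp))) abort("FC matrices must match in dimension")
  us <- upper_triangle(unclass(fc_sim)); ue <- upper_triangle(unclass(fc_emp))
  r <- cor(us, ue)
  d <- abs(mean(ue) - mean(us))
  ks <- ks_distance(upper_triangle(unclass(fcd_sim)),
                    upper_triangle(unclass(fcd_emp)))
  structure(list(corr_cost = 1 - r, mean_abs_diff = d, ks_cost = ks,
                 total = (1 - r) + d + ks),
            class = "realism_cost")
}

#' @export
print.realism_cost <- function(x, ...) {
  cat(sprintf("<realism_cost> (1-r)=%.4f  d=%.4f  KS=%.4f  total=%.4f\n",
              x$corr_cost, x$mean_abs_diff, x$ks_cost, x$total))
  invisible(x)
}

#' @export
tidy.realism_cost <- function(x, ...) {
  tibble(component = c("corr_cost", "mean_abs_diff", "ks_cost", "total"),
         value = c(x$corr_cost, x$mean_abs_diff, x$ks_cost, x$total))
}
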