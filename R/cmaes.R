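#' Initialize a CMA-ES state
#'
#' Standard covariance matrix adaptation evolution strategy (rank-one plus
#' rank-mu updates, log-decreasing parent weights, cumulative step-size
#' adaptation). Each epoch samples `lambda` children from
#' `N(mean, step_size^2 * C)` and updates the distribution from the `mu`
#' best-ranked children.
#'
#' @param mean Length-D initial distribution mean.
#' @param step_size Initial global step size (sigma).
#' @param lambda Children per epoch (population size, default 100).
#' @param mu Parents used in the update (default 10).
#' @param C Initial D x D covariance shape (default identity); use a
#'   diagonal of squared per-coordinate scales for anisotropic searches.
#' @param seed Integer seed; child draws are derived from it and the epoch
#'   counter, so sampling is deterministic.
#' @return Object of class `"cma_state"`.
#' @export
cma_init <- function(mean, step_size, lambda = 100L, mu = 10L, C = NULL,
                     seed = 1L) {
  D <- length(mean)
  if (mu >= lambda) abort("`mu` must be smaller than `lambda`")
  C <- C %||% diag(D)
  if (!isTRUE(all.equal(C, t(C))) || any(eigen(C, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0)) {
    abort("`C` must be symmetric positive-definite")
  }
  structure(
    list(mean = as.numeric(mean), C = C, step_size = step_size,
         lambda = as.integer(lambda), mu = as.integer(mu),
         epoch = 0L, seed = as.integer(seed),
         p_sigma = numeric(D), p_c = numeric(D),
         chiN = sqrt(D) * (1 - 1 / (4 * D) + 1 / (21 * D^2))),
    class = "cma_state"
  )
}

# eigendecomposition helpers (D is small; recompute on demand)
cma_eig <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 1e-20)
  list(B = e$vectors, d = sqrt(d))
}

#' Sample one population of CMA-ES children
#'
#' Draws `lambda` i.i.d. candidates from `N(mean, step_size^2 * C)`.
#' Deterministic given the state's seed and epoch counter.
#'
#' @param state A `"cma_state"`.
#' @return D x lambda matrix, one child per column.
#' @export
sample_children <- function(state) {
  D <- length(state$mean)
  eg <- cma_eig(state$C)
  set.seed(derive_seed(state$seed, state$epoch, 101L))
  Z <- matrix(rnorm(D * state$lambda), D, state$lambda)
  state$mean + state$step_size * (eg$B %*% (eg$d * Z))
}

#' CMA-ES distribution update from ranked children
#'
#' Applies the standard Hansen update (mean recombination with
#' log-decreasing weights, cumulative paths, rank-one + rank-mu covariance
#' update, cumulative step-size adaptation) using the `mu` lowest-cost
#' children. Children with non-finite cost (the out-of-range candidates) are
#' excluded from ranking; if fewer than `mu` remain, all valid children are
#' used with renormalized weights, and if none remain the distribution is
#' kept with the step size shrunk by 0.7.
#'
#' @param state A `"cma_state"`.
#' @param children D x lambda matrix from [sample_children()].
#' @param costs Length-lambda numeric costs (`Inf`/`NA` = invalid child).
#' @return The updated `"cma_state"` (epoch incremented).
#' @export
update_distribution <- function(state, children, costs) {
  D <- length(state$mean)
  costs[!is.finite(costs)] <- Inf
  valid <- which(is.finite(costs))
  state$epoch <- state$epoch + 1L
  if (length(valid) == 0L) {
    state$step_size <- state$step_size * 0.7
    return(state)
  }
  n_sel <- min(state$mu, length(valid))
  sel <- valid[order(costs[valid])][seq_len(n_sel)]
  w <- log(state$mu + 0.5) - log(seq_len(n_sel))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)

  cs <- (mu_eff + 2) / (D + mu_eff + 5)
  ds <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (D + 1)) - 1) + cs
  cc <- (4 + mu_eff / D) / (D + 4 + 2 * mu_eff / D)
  c1 <- 2 / ((D + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((D + 2)^2 + mu_eff))

  old_mean <- state$mean
  X <- children[, sel, drop = FALSE]
  new_mean <- as.vector(X %*% w)
  y <- (new_mean - old_mean) / state$step_size

  eg <- cma_eig(state$C)
  C_inv_sqrt <- eg$B %*% (t(eg$B) / eg$d)
  state$p_sigma <- (1 - cs) * state$p_sigma +
    sqrt(cs * (2 - cs) * mu_eff) * as.vector(C_inv_sqrt %*% y)
  hsig <- sqrt(sum(state$p_sigma^2)) /
    sqrt(1 - (1 - cs)^(2 * state$epoch)) / state$chiN < 1.4 + 2 / (D + 1)
  state$p_c <- (1 - cc) * state$p_c + hsig * sqrt(cc * (2 - cc) * mu_eff) * y

  Y <- sweep(X, 1, old_mean) / state$step_size
  rank_mu <- Y %*% (w * t(Y))
  state$C <- (1 - c1 - cmu) * state$C +
    c1 * (outer(state$p_c, state$p_c) + (1 - hsig) * cc * (2 - cc) * state$C) +
    cmu * rank_mu
  state$C <- (state$C + t(state$C)) / 2
  state$step_size <- state$step_size *
    exp((cs / ds) * (sqrt(sum(state$p_sigma^2)) / state$chiN - 1))
  state$mean <- new_mean
  state
}

#' Minimize a deterministic function with CMA-ES
#'
#' Convenience loop over [sample_children()] and [update_distribution()] for
#' an analytic objective; used for benchmarking the strategy itself.
#'
#' @param fn Function of a length-D numeric vector returning a scalar cost.
#' @param mean0 Initial mean.
#' @param step_size Initial step size.
#' @param lambda,mu Population and parent sizes.
#' @param epochs Number of epochs.
#' @param seed Integer seed.
#' @return List with `best` (best candidate seen), `best_cost`, `mean`
#'   (final distribution mean) and `trace` (best cost per epoch).
#' @export
cma_optimize <- function(fn, mean0, step_size = 0.3, lambda = 100L, mu = 10L,
                         epochs = 100L, seed = 1L) {
  state <- cma_init(mean0, step_size, lambda, mu, seed = seed)
  best <- mean0; best_cost <- fn(mean0)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ch <- sample_children(state)
    costs <- apply(ch, 2, fn)
    i <- which.min(costs)
    if (costs[i] < best_cost) { best_cost <- costs[i]; best <- ch[, i] }
    trace[e] <- costs[i]
    state <- update_distribution(state, ch, costs)
  }
  list(best = best, best_cost = best_cost, mean = state$mean, trace = trace)
}
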