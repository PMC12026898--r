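# An evaluator scores one coefficient vector: it returns the within-range
# gate outcome and, when the gate passes, the three realism-cost components.
# Evaluators are the pluggable heart of the optimizer: "euler" runs the full
# integrate -> gate -> BOLD -> FC/FCD pipeline, "surrogate" replaces it with
# the trained networks, "analytic" scores a closed-form objective (used for
# strategy benchmarks and for counting-mode bookkeeping runs).

new_evaluator <- function(tag, fn) {
  structure(list(tag = tag, eval_theta = fn), class = "ficsurr_evaluator")
}

#' Integrator-backed candidate evaluator
#'
#' Builds an evaluator that scores a coefficient vector by the full forward
#' pipeline: expand to per-region parameters, calibrate w_IE (feedback
#' inhibition control), integrate the stochastic neural dynamics, apply the
#' firing-rate gate, and - for within-range candidates - simulate BOLD,
#' compute FC and FCD, and score the realism cost against the empirical
#' target. Calibration failures and out-of-band firing rates both mark the
#' candidate out of range (no cost attached).
#'
#' @param conn A [connectome()].
#' @param target An [make_empirical_target()] result, or any list with
#'   elements `fc` and `fcd`.
#' @param config A [run_config()].
#' @param consts,hconsts Model and hemodynamic constants.
#' @return An evaluator object with tag `"euler"`.
#' @export
euler_evaluator <- function(conn, target, config = run_config(),
                            consts = fic_constants(),
                            hconsts = hemo_constants()) {
  w_tr <- window_len_from_seconds(config$window_s, config$tr_s)
  # target-side quantities are fixed across thousands of evaluations
  ue <- upper_triangle(unclass(target$fc))
  mean_ue <- mean(ue)
  emp_fcd_sorted <- sort(upper_triangle(unclass(target$fcd)))
  new_evaluator("euler", function(theta, seed) {
    params <- expand_coefficients(theta, conn, consts)
    params <- tryCatch(
      calibrate_fic(params, conn, config$target_rate_hz, consts,
                    dt_s = config$dt_s, eta = config$calib_eta,
                    tol = config$calib_tol,
                    max_sweeps = config$calib_max_sweeps,
                    sweep_s = config$calib_sweep_s),
      ficsurr_calibration_error = function(e) NULL
    )
    if (is.null(params)) {
      return(list(within = FALSE, corr_cost = NA_real_,
                  mean_abs_diff = NA_real_, ks_cost = NA_real_,
                  total = NA_real_))
    }
    sim <- simulate_scan(params, conn, config, seed = seed,
                         consts = consts, hconsts = hconsts)
    if (!rates_within(sim$mean_rates, config$rate_lo_hz, config$rate_hi_hz,
                      config$range_rule)) {
      return(list(within = FALSE, corr_cost = NA_real_,
                  mean_abs_diff = NA_real_, ks_cost = NA_real_,
                  total = NA_real_))
    }
    fc <- compute_fc(sim$bold)
    fcd <- compute_fcd(sim$bold, w_tr)
    us <- upper_triangle(unclass(fc))
    corr_cost <- 1 - cor(us, ue)
    d <- abs(mean_ue - mean(us))
    ks <- ks_sorted(sort(upper_triangle(unclass(fcd))), emp_fcd_sorted)
    list(within = TRUE, corr_cost = corr_cost, mean_abs_diff = d,
         ks_cost = ks, total = corr_cost + d + ks)
  })
}

#' Surrogate-backed candidate evaluator
#'
#' Gates candidates with the trained within-range classifier (predicted
#' probability >= `config$gate_threshold`) and scores survivors with the
#' FC+FCD cost predictor; no numerical integration is performed.
#'
#' @param models Trained [train_surrogates()] networks.
#' @param conn A [connectome()].
#' @param target Empirical target supplying the FC/FCD embedding inputs.
#' @param config A [run_config()].
#' @return An evaluator object with tag `"surrogate"`.
#' @export
surrogate_evaluator <- function(models, conn, target, config = run_config()) {
  feats <- featurize_triplet(conn, target$fc, target$fcd,
                             n_quantiles = config$fcd_quantiles)
  thr <- config$gate_threshold
  new_evaluator("surrogate", function(theta, seed) {
    p <- predict_within_range(models, matrix(theta, nrow = 1),
                              matrix(feats$sc, nrow = 1))
    if (p < thr) {
      return(list(within = FALSE, corr_cost = NA_real_,
                  mean_abs_diff = NA_real_, ks_cost = NA_real_,
                  total = NA_real_))
    }
    co <- predict_cost(models, matrix(theta, nrow = 1),
                       matrix(feats$sc, nrow = 1),
                       matrix(feats$fc, nrow = 1),
                       matrix(feats$fcd, nrow = 1))
    list(within = TRUE, corr_cost = co[1, "corr_cost"],
         mean_abs_diff = co[1, "mean_abs_diff"], ks_cost = co[1, "ks_cost"],
         total = sum(co[1, ]))
  })
}

#' Analytic candidate evaluator
#'
#' Scores candidates with a closed-form objective (default: squared
#' Euclidean norm). Every candidate passes the gate. Used to benchmark the
#' evolution strategy and to populate evaluation ledgers in counting mode,
#' where the schedule's bookkeeping (epochs x children) is exercised without
#' running the integrator.
#'
#' @param fn Objective function of theta.
#' @param tag Evaluator tag recorded in the ledger (default `"analytic"`;
#'   counting-mode runs use `"counting"`).
#' @return An evaluator object.
#' @export
analytic_evaluator <- function(fn = function(theta) sum(theta^2),
                               tag = "analytic") {
  new_evaluator(tag, function(theta, seed) {
    list(within = TRUE, corr_cost = NA_real_, mean_abs_diff = NA_real_,
         ks_cost = NA_real_, total = fn(theta))
  })
}

#' Evaluate a population of candidates into a ledger
#'
#' Applies an evaluator to every child and returns one ledger row per child
#' (gate outcome, cost components, evaluator tag, per-child derived seed).
#' Every sampled child appears exactly once.
#'
#' @param children D x lambda matrix of coefficient vectors.
#' @param evaluator An evaluator object.
#' @param epoch Epoch index recorded in the ledger.
#' @param base_seed Seed from which per-child seeds are derived.
#' @return A tibble with columns `epoch`, `child`, `theta` (list-column),
#'   `within_range`, `corr_cost`, `mean_abs_diff`, `ks_cost`, `total`,
#'   `evaluator_tag`, `seed`.
#' @export
evaluate_candidates <- function(children, evaluator, epoch = 1L,
                                base_seed = 1L) {
  lam <- ncol(children)
  seeds <- vapply(seq_len(lam), function(i) derive_seed(base_seed, epoch, i),
                  integer(1))
  res <- lapply(seq_len(lam), function(i) {
    evaluator$eval_theta(children[, i], seeds[i])
  })
  num <- function(nm) vapply(res, `[[`, numeric(1), nm)
  tibble(epoch = as.integer(epoch), child = seq_len(lam),
         theta = lapply(seq_len(lam), function(i) children[, i]),
         within_range = vapply(res, `[[`, logical(1), "within"),
         corr_cost = num("corr_cost"), mean_abs_diff = num("mean_abs_diff"),
         ks_cost = num("ks_cost"), total = num("total"),
         evaluator_tag = evaluator$tag, seed = seeds)
}

#' @rdname evaluate_candidates
#' @param conn,target,config,consts,hconsts Passed to [euler_evaluator()].
#' @export
evaluate_candidates_euler <- function(children, conn, target,
                                      config = run_config(), epoch = 1L,
                                      base_seed = 1L,
                                      consts = fic_constants(),
                                      hconsts = hemo_constants()) {
  evaluate_candidates(children, euler_evaluator(conn, target, config,
                                                consts, hconsts),
                      epoch, base_seed)
}

#' @rdname evaluate_candidates
#' @param models Trained surrogate networks.
#' @export
evaluate_candidates_surrogate <- function(children, models, conn, target,
                                          config = run_config(), epoch = 1L,
                                          base_seed = 1L) {
  evaluate_candidates(children, surrogate_evaluator(models, conn, target,
                                                    config),
                      epoch, base_seed)
}
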