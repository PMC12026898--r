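#' Fit FIC model coefficients with CMA-ES
#'
#' Runs the full model-inversion protocol: for each of `restarts` random
#' initializations, CMA-ES samples `lambda` coefficient vectors per epoch,
#' the chosen evaluator scores them (out-of-range children receive infinite
#' cost and are excluded from the distribution update), and the best valid
#' child of each epoch is collated as a candidate. After the training loop
#' the candidates are re-evaluated with the numerical integrator on the
#' validation target (validation and test are always integrator-backed, so a
#' surrogate-driven fit is selected and scored against ground truth); the
#' argmin candidate is then scored on the test target.
#'
#' @param conn A [connectome()].
#' @param target Training empirical target (list with `fc`, `fcd`).
#' @param evaluator `"euler"`, `"surrogate"`, `"counting"`, or an evaluator
#'   object built with [euler_evaluator()] / [surrogate_evaluator()] /
#'   [analytic_evaluator()].
#' @param epochs CMA-ES epochs per restart.
#' @param restarts Independent CMA-ES restarts (candidates accumulate:
#'   `restarts * epochs` in total when every epoch has a valid child).
#' @param seed Integer seed driving every random stage.
#' @param config A [run_config()] (also supplies `lambda`, `mu`).
#' @param bounds Coefficient box from [default_coef_bounds()]; the CMA-ES
#'   mean is initialized uniformly inside it and the initial per-coordinate
#'   scale is `config$cma_step_size` of each range.
#' @param models Trained surrogates (required when `evaluator="surrogate"`).
#' @param validation_target,test_target Empirical targets for the selection
#'   and test phases; both default to `target`.
#' @param n_eval_seeds Independent integrator realizations averaged when
#'   scoring a candidate in the validation and test phases (default 1;
#'   small scans benefit from 3, which suppresses the finite-sample noise
#'   that argmin selection would otherwise exploit). A candidate counts as
#'   within range only if every realization passes the gate.
#' @param consts,hconsts Model and hemodynamic constants.
#' @param validate If `FALSE`, skip the validation/test phases (used when
#'   only the training ledger is needed, e.g. surrogate data generation).
#' @return Object of class `"fic_fit"` with the full candidate `ledger`
#'   (one row per sampled child), the collated `candidates` (best per
#'   epoch, with validation costs when validated), `selected_theta`,
#'   `test_cost`, and the run metadata.
#' @export
fic_fit <- function(conn, target, evaluator = "euler", epochs = 100L,
                    restarts = 1L, seed = 1L, config = run_config(),
                    bounds = default_coef_bounds(ncol(conn$covariates)),
                    models = NULL, validation_target = NULL,
                    test_target = NULL, consts = fic_constants(),
                    hconsts = hemo_constants(), validate = TRUE,
                    n_eval_seeds = 1L) {
  if (epochs < 1) abort("`epochs` must be at least 1")
  if (is.character(evaluator)) {
    evaluator <- switch(match.arg(evaluator, c("euler", "surrogate", "counting")),
      euler = euler_evaluator(conn, target, config, consts, hconsts),
      surrogate = {
        if (is.null(models)) abort("surrogate evaluator needs trained `models`")
        surrogate_evaluator(models, conn, target, config)
      },
      counting = analytic_evaluator(tag = "counting")
    )
  }
  D <- n_coefficients(ncol(conn$covariates))
  rng <- bounds$upper - bounds$lower
  ledgers <- list()
  cand_rows <- list()
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r, 7L))
    mean0 <- bounds$lower + runif(D) * rng
    state <- cma_init(mean0, step_size = config$cma_step_size,
                      lambda = config$lambda, mu = config$mu,
                      C = diag(rng^2, D), seed = derive_seed(seed, r, 11L))
    for (e in seq_len(epochs)) {
      children <- sample_children(state)
      led <- evaluate_candidates(children, evaluator, epoch = e,
                                 base_seed = derive_seed(seed, r, 13L))
      led$restart <- as.integer(r)
      ledgers[[length(ledgers) + 1L]] <- led
      costs <- ifelse(is.na(led$total), Inf, led$total)
      if (any(is.finite(costs))) {
        i <- which.min(costs)
        cand_rows[[length(cand_rows) + 1L]] <- tibble(
          restart = as.integer(r), epoch = as.integer(e),
          theta = list(children[, i]), train_total = costs[i]
        )
      }
      state <- update_distribution(state, children, costs)
    }
  }
  ledger <- dplyr::bind_rows(ledgers)
  candidates <- if (length(cand_rows)) dplyr::bind_rows(cand_rows) else
    tibble(restart = integer(), epoch = integer(), theta = list(),
           train_total = numeric())

  selected_theta <- NULL; selected_idx <- NA_integer_; test_cost <- NULL
  if (validate && nrow(candidates) > 0) {
    vt <- validation_target %||% target
    # selection is always integrator-backed, unless the training run itself
    # was an analytic benchmark (no physical target to integrate against)
    val_ev <- if (evaluator$tag %in% c("analytic", "counting")) evaluator
              else euler_evaluator(conn, vt, config, consts, hconsts)
    eval_avg <- function(ev, theta, key) {
      runs <- lapply(seq_len(n_eval_seeds), function(j) {
        ev$eval_theta(theta, derive_seed(seed, key, j))
      })
      if (!all(vapply(runs, function(r) isTRUE(r$within), logical(1)))) {
        return(list(within = FALSE, corr_cost = NA_real_,
                    mean_abs_diff = NA_real_, ks_cost = NA_real_,
                    total = NA_real_))
      }
      comp <- function(nm) mean(vapply(runs, `[[`, numeric(1), nm))
      list(within = TRUE, corr_cost = comp("corr_cost"),
           mean_abs_diff = comp("mean_abs_diff"),
           ks_cost = comp("ks_cost"), total = comp("total"))
    }
    val <- vapply(seq_len(nrow(candidates)), function(i) {
      res <- eval_avg(val_ev, candidates$theta[[i]], derive_seed(seed, 17L, i))
      if (isTRUE(res$within)) res$total else Inf
    }, numeric(1))
    candidates$validation_total <- val
    if (any(is.finite(val))) {
      selected_idx <- which.min(val)
      selected_theta <- candidates$theta[[selected_idx]]
      tt <- test_target %||% vt
      test_ev <- if (evaluator$tag %in% c("analytic", "counting")) evaluator
                 else euler_evaluator(conn, tt, config, consts, hconsts)
      test_cost <- eval_avg(test_ev, selected_theta, derive_seed(seed, 19L, 1L))
    }
  }
  structure(
    list(ledger = ledger, candidates = candidates,
         selected_theta = selected_theta, selected_idx = selected_idx,
         test_cost = test_cost, epochs = as.integer(epochs),
         restarts = as.integer(restarts), lambda = config$lambda,
         mu = config$mu, seed = as.integer(seed),
         evaluator_tag = evaluator$tag, config_hash = attr(config, "hash")),
    class = "fic_fit"
  )
}

#' @export
print.fic_fit <- function(x, ...) {
  cat(sprintf("<fic_fit> %d restart(s) x %d epoch(s) x %d children (%s evaluator)\n",
              x$restarts, x$epochs, x$lambda, x$evaluator_tag))
  cat(sprintf("  %d evaluations, %.1f%% within range, %d collated candidate(s)\n",
              nrow(x$ledger), 100 * mean(x$ledger$within_range),
              nrow(x$candidates)))
  if (!is.null(x$test_cost)) {
    cat(sprintf("  test total cost: %.4f\n", x$test_cost$total))
  }
  invisible(x)
}

#' @describeIn fic_fit One row per collated candidate (best child of each
#'   epoch) with its training and validation costs.
#' @param x,... Fitted object and ignored arguments.
#' @export
tidy.fic_fit <- function(x, ...) {
  x$candidates
}

#' @describeIn fic_fit One-row summary: evaluation counts, within-range
#'   fraction, best validation cost and test cost.
#' @export
glance.fic_fit <- function(x, ...) {
  tibble(
    n_evaluations = nrow(x$ledger),
    n_within_range = sum(x$ledger$within_range),
    n_candidates = nrow(x$candidates),
    best_validation_total = {
      vt <- if (nrow(x$candidates)) x$candidates[["validation_total"]] else NULL
      if (!is.null(vt) && any(is.finite(vt))) min(vt, na.rm = TRUE) else NA_real_
    },
    test_total = if (!is.null(x$test_cost)) x$test_cost$total else NA_real_,
    evaluator = x$evaluator_tag
  )
}
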