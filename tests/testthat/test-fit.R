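test_that("every sampled child is ledgered once with its gate outcome", {
  cn <- fx_conn()
  tgt <- fx_target_short()
  cfg <- micro_config(duration_s = 43.2, burn_in_s = 10, lambda = 8L, mu = 3L)
  fit <- fic_fit(cn, tgt, "euler", epochs = 3, seed = 2, config = cfg,
                 validate = FALSE)
  expect_equal(nrow(fit$ledger), 3L * 8L)
  expect_equal(dplyr::count(fit$ledger, epoch)$n, rep(8L, 3))
  expect_false(any(duplicated(fit$ledger[c("restart", "epoch", "child")])))
  # cost present iff within range
  expect_identical(is.na(fit$ledger$total), !fit$ledger$within_range)
  expect_true(all(fit$ledger$evaluator_tag == "euler"))
})

test_that("integrator-backed fits are reproducible and evaluate constructed points", {
  cn <- fx_conn()
  tgt <- fx_target_short()
  cfg <- micro_config(duration_s = 43.2, burn_in_s = 10, lambda = 6L, mu = 2L)
  f1 <- fic_fit(cn, tgt, "euler", epochs = 2, seed = 5, config = cfg,
                validate = FALSE)
  f2 <- fic_fit(cn, tgt, "euler", epochs = 2, seed = 5, config = cfg,
                validate = FALSE)
  expect_equal(f1$ledger$total, f2$ledger$total)

  # a coefficient vector known to pass the gate (the target's own truth)
  ev <- euler_evaluator(cn, tgt, fx_cfg_short())
  res <- ev$eval_theta(fx_spec()$theta, 123)
  expect_true(res$within)
  expect_true(is.finite(res$total))
  expect_equal(res$total, res$corr_cost + res$mean_abs_diff + res$ks_cost,
               tolerance = 1e-12)

  # a sigma slope that drives sigma negative pre-clamp is still evaluated
  th <- fx_spec()$theta
  th[7] <- -0.5
  res2 <- ev$eval_theta(th, 124)
  expect_true(is.logical(res2$within))
})

test_that("candidate collation follows the epochs-times-restarts schedule", {
  cn <- fx_conn()
  tgt <- list(conn = cn, fc = diag(5), fcd = diag(3))
  cfg <- run_config()                              # lambda 100, mu 10
  f100 <- fic_fit(cn, tgt, "counting", epochs = 100, seed = 1, config = cfg)
  expect_equal(nrow(f100$ledger), 10000L)
  expect_equal(nrow(f100$candidates), 100L)
  expect_true(all(f100$ledger$evaluator_tag == "counting"))

  f250 <- fic_fit(cn, tgt, "counting", epochs = 50, restarts = 5, seed = 1,
                  config = cfg)
  expect_equal(nrow(f250$candidates), 250L)
  expect_equal(nrow(f250$ledger), 5L * 50L * 100L)
})

test_that("validation selects the argmin candidate and scores it on the test set", {
  cn <- fx_conn()
  tgt <- list(conn = cn, fc = diag(5), fcd = diag(3))
  fit <- fic_fit(cn, tgt, "counting", epochs = 10, seed = 3,
                 config = micro_config(lambda = 20L, mu = 5L))
  expect_equal(fit$selected_idx,
               which.min(fit$candidates$validation_total))
  expect_true(is.finite(fit$test_cost$total))
  g <- glance(fit)
  expect_equal(g$n_evaluations, 200L)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("fit results render as plots and summaries", {
  cn <- fx_conn()
  tgt <- list(conn = cn, fc = diag(5), fcd = diag(3))
  fit <- fic_fit(cn, tgt, "counting", epochs = 4, seed = 1,
                 config = micro_config(lambda = 10L, mu = 3L))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "counting")
})
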