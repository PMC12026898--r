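# Shared fixtures, memoized per test run: the surrogate corpus, trained
# networks and protocol experiments are expensive (minutes), so every test
# file pulls them from this cache instead of regenerating them.

fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = fx_cache)) {
    assign(name, expr, envir = fx_cache)
  }
  get(name, envir = fx_cache)
}

fx_spec <- function() synthetic_spec(5, seed = 3)

fx_conn <- function() fixture("conn", make_connectome(fx_spec()))

fx_cfg <- function() micro_config()

fx_target <- function() fixture("target", {
  make_empirical_target(fx_spec(), fx_conn(), fx_cfg())
})

# a short, cheap configuration for contract tests that need a real
# integrator-backed evaluation but not a realistic cost
fx_cfg_short <- function() micro_config(duration_s = 43.2, burn_in_s = 10)

fx_target_short <- function() fixture("target_short", {
  make_empirical_target(fx_spec(), fx_conn(), fx_cfg_short())
})

# --- surrogate corpus: 72 cohort triplets, 2 epochs x 40 children ---

fx_triplets <- function() fixture("triplets", {
  make_triplets(72, seed = 5, config = fx_cfg())
})

fx_tdata <- function() fixture("tdata", {
  generate_training_data(fx_triplets()[1:64], epochs = 2, lambda = 40,
                         seed = 21, config = fx_cfg())
})

fx_tdata_test <- function() fixture("tdata_test", {
  generate_training_data(fx_triplets()[65:72], epochs = 2, lambda = 40,
                         seed = 22, config = fx_cfg())
})

fx_models <- function() fixture("models", {
  train_surrogates(fx_tdata(), split = list(train = 1:52, val = 53:64),
                   seed = 31)
})

# held-out design matrices + labels for the surrogate skill checks
fx_heldout <- function() fixture("heldout", {
  tdt <- fx_tdata_test()
  all_rows <- seq_len(nrow(tdt$samples))
  wr <- which(tdt$samples$within_range)
  list(
    all = ficsurr:::surrogate_design(tdt, all_rows),
    within = ficsurr:::surrogate_design(tdt, wr),
    total_within = tdt$samples$total[wr],
    within_frac = mean(tdt$samples$within_range)
  )
})

# label-permutation control: classifier trained on shuffled gate labels
fx_perm_model <- function() fixture("perm_model", {
  tdp <- fx_tdata()
  set.seed(99)
  tdp$samples$within_range <- sample(tdp$samples$within_range)
  train_surrogates(tdp, split = list(train = 1:52, val = 53:64),
                   seed = 31, components = "classifier")
})

# --- model-inversion problem: unseen connectome, three realizations of
#     one ground truth (training / validation / test targets) ---

fx_inversion <- function() fixture("inversion", {
  cfg <- fx_cfg()
  spec <- synthetic_spec(5, theta = random_plausible_theta(2, 901), seed = 901)
  conn <- make_connectome(spec)
  list(
    conn = conn, theta = spec$theta,
    train = make_empirical_target(spec, conn, cfg),
    val = make_empirical_target(
      synthetic_spec(5, theta = spec$theta, seed = 902, geometry_seed = 901),
      conn, cfg),
    test = make_empirical_target(
      synthetic_spec(5, theta = spec$theta, seed = 903, geometry_seed = 901),
      conn, cfg)
  )
})

# parity experiment: Euler-driven vs surrogate-driven fits, 10 seeds
fx_parity <- function() fixture("parity", {
  inv <- fx_inversion()
  mod <- fx_models()
  cfg <- micro_config(lambda = 24L, mu = 6L)
  res <- vapply(1:10, function(s) {
    fE <- fic_fit(inv$conn, inv$train, "euler", epochs = 5, restarts = 3,
                  seed = s, config = cfg, validation_target = inv$val,
                  test_target = inv$test, n_eval_seeds = 3)
    fS <- fic_fit(inv$conn, inv$train, "surrogate", models = mod, epochs = 5,
                  restarts = 3, seed = s, config = cfg,
                  validation_target = inv$val, test_target = inv$test,
                  n_eval_seeds = 3)
    c(euler = if (is.null(fE$test_cost)) NA_real_ else fE$test_cost$total,
      surrogate = if (is.null(fS$test_cost)) NA_real_ else fS$test_cost$total)
  }, numeric(2))
  list(euler = res["euler", ], surrogate = res["surrogate", ])
})

# ground-truth recovery: 5 fit seeds against the initialization cost
fx_recovery <- function() fixture("recovery", {
  inv <- fx_inversion()
  cfg <- micro_config(lambda = 24L, mu = 6L)
  bounds <- default_coef_bounds(2)
  test_ev <- euler_evaluator(inv$conn, inv$test, cfg)
  eval3 <- function(theta, key) {
    tot <- vapply(1:3, function(j) {
      r <- test_ev$eval_theta(theta, derive_seed(key, j))
      if (isTRUE(r$within)) r$total else Inf
    }, numeric(1))
    mean(tot)
  }
  out <- lapply(1:5, function(s) {
    fit <- fic_fit(inv$conn, inv$train, "euler", epochs = 5, restarts = 2,
                   seed = s, config = cfg, validation_target = inv$val,
                   test_target = inv$test, n_eval_seeds = 3)
    # initialization cost: the first restart's CMA-ES starting mean
    set.seed(derive_seed(s, 1L, 7L))
    mean0 <- bounds$lower + runif(length(bounds$lower)) *
      (bounds$upper - bounds$lower)
    list(test = if (is.null(fit$test_cost)) NA_real_ else fit$test_cost$total,
         init = eval3(mean0, derive_seed(s, 77L)))
  })
  list(test = vapply(out, `[[`, numeric(1), "test"),
       init = vapply(out, `[[`, numeric(1), "init"))
})
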