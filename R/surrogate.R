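#' Featurize a (SC, FC, FCD) triplet for the surrogate networks
#'
#' Fixed-length inputs for the embedding MLPs: the strictly-upper-triangular
#' SC and empirical-FC entries (row-major order), and the empirical FCD
#' summarized as the quantile vector of its upper-triangular entries (a
#' fixed-length, scale-free description of the FCD entry distribution,
#' matching how the KS cost consumes the FCD).
#'
#' @param conn A [connectome()].
#' @param fc_emp,fcd_emp Empirical FC and FCD matrices.
#' @param n_quantiles Length of the FCD quantile vector (default 100).
#' @return List with numeric vectors `sc`, `fc`, `fcd`.
#' @export
featurize_triplet <- function(conn, fc_emp, fcd_emp, n_quantiles = 100L) {
  list(
    sc = upper_triangle(conn$sc),
    fc = upper_triangle(unclass(fc_emp)),
    fcd = quantile(upper_triangle(unclass(fcd_emp)),
                   probs = seq(0, 1, length.out = n_quantiles),
                   names = FALSE, type = 7)
  )
}

#' Generate surrogate training samples by integrator-backed CMA-ES
#'
#' For each (SC, empirical FC, empirical FCD) triplet, runs CMA-ES with the
#' numerical integrator as evaluator and logs every sampled child as one
#' training sample: its coefficients, its within-range label and - for
#' within-range children - its three ground-truth cost components. The
#' sample count is exactly `triplets x epochs x lambda`. With
#' `dry_run = TRUE` the same schedule is exercised in counting mode (an
#' analytic stand-in objective, no integration), which populates the ledger
#' for bookkeeping.
#'
#' @param triplets List of triplets, each a list with `conn`, `fc`, `fcd`.
#' @param epochs CMA-ES epochs per triplet (default 100).
#' @param lambda Children per epoch (default 100).
#' @param seed Integer seed.
#' @param config A [run_config()].
#' @param dry_run Counting mode (see above).
#' @param consts,hconsts Model and hemodynamic constants.
#' @return Object of class `"training_data"`: `samples` (tibble with
#'   `triplet`, `epoch`, `child`, `theta`, `within_range`, cost components,
#'   `evaluator_tag`, `seed`) and `features` (per-triplet surrogate inputs).
#' @export
generate_training_data <- function(triplets, epochs = 100L, lambda = 100L,
                                   seed = 1L, config = run_config(),
                                   dry_run = FALSE,
                                   consts = fic_constants(),
                                   hconsts = hemo_constants()) {
  if (!length(triplets)) abort("need at least one (SC, FC, FCD) triplet")
  cfg <- config_update(config, lambda = lambda,
                       mu = min(config$mu, as.integer(lambda) - 1L))
  samples <- vector("list", length(triplets))
  features <- vector("list", length(triplets))
  for (t in seq_along(triplets)) {
    tri <- triplets[[t]]
    fit <- fic_fit(tri$conn, tri, evaluator = if (dry_run) "counting" else "euler",
                   epochs = epochs, restarts = 1L,
                   seed = derive_seed(seed, t, 31L), config = cfg,
                   consts = consts, hconsts = hconsts, validate = FALSE)
    led <- fit$ledger
    led$triplet <- as.integer(t)
    samples[[t]] <- led
    features[[t]] <- featurize_triplet(tri$conn, tri$fc, tri$fcd,
                                       cfg$fcd_quantiles)
  }
  structure(
    list(samples = dplyr::bind_rows(samples), features = features,
         epochs = as.integer(epochs), lambda = as.integer(lambda),
         config_hash = attr(cfg, "hash")),
    class = "training_data"
  )
}

#' @export
print.training_data <- function(x, ...) {
  cat(sprintf("<training_data> %d samples from %d triplet(s) (%d epochs x %d children), %.1f%% within range\n",
              nrow(x$samples), length(x$features), x$epochs, x$lambda,
              100 * mean(x$samples$within_range)))
  invisible(x)
}

# assemble design matrices for a set of sample rows
surrogate_design <- function(tdata, rows) {
  s <- tdata$samples[rows, ]
  Xth <- do.call(rbind, s$theta)
  f <- tdata$features
  Xsc <- do.call(rbind, lapply(s$triplet, function(t) f[[t]]$sc))
  Xfc <- do.call(rbind, lapply(s$triplet, function(t) f[[t]]$fc))
  Xfcd <- do.call(rbind, lapply(s$triplet, function(t) f[[t]]$fcd))
  list(Xth = Xth, Xsc = Xsc, Xfc = Xfc, Xfcd = Xfcd,
       y = as.numeric(s$within_range),
       Y_fc = cbind(s$corr_cost, s$mean_abs_diff),
       Y_ks = cbind(s$ks_cost))
}

norm_stats <- function(X) {
  mu <- colMeans(X); sd <- apply(X, 2, sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}
apply_norm <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

#' Surrogate training hyperparameters
#'
#' @param H Latent embedding width shared by all embedding MLPs (addition of
#'   embeddings requires a common width).
#' @param depth Hidden layers per MLP block.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epoch budget.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param weight_decay L2 penalty on the weight matrices (not biases).
#' @return Named list.
#' @export
surrogate_hyper <- function(H = 128L, depth = 2L, lr = 1e-3, batch_size = 64L,
                            max_epochs = 400L, patience = 60L,
                            weight_decay = 1e-2) {
  list(H = as.integer(H), depth = as.integer(depth), lr = lr,
       batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       weight_decay = weight_decay)
}

#' Train the surrogate networks
#'
#' Trains (i) the within-range classifier on all training samples and
#' (ii) the FC+FCD cost predictor on the within-range training samples only.
#' Both use the embedding-addition architecture: inputs pass through
#' separate MLPs whose equal-width latent embeddings are summed into a model
#' embedding before the prediction head. The split unit is the triplet (not
#' the row), preventing leakage through shared empirical targets; features
#' are z-scored with statistics frozen from the training split and stored in
#' the model object.
#'
#' @param tdata A [generate_training_data()] result.
#' @param split List with integer vectors `train` and `val` of triplet ids
#'   (must be disjoint).
#' @param hyper [surrogate_hyper()] settings.
#' @param seed Integer seed.
#' @param components Which networks to train (`"classifier"`,
#'   `"predictor"`, or both). Training only the classifier is useful for
#'   label-permutation controls, where cost targets are meaningless.
#' @return Object of class `"surrogate_models"`.
#' @export
train_surrogates <- function(tdata, split, hyper = surrogate_hyper(),
                             seed = 1L,
                             components = c("classifier", "predictor")) {
  components <- match.arg(components, several.ok = TRUE)
  if (length(intersect(split$train, split$val))) {
    abort("train and validation triplet sets must be disjoint")
  }
  s <- tdata$samples
  tr_rows <- which(s$triplet %in% split$train)
  va_rows <- which(s$triplet %in% split$val)
  if (!length(tr_rows) || !length(va_rows)) {
    abort("both splits must contain at least one triplet's samples")
  }
  dtr <- surrogate_design(tdata, tr_rows)
  dva <- surrogate_design(tdata, va_rows)
  norm <- list(th = norm_stats(dtr$Xth), sc = norm_stats(dtr$Xsc),
               fc = norm_stats(dtr$Xfc), fcd = norm_stats(dtr$Xfcd))
  ntr <- lapply(c(Xth = "Xth", Xsc = "Xsc", Xfc = "Xfc", Xfcd = "Xfcd"),
                function(nm) apply_norm(dtr[[nm]],
                                        norm[[sub("X", "", nm)]]))
  nva <- lapply(c(Xth = "Xth", Xsc = "Xsc", Xfc = "Xfc", Xfcd = "Xfcd"),
                function(nm) apply_norm(dva[[nm]],
                                        norm[[sub("X", "", nm)]]))

  # --- classifier (all rows) ---
  cls_fit <- NULL
  cls <- classifier_new(ncol(ntr$Xth), ncol(ntr$Xsc), hyper$H, hyper$depth,
                        seed = derive_seed(seed, 41L))
  cls_step <- function(nets, st, bi, lr) {
    fw <- classifier_fwd(nets, ntr$Xth[bi, , drop = FALSE],
                         ntr$Xsc[bi, , drop = FALSE])
    g <- classifier_grads(nets, fw, dtr$y[bi])
    adam_step(nets, g, st, lr, weight_decay = hyper$weight_decay)
  }
  cls_val <- function(nets) {
    bce_loss(classifier_fwd(nets, nva$Xth, nva$Xsc)$prob, dva$y)
  }
  if ("classifier" %in% components) {
    cls_fit <- train_loop(cls, cls_step, cls_val, length(tr_rows), hyper,
                          derive_seed(seed, 43L))
  }

  # --- cost predictor (within-range rows only) ---
  prd_fit <- NULL
  target_scale <- NULL
  wtr <- which(s$within_range[tr_rows])
  wva <- which(s$within_range[va_rows])
  if ("predictor" %in% components) {
  if (!length(wtr)) {
    abort("no within-range training samples: cannot train the cost predictor")
  }
  if (anyNA(dtr$Y_fc[wtr, ]) || anyNA(dtr$Y_ks[wtr, ])) {
    abort("within-range sample lacking ground-truth costs: corrupt ledger")
  }
  # balance the three heads: train on costs scaled to unit training mean
  # (softplus nonnegativity is preserved; predictions are unscaled on output)
  target_scale <- pmax(c(colMeans(dtr$Y_fc[wtr, , drop = FALSE]),
                         mean(dtr$Y_ks[wtr, ])), 1e-6)
  Ytr_fc <- sweep(dtr$Y_fc, 2, target_scale[1:2], "/")
  Ytr_ks <- dtr$Y_ks / target_scale[3]
  Yva_fc <- sweep(dva$Y_fc, 2, target_scale[1:2], "/")
  Yva_ks <- dva$Y_ks / target_scale[3]
  prd <- predictor_new(ncol(ntr$Xth), ncol(ntr$Xsc), ncol(ntr$Xfc),
                       ncol(ntr$Xfcd), hyper$H, hyper$depth,
                       seed = derive_seed(seed, 47L))
  prd_step <- function(nets, st, bi, lr) {
    bi <- wtr[bi]
    fw <- predictor_fwd(nets, ntr$Xth[bi, , drop = FALSE],
                        ntr$Xsc[bi, , drop = FALSE],
                        ntr$Xfc[bi, , drop = FALSE],
                        ntr$Xfcd[bi, , drop = FALSE])
    g <- predictor_grads(nets, fw, Ytr_fc[bi, , drop = FALSE],
                         Ytr_ks[bi, , drop = FALSE])
    adam_step(nets, g, st, lr, weight_decay = hyper$weight_decay)
  }
  prd_val <- function(nets) {
    if (!length(wva)) return(Inf)
    fw <- predictor_fwd(nets, nva$Xth[wva, , drop = FALSE],
                        nva$Xsc[wva, , drop = FALSE],
                        nva$Xfc[wva, , drop = FALSE],
                        nva$Xfcd[wva, , drop = FALSE])
    mse_loss(fw, Yva_fc[wva, , drop = FALSE], Yva_ks[wva, , drop = FALSE])
  }
  prd_fit <- train_loop(prd, prd_step, prd_val, length(wtr), hyper,
                        derive_seed(seed, 53L))
  }

  structure(
    list(classifier = if (!is.null(cls_fit)) cls_fit$nets,
         predictor = if (!is.null(prd_fit)) prd_fit$nets, norm = norm,
         target_scale = target_scale, hyper = hyper,
         meta = list(classifier_val_loss = if (!is.null(cls_fit)) cls_fit$val_loss,
                     classifier_curve = if (!is.null(cls_fit)) cls_fit$curve,
                     predictor_val_loss = if (!is.null(prd_fit)) prd_fit$val_loss,
                     predictor_curve = if (!is.null(prd_fit)) prd_fit$curve,
                     train_base_rate = mean(s$within_range[tr_rows]),
                     n_train = length(tr_rows), n_val = length(va_rows))),
    class = "surrogate_models"
  )
}

#' @export
print.surrogate_models <- function(x, ...) {
  cat(sprintf("<surrogate_models> H=%d; classifier val BCE %s; predictor val MSE %s\n",
              x$hyper$H,
              if (is.null(x$meta$classifier_val_loss)) "-" else
                sprintf("%.4f", x$meta$classifier_val_loss),
              if (is.null(x$meta$predictor_val_loss)) "-" else
                sprintf("%.4f", x$meta$predictor_val_loss)))
  invisible(x)
}

#' Predict the within-range probability of coefficient vectors
#'
#' @param models Trained [train_surrogates()] networks.
#' @param theta Coefficient matrix (one row per candidate) or vector.
#' @param sc_features Matching rows of SC upper-triangle features.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_within_range <- function(models, theta, sc_features) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
  if (is.vector(sc_features)) sc_features <- matrix(sc_features, nrow = 1)
  fw <- classifier_fwd(models$classifier,
                       apply_norm(theta, models$norm$th),
                       apply_norm(sc_features, models$norm$sc))
  as.numeric(fw$prob)
}

#' Predict the three realism-cost components
#'
#' Valid for candidates assumed within range (the predictor is trained only
#' on within-range samples). Outputs pass through a softplus map, so all
#' predictions are non-negative.
#'
#' @param models Trained [train_surrogates()] networks.
#' @param theta,sc_features,fc_features,fcd_features Input matrices (one row
#'   per candidate).
#' @return Matrix with columns `corr_cost`, `mean_abs_diff`, `ks_cost`.
#' @export
predict_cost <- function(models, theta, sc_features, fc_features,
                         fcd_features) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
  fw <- predictor_fwd(models$predictor,
                      apply_norm(theta, models$norm$th),
                      apply_norm(sc_features, models$norm$sc),
                      apply_norm(fc_features, models$norm$fc),
                      apply_norm(fcd_features, models$norm$fcd))
  out <- sweep(cbind(fw$y_fc, fw$y_ks), 2, models$target_scale, "*")
  colnames(out) <- c("corr_cost", "mean_abs_diff", "ks_cost")
  out
}
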