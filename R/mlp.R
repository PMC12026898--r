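# Minimal multilayer-perceptron machinery (dense layers, tanh hidden
# activations, linear outputs) with hand-written backpropagation and Adam.
# Kept deliberately small: the surrogate networks are compositions of a few
# MLP blocks whose embeddings are combined by addition, so a full autograd
# framework is unnecessary.

mlp_new <- function(sizes, seed = 1L) {
  set.seed(seed)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

# forward pass; returns output and the activation cache for backprop
mlp_fwd <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  list(out = A[[L + 1]], A = A)
}

# backward pass given dL/d(output); returns parameter grads and dL/d(input)
mlp_bwd <- function(net, cache, d_out) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- d_out
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(cache$A[[l]], dZ)
    db[[l]] <- colSums(dZ)
    dA <- dZ %*% t(net$W[[l]])
    if (l > 1L) dZ <- dA * (1 - cache$A[[l]]^2)   # tanh'
  }
  list(W = dW, b = db, dX = dA)
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

# Adam state/update over a named list of mlp nets
adam_new <- function(nets) {
  zero_like <- function(net) list(W = lapply(net$W, function(w) w * 0),
                                  b = lapply(net$b, function(v) v * 0))
  list(m = lapply(nets, zero_like), v = lapply(nets, zero_like), t = 0L)
}

adam_step <- function(nets, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(nets)) {
    for (part in c("W", "b")) {
      for (l in seq_along(nets[[nm]][[part]])) {
        g <- grads[[nm]][[part]][[l]]
        if (weight_decay > 0 && part == "W") {
          g <- g + weight_decay * nets[[nm]][[part]][[l]]
        }
        st$m[[nm]][[part]][[l]] <- beta1 * st$m[[nm]][[part]][[l]] + (1 - beta1) * g
        st$v[[nm]][[part]][[l]] <- beta2 * st$v[[nm]][[part]][[l]] + (1 - beta2) * g^2
        nets[[nm]][[part]][[l]] <- nets[[nm]][[part]][[l]] -
          lr * (st$m[[nm]][[part]][[l]] / bc1) /
          (sqrt(st$v[[nm]][[part]][[l]] / bc2) + eps)
      }
    }
  }
  list(nets = nets, st = st)
}

# ---- within-range classifier: sigmoid(head(emb_theta(x) + emb_sc(x))) ----

classifier_new <- function(d_theta, d_sc, H = 64L, depth = 2L, seed = 1L) {
  hid <- rep(H, depth)
  list(
    emb_theta = mlp_new(c(d_theta, hid, H), seed = derive_seed(seed, 1L)),
    emb_sc = mlp_new(c(d_sc, hid, H), seed = derive_seed(seed, 2L)),
    head = mlp_new(c(H, H, 1L), seed = derive_seed(seed, 3L))
  )
}

classifier_fwd <- function(nets, Xth, Xsc) {
  cth <- mlp_fwd(nets$emb_theta, Xth)
  csc <- mlp_fwd(nets$emb_sc, Xsc)
  E <- cth$out + csc$out
  ch <- mlp_fwd(nets$head, E)
  list(prob = 1 / (1 + exp(-ch$out)), logits = ch$out,
       cth = cth, csc = csc, ch = ch)
}

classifier_grads <- function(nets, fw, y) {
  n <- length(y)
  dlogit <- (fw$prob - y) / n                     # BCE w.r.t. logits
  gh <- mlp_bwd(nets$head, fw$ch, dlogit)
  gth <- mlp_bwd(nets$emb_theta, fw$cth, gh$dX)
  gsc <- mlp_bwd(nets$emb_sc, fw$csc, gh$dX)
  list(emb_theta = gth, emb_sc = gsc, head = gh)
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- cost predictor: shared model embedding, FC head (1-r, d), FCD head (KS)

predictor_new <- function(d_theta, d_sc, d_fc, d_fcd, H = 64L, depth = 2L,
                          seed = 1L) {
  hid <- rep(H, depth)
  list(
    emb_theta = mlp_new(c(d_theta, hid, H), seed = derive_seed(seed, 4L)),
    emb_sc = mlp_new(c(d_sc, hid, H), seed = derive_seed(seed, 5L)),
    emb_fc = mlp_new(c(d_fc, hid, H), seed = derive_seed(seed, 6L)),
    emb_fcd = mlp_new(c(d_fcd, hid, H), seed = derive_seed(seed, 7L)),
    head_fc = mlp_new(c(H, H, 2L), seed = derive_seed(seed, 8L)),
    head_ks = mlp_new(c(H, H, 1L), seed = derive_seed(seed, 9L))
  )
}

predictor_fwd <- function(nets, Xth, Xsc, Xfc, Xfcd) {
  cth <- mlp_fwd(nets$emb_theta, Xth)
  csc <- mlp_fwd(nets$emb_sc, Xsc)
  cfc <- mlp_fwd(nets$emb_fc, Xfc)
  cfcd <- mlp_fwd(nets$emb_fcd, Xfcd)
  M <- cth$out + csc$out
  hfc <- mlp_fwd(nets$head_fc, M + cfc$out)
  hks <- mlp_fwd(nets$head_ks, M + cfcd$out)
  list(y_fc = softplus(hfc$out), y_ks = softplus(hks$out),
       cth = cth, csc = csc, cfc = cfc, cfcd = cfcd, hfc = hfc, hks = hks)
}

predictor_grads <- function(nets, fw, Y_fc, Y_ks) {
  n <- nrow(Y_fc)
  dz_fc <- 2 * (fw$y_fc - Y_fc) * stats::plogis(fw$hfc$out) / n
  dz_ks <- 2 * (fw$y_ks - Y_ks) * stats::plogis(fw$hks$out) / n
  g_hfc <- mlp_bwd(nets$head_fc, fw$hfc, dz_fc)
  g_hks <- mlp_bwd(nets$head_ks, fw$hks, dz_ks)
  dM <- g_hfc$dX + g_hks$dX
  list(
    emb_theta = mlp_bwd(nets$emb_theta, fw$cth, dM),
    emb_sc = mlp_bwd(nets$emb_sc, fw$csc, dM),
    emb_fc = mlp_bwd(nets$emb_fc, fw$cfc, g_hfc$dX),
    emb_fcd = mlp_bwd(nets$emb_fcd, fw$cfcd, g_hks$dX),
    head_fc = g_hfc, head_ks = g_hks
  )
}

mse_loss <- function(fw, Y_fc, Y_ks) {
  mean(rowSums((fw$y_fc - Y_fc)^2) + (fw$y_ks - Y_ks)^2)
}

# generic minibatch training loop: early stopping on validation loss, with
# learning-rate halving when validation plateaus for half the patience window
train_loop <- function(nets, step_fn, val_fn, n_train, hyper, seed) {
  st <- adam_new(nets)
  best <- list(nets = nets, loss = val_fn(nets), epoch = 0L)
  curve <- numeric(0)
  patience_left <- hyper$patience
  lr <- hyper$lr
  stall <- 0L
  for (ep in seq_len(hyper$max_epochs)) {
    set.seed(derive_seed(seed, ep, 23L))
    idx <- sample.int(n_train)
    batches <- split(idx, ceiling(seq_along(idx) / hyper$batch_size))
    for (bi in batches) {
      out <- step_fn(nets, st, bi, lr)
      nets <- out$nets; st <- out$st
    }
    vl <- val_fn(nets)
    curve <- c(curve, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(nets = nets, loss = vl, epoch = ep)
      patience_left <- hyper$patience
      stall <- 0L
    } else {
      patience_left <- patience_left - 1L
      stall <- stall + 1L
      if (patience_left <= 0L) break
      if (stall >= max(2L, hyper$patience %/% 2L)) {
        lr <- lr * 0.5
        stall <- 0L
      }
    }
  }
  list(nets = best$nets, val_loss = best$loss, best_epoch = best$epoch,
       curve = curve)
}
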