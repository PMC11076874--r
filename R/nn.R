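# Internal neural-network engine. The hot path (full-network forward and
# backward for a minibatch) lives in compiled code (src/nn_ops.cpp); this
# file owns parameter initialization, the AdamW optimizer with decoupled
# weight decay, the training loop with the stepped learning-rate schedule,
# and batched inference.

# One fused forward(/backward) call. y = NULL for inference.
nn_step <- function(params, spec, x, y = NULL, training = FALSE,
                    trainable = NULL) {
  if (ncol(x) != spec$input_len) {
    stopf("input windows have %d samples; the model expects %d",
          ncol(x), spec$input_len)
  }
  nb <- length(spec$channels)
  frozen <- if (is.null(trainable)) rep(0L, nb) else
    as.integer(!trainable$blocks)
  head_trainable <- if (is.null(trainable)) TRUE else trainable$head
  .nn_step_cpp(
    lapply(params$conv, `[[`, "W"),
    lapply(params$bn, `[[`, "gamma"),
    lapply(params$bn, `[[`, "beta"),
    lapply(params$bn, `[[`, "running_mean"),
    lapply(params$bn, `[[`, "running_var"),
    params$fc1$W, params$fc1$b, params$fc2$W, params$fc2$b,
    x,
    if (is.null(y)) integer(0) else as.integer(y),
    spec$kernels, spec$pool_after,
    training, frozen, head_trainable,
    spec$bn_eps, spec$bn_momentum)
}

# Write the updated BN running statistics back into the parameter list
# (only for blocks that are training and not frozen; the C++ side returns
# unchanged statistics for the others, so a blanket copy is safe).
nn_absorb_bn <- function(params, step) {
  for (blk in seq_along(params$bn)) {
    params$bn[[blk]]$running_mean <- as.numeric(step$new_rmean[[blk]])
    params$bn[[blk]]$running_var <- as.numeric(step$new_rvar[[blk]])
  }
  params
}

# Forward pass; returns B x n_classes probabilities. In training mode the
# returned params carry updated BN running statistics.
nn_forward <- function(params, spec, x, training = FALSE, trainable = NULL) {
  st <- nn_step(params, spec, x, y = NULL, training = training,
                trainable = trainable)
  if (training) params <- nn_absorb_bn(params, st)
  list(probs = st$probs, params = params)
}

nn_init_params <- function(spec, seed) {
  with_seed(seed, {
    nb <- length(spec$channels)
    cin <- 1L
    conv <- vector("list", nb)
    bn <- vector("list", nb)
    for (blk in seq_len(nb)) {
      cout <- spec$channels[blk]
      k <- spec$kernels[blk]
      fan_in <- cin * k
      conv[[blk]] <- list(W = matrix(stats::rnorm(cout * fan_in) *
                                       sqrt(2 / fan_in), cout, fan_in))
      bn[[blk]] <- list(gamma = rep(1, cout), beta = rep(0, cout),
                        running_mean = rep(0, cout),
                        running_var = rep(1, cout))
      cin <- cout
    }
    flat <- spec$channels[nb] * spec$input_len %/%
      (2L^length(spec$pool_after))
    fc1 <- list(W = matrix(stats::rnorm(spec$hidden * flat) *
                             sqrt(2 / flat), spec$hidden, flat),
                b = rep(0, spec$hidden))
    fc2 <- list(W = matrix(stats::rnorm(spec$n_classes * spec$hidden) *
                             sqrt(2 / spec$hidden), spec$n_classes,
                           spec$hidden),
                b = rep(0, spec$n_classes))
    list(conv = conv, bn = bn, fc1 = fc1, fc2 = fc2)
  })
}

adamw_init <- function(params) {
  zeros_like <- function(x) if (is.list(x)) lapply(x, zeros_like) else x * 0
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

# One AdamW step over the trainable tensors. Decoupled weight decay applies
# to convolution and fully-connected weight matrices only (not biases or
# batch-norm scale/shift). `grads` uses the layout produced by nn_train().
adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (blk in seq_along(params$conv)) {
    g <- grads$conv[[blk]]
    if (!is.null(g)) {
      m <- beta1 * state$m$conv[[blk]]$W + (1 - beta1) * g
      v <- beta2 * state$v$conv[[blk]]$W + (1 - beta2) * g * g
      state$m$conv[[blk]]$W <- m
      state$v$conv[[blk]]$W <- v
      params$conv[[blk]]$W <- params$conv[[blk]]$W -
        lr * ((m / bc1) / (sqrt(v / bc2) + eps) +
                weight_decay * params$conv[[blk]]$W)
    }
    for (nm in c("gamma", "beta")) {
      g <- grads$bn[[blk]][[nm]]
      if (is.null(g)) next
      m <- beta1 * state$m$bn[[blk]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v$bn[[blk]][[nm]] + (1 - beta2) * g * g
      state$m$bn[[blk]][[nm]] <- m
      state$v$bn[[blk]][[nm]] <- v
      params$bn[[blk]][[nm]] <- params$bn[[blk]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  for (fc in c("fc1", "fc2")) {
    if (is.null(grads[[fc]])) next
    for (nm in c("W", "b")) {
      g <- grads[[fc]][[nm]]
      m <- beta1 * state$m[[fc]][[nm]] + (1 - beta1) * g
      v <- beta2 * state$v[[fc]][[nm]] + (1 - beta2) * g * g
      state$m[[fc]][[nm]] <- m
      state$v[[fc]][[nm]] <- v
      decay <- if (nm == "W") weight_decay else 0
      params[[fc]][[nm]] <- params[[fc]][[nm]] -
        lr * ((m / bc1) / (sqrt(v / bc2) + eps) +
                decay * params[[fc]][[nm]])
    }
  }
  list(params = params, state = state)
}

# Training engine shared by spindle_cnn() and finetune(). Returns updated
# parameters plus a per-epoch log (epoch 0-based, lr, loss, accuracy).
nn_train <- function(params, spec, x, y, epochs, batch_size, lr0,
                     lr_decay_factor, lr_decay_every, weight_decay,
                     trainable, seed, verbose = FALSE) {
  n <- nrow(x)
  state <- adamw_init(params)
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    accuracy = numeric(0))
  with_seed(seed, {
    for (e in seq_len(epochs) - 1L) {
      lr <- lr0 * lr_decay_factor^(e %/% lr_decay_every)
      ord <- sample.int(n)
      tot_loss <- 0
      tot_correct <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        yb <- y[idx]
        st <- nn_step(params, spec, x[idx, , drop = FALSE], y = yb,
                      training = TRUE, trainable = trainable)
        if (!is.finite(st$loss)) {
          stopf(paste0("training diverged (non-finite loss) at epoch %d, ",
                       "lr = %g; consider a smaller learning rate ",
                       "(e.g. lr0 = 0.001)"), e, lr)
        }
        params <- nn_absorb_bn(params, st)
        tot_loss <- tot_loss + st$loss * length(idx)
        tot_correct <- tot_correct + sum((st$probs[, 2L] >= 0.5) == (yb == 1L))
        grads <- list(conv = lapply(seq_along(params$conv), function(b) {
                        if (trainable$blocks[b]) st$gconv[[b]] else NULL
                      }),
                      bn = lapply(seq_along(params$bn), function(b) {
                        if (!trainable$blocks[b]) return(NULL)
                        list(gamma = st$gbn_gamma[[b]],
                             beta = st$gbn_beta[[b]])
                      }),
                      fc1 = if (!is.null(st$gfc1_w))
                        list(W = st$gfc1_w, b = as.numeric(st$gfc1_b)),
                      fc2 = if (!is.null(st$gfc2_w))
                        list(W = st$gfc2_w, b = as.numeric(st$gfc2_b)))
        upd <- adamw_step(params, grads, state, lr, weight_decay)
        params <- upd$params
        state <- upd$state
      }
      log <- rbind(log, data.frame(epoch = e, lr = lr, loss = tot_loss / n,
                                   accuracy = tot_correct / n))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.5f  loss %.4f  acc %.4f",
                        e, lr, tot_loss / n, tot_correct / n))
      }
    }
  })
  list(params = params, log = log)
}

# Batched inference (BN running statistics, no caching).
nn_predict_probs <- function(params, spec, x, batch_size = 512L) {
  n <- nrow(x)
  out <- matrix(0, n, spec$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- nn_step(params, spec, x[idx, , drop = FALSE])$probs
  }
  out
}
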