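#' CNN architecture specification
#'
#' Describes the five-block 1D convolutional classifier: each block is
#' convolution (stride 1, "same" padding) -> batch normalization -> ReLU,
#' with average pooling (size 2, stride 2) after blocks 2 and 4, followed by
#' a fully-connected head (hidden ReLU layer, then a 2-unit softmax output).
#' The temporal geometry is governed only by the two pools, so a 300-sample
#' window reaches the head at 75 positions.
#'
#' @param channels output channels per conv block (exactly 5).
#' @param kernels odd kernel sizes per conv block (exactly 5).
#' @param pool_after blocks followed by average pooling; must be `c(2, 4)`.
#' @param hidden width of the fully-connected hidden layer.
#' @param input_len window length in samples (default 300 = 3 s at 100 Hz);
#'   must be divisible by 4.
#' @param n_classes number of output classes (2: non-spindle, spindle).
#' @param bn_eps batch-normalization variance epsilon.
#' @param bn_momentum running-statistics update rate.
#' @return an object of class `cnn_spec`.
#' @examples
#' cnn_spec()
#' @export
cnn_spec <- function(channels = c(16, 16, 32, 32, 64),
                     kernels = c(7, 7, 5, 5, 3),
                     pool_after = c(2, 4),
                     hidden = 64,
                     input_len = 300,
                     n_classes = 2,
                     bn_eps = 1e-5,
                     bn_momentum = 0.1) {
  if (length(channels) != 5L || length(kernels) != 5L) {
    stopf("the architecture has exactly 5 conv blocks; got %d channels / %d kernels",
          length(channels), length(kernels))
  }
  if (!identical(as.integer(pool_after), c(2L, 4L))) {
    stopf("pooling must sit after blocks 2 and 4")
  }
  if (any(kernels %% 2 == 0)) stopf("kernel sizes must be odd ('same' padding)")
  if (input_len %% 4 != 0) stopf("input_len must be divisible by 4 (two pools of 2)")
  structure(list(channels = as.integer(channels),
                 kernels = as.integer(kernels),
                 pool_after = as.integer(pool_after),
                 hidden = as.integer(hidden),
                 input_len = as.integer(input_len),
                 n_classes = as.integer(n_classes),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat("1D CNN spec: 5 conv blocks (Conv -> BatchNorm -> ReLU)\n")
  l <- x$input_len
  for (b in seq_along(x$channels)) {
    cat(sprintf("  block %d: conv(out=%d, k=%d, same) @ %d positions%s\n",
                b, x$channels[b], x$kernels[b], l,
                if (b %in% x$pool_after) " -> avgpool/2" else ""))
    if (b %in% x$pool_after) l <- l %/% 2L
  }
  cat(sprintf("  head: flatten(%d) -> FC(%d) -> ReLU -> FC(%d) -> softmax\n",
              x$channels[5] * l, x$hidden, x$n_classes))
  invisible(x)
}

default_trainable <- function(spec) {
  list(blocks = rep(TRUE, length(spec$channels)), head = TRUE)
}

#' Fit the sleep spindle CNN classifier
#'
#' Trains the five-block 1D CNN on a balanced window set with softmax
#' cross-entropy and an AdamW optimizer (decoupled weight decay). The
#' learning rate at (0-based) epoch e is
#' `lr0 * lr_decay_factor^floor(e / lr_decay_every)`. With `epochs = 0` the
#' model is returned initialized but untrained (useful for architecture
#' checks and as a transfer skeleton). Training is deterministic given
#' `seed` and the data.
#'
#' The literature default `lr0 = 0.1` is aggressive for AdamW; training
#' aborts with a diagnostic if the loss becomes non-finite, and
#' `lr0 = 0.001` is a safe alternative.
#'
#' @param windows a `window_set` from [build_window_set()], or a numeric
#'   matrix of windows (rows) with `y` supplied.
#' @param y 0/1 labels when `windows` is a matrix.
#' @param spec a [cnn_spec()].
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 128).
#' @param lr0 initial learning rate (default 0.1).
#' @param lr_decay_factor multiplicative decay (default 0.75).
#' @param lr_decay_every epochs between decays (default 3).
#' @param weight_decay AdamW decoupled weight decay (default 0.01), applied
#'   to convolution and fully-connected weights only.
#' @param seed integer RNG seed for initialization and batch shuffling.
#' @param init optional `spindle_cnn` model (or its parameter list) to start
#'   from instead of fresh initialization.
#' @param trainable optional trainability flags,
#'   `list(blocks = logical(5), head = logical(1))`; frozen tensors receive
#'   no updates and frozen batch-norm keeps its running statistics.
#' @param verbose print per-epoch progress.
#' @return an object of class `spindle_cnn` with components `spec`,
#'   `params`, `log` (per-epoch learning rate, loss, training accuracy),
#'   `trainable`, and `provenance`.
#' @seealso [predict.spindle_cnn()], [cross_validate()], [transfer_model()]
#' @export
spindle_cnn <- function(windows, y = NULL, spec = cnn_spec(),
                        epochs = 100, batch_size = 128,
                        lr0 = 0.1, lr_decay_factor = 0.75,
                        lr_decay_every = 3, weight_decay = 0.01,
                        seed = 1L, init = NULL, trainable = NULL,
                        verbose = FALSE) {
  if (inherits(windows, "window_set")) {
    x <- windows$x
    y <- windows$y
  } else {
    x <- as.matrix(windows)
    if (is.null(y)) stopf("y labels required when windows is a matrix")
  }
  if (!all(y %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (!all(is.finite(x))) stopf("windows contain non-finite values")
  if (ncol(x) != spec$input_len) {
    stopf("windows have %d samples but spec$input_len is %d",
          ncol(x), spec$input_len)
  }
  trainable <- trainable %||% default_trainable(spec)
  params <- if (is.null(init)) {
    nn_init_params(spec, seed)
  } else if (inherits(init, "spindle_cnn")) {
    if (!identical(unclass(init$spec), unclass(spec))) {
      stopf("init model's spec differs from the requested spec")
    }
    init$params
  } else {
    init
  }
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    accuracy = numeric(0))
  if (epochs > 0) {
    tr <- nn_train(params, spec, x, y, epochs = epochs,
                   batch_size = batch_size, lr0 = lr0,
                   lr_decay_factor = lr_decay_factor,
                   lr_decay_every = lr_decay_every,
                   weight_decay = weight_decay, trainable = trainable,
                   seed = seed, verbose = verbose)
    params <- tr$params
    log <- tr$log
  }
  structure(list(
    spec = spec, params = params, log = log, trainable = trainable,
    provenance = list(
      n_windows = nrow(x), class_counts = table(y),
      epochs = epochs, batch_size = batch_size, lr0 = lr0,
      lr_decay_factor = lr_decay_factor, lr_decay_every = lr_decay_every,
      weight_decay = weight_decay, seed = seed,
      data_fingerprint = sum(x) + sum(y)
    )
  ), class = "spindle_cnn")
}

#' @export
print.spindle_cnn <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Sleep spindle CNN (%s)\n",
              if (nrow(x$log)) sprintf("trained %d epoch(s) on %d windows",
                                       nrow(x$log), p$n_windows)
              else "initialized, untrained"))
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final training loss %.4f, accuracy %.4f (lr %.5f)\n",
                last$loss, last$accuracy, last$lr))
  }
  if (!all(x$trainable$blocks) || !x$trainable$head) {
    cat(sprintf("  trainable: blocks [%s], head %s\n",
                paste(ifelse(x$trainable$blocks, "+", "frozen"),
                      collapse = " "),
                if (x$trainable$head) "+" else "frozen"))
  }
  invisible(x)
}

#' @export
summary.spindle_cnn <- function(object, ...) {
  print(object)
  print(object$spec)
  n_par <- sum(vapply(object$params$conv, function(l) length(l$W), 0)) +
    sum(vapply(object$params$bn, function(l) length(l$gamma) * 2, 0)) +
    length(object$params$fc1$W) + length(object$params$fc1$b) +
    length(object$params$fc2$W) + length(object$params$fc2$b)
  cat(sprintf("  learnable parameters: %d\n", as.integer(n_par)))
  invisible(object)
}

#' @export
coef.spindle_cnn <- function(object, ...) object$params

#' Predict spindle probabilities or classes
#'
#' In inference mode the network is a pure function of its parameters and
#' input (batch-norm uses frozen running statistics), so predictions are
#' batch-order independent.
#'
#' @param object a fitted [spindle_cnn()].
#' @param newdata a `window_set` or a windows matrix (rows = windows).
#' @param type `"prob"` (n x 2 matrix of class probabilities), `"score"`
#'   (spindle-class probability vector, the score used for ROC/AUC), or
#'   `"class"` (0/1 labels at the 0.5 / argmax threshold).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.spindle_cnn <- function(object, newdata,
                                type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "window_set")) newdata$x else as.matrix(newdata)
  probs <- nn_predict_probs(object$params, object$spec, x)
  colnames(probs) <- c("nonspindle", "spindle")
  switch(type,
    prob = probs,
    score = probs[, 2L],
    class = as.integer(probs[, 2L] >= 0.5)
  )
}

#' Plot training history
#'
#' @param x a fitted [spindle_cnn()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.spindle_cnn <- function(x, ...) {
  if (!nrow(x$log)) stopf("model has no training log")
  graphics::plot(x$log$epoch, x$log$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' The on-disk object holds the architecture spec, every parameter array
#' (including batch-norm running statistics) and the training provenance;
#' the round trip is bitwise lossless.
#'
#' @param model a [spindle_cnn()].
#' @param path file path.
#' @return `path` invisibly for save; the model for load.
#' @export
save_spindle_cnn <- function(model, path) {
  stopifnot(inherits(model, "spindle_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_spindle_cnn
#' @param spec optional [cnn_spec()] the loaded model must match; a
#'   mismatch (e.g. different kernel sizes) is an error.
#' @export
read_spindle_cnn <- function(path, spec = NULL) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stopf("cannot parse model file '%s': %s", path, conditionMessage(e))
  })
  if (!inherits(model, "spindle_cnn")) {
    stopf("file '%s' does not contain a spindle_cnn model", path)
  }
  if (!is.null(spec) && !identical(unclass(model$spec), unclass(spec))) {
    stopf("loaded model's architecture differs from the requested spec")
  }
  model
}
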