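# Transfer learning: carry convolutional blocks (with their batch-norm
# parameters and running statistics) from a model trained on a source
# cohort into a fresh model for a target cohort, re-initialize the rest,
# and optionally freeze the transferred part during finetuning.

#' Prepare a model for transfer learning
#'
#' Two modes mirror the two published transfer schemes:
#' \describe{
#'   \item{`"all_conv"`}{all five conv blocks are transferred; only the
#'     fully-connected head is (re-initialized and) trainable.}
#'   \item{`"first_four"`}{conv blocks 1-4 are transferred; block 5 and the
#'     head are re-initialized and trainable.}
#' }
#' The head is always re-initialized (both schemes retrain it from
#' scratch). With `freeze_transferred = TRUE` (default) the transferred
#' blocks - including batch-norm running statistics - receive no updates
#' during [finetune()], so they stay bitwise identical; with `FALSE` the
#' whole network is fine-tuned from the transferred initialization.
#'
#' @param source a fitted [spindle_cnn()] trained on the source domain.
#' @param mode `"all_conv"` or `"first_four"`.
#' @param freeze_transferred freeze the transferred blocks (default TRUE).
#' @param seed seed for re-initializing the non-transferred tensors.
#' @return an untrained `spindle_cnn` carrying the transferred parameters
#'   and trainability flags, ready for [finetune()].
#' @export
transfer_model <- function(source, mode = c("all_conv", "first_four"),
                           freeze_transferred = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(source, "spindle_cnn"))
  spec <- source$spec
  nb <- length(spec$channels)
  n_transfer <- if (mode == "all_conv") nb else nb - 1L
  fresh <- nn_init_params(spec, seed)
  params <- fresh
  for (blk in seq_len(n_transfer)) {
    params$conv[[blk]] <- source$params$conv[[blk]]
    params$bn[[blk]] <- source$params$bn[[blk]]
  }
  trainable <- list(
    blocks = c(rep(!freeze_transferred, n_transfer),
               rep(TRUE, nb - n_transfer)),
    head = TRUE
  )
  structure(list(
    spec = spec, params = params,
    log = data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     accuracy = numeric(0)),
    trainable = trainable,
    provenance = list(transfer_mode = mode,
                      freeze_transferred = freeze_transferred,
                      n_transferred_blocks = n_transfer, seed = seed,
                      source_provenance = source$provenance)
  ), class = "spindle_cnn")
}

#' Fine-tune a transferred model on target-domain windows
#'
#' Runs the standard training loop respecting the model's trainability
#' flags: frozen parameters (and frozen batch-norm statistics) are bitwise
#' identical before and after.
#'
#' @param model a `spindle_cnn` from [transfer_model()] (or any model with
#'   trainability flags set).
#' @param windows target-domain `window_set`.
#' @param ... training arguments passed to [spindle_cnn()] (`epochs`,
#'   `lr0`, `seed`, ...).
#' @return the fine-tuned `spindle_cnn`.
#' @export
finetune <- function(model, windows, ...) {
  stopifnot(inherits(model, "spindle_cnn"))
  fit <- spindle_cnn(windows, spec = model$spec, init = model$params,
                     trainable = model$trainable, ...)
  fit$provenance <- c(fit$provenance,
                      model$provenance[c("transfer_mode",
                                         "freeze_transferred",
                                         "n_transferred_blocks")])
  fit$trainable <- model$trainable
  fit
}

#' Compare transfer-learning schemes between two domains
#'
#' Trains a source-domain model on all source windows, then for each
#' requested transfer mode runs k-fold cross-validation on the target
#' window set: per fold, the source model is transferred, fine-tuned on the
#' fold's training windows and evaluated on its test windows. The
#' un-finetuned source model evaluated on the same test folds is reported
#' as the no-transfer baseline.
#'
#' @param source_windows source-domain `window_set` (e.g. normal regime).
#' @param target_windows target-domain `window_set` (e.g. insomnia regime).
#' @param spec a [cnn_spec()].
#' @param modes transfer modes to evaluate.
#' @param k folds on the target set.
#' @param grouping fold grouping (see [make_folds()]).
#' @param freeze_transferred freeze transferred blocks during finetuning.
#' @param seed base seed.
#' @param source_args list of training arguments for the source fit.
#' @param finetune_args list of training arguments for each finetune.
#' @return an object of class `transfer_report`: `source_fit`, `baseline`
#'   (per-fold metrics of the unadapted source model), and one `spindle_cv`
#'   style table per mode in `reports`.
#' @export
transfer_experiment <- function(source_windows, target_windows,
                                spec = cnn_spec(),
                                modes = c("all_conv", "first_four"),
                                k = 5, grouping = "by_subject",
                                freeze_transferred = TRUE, seed = 1L,
                                source_args = list(),
                                finetune_args = list()) {
  source_fit <- do.call(spindle_cnn, c(
    list(source_windows, spec = spec, seed = derive_seed(seed, "source")),
    source_args))
  folds <- make_folds(target_windows, k = k, grouping = grouping,
                      seed = seed)
  metric_cols <- c("accuracy", "recall", "f1", "precision", "auc")
  eval_fold <- function(fit, f) {
    test_ws <- target_windows[folds[[f]]$test]
    compute_metrics(test_ws$y, predict(fit, test_ws, type = "score"))
  }
  baseline <- do.call(rbind, lapply(seq_along(folds), function(f) {
    data.frame(fold = f, t(eval_fold(source_fit, f)))
  }))
  reports <- list()
  for (mode in modes) {
    per_fold <- NULL
    for (f in seq_along(folds)) {
      tm <- transfer_model(source_fit, mode = mode,
                           freeze_transferred = freeze_transferred,
                           seed = derive_seed(seed, paste(mode, f)))
      ft <- do.call(finetune, c(
        list(tm, target_windows[folds[[f]]$train],
             seed = derive_seed(seed, paste(mode, "ft", f))),
        finetune_args))
      per_fold <- rbind(per_fold, data.frame(fold = f, t(eval_fold(ft, f))))
    }
    reports[[mode]] <- list(per_fold = per_fold,
                            mean = colMeans(per_fold[, metric_cols]),
                            sd = apply(per_fold[, metric_cols], 2L,
                                       stats::sd))
  }
  structure(list(source_fit = source_fit, baseline = baseline,
                 baseline_mean = colMeans(baseline[, metric_cols]),
                 reports = reports, modes = modes, k = k, seed = seed),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("Transfer experiment (%d folds)\n", x$k))
  cat(sprintf("  no-transfer baseline: accuracy %.4f, auc %.4f\n",
              x$baseline_mean[["accuracy"]], x$baseline_mean[["auc"]]))
  for (mode in x$modes) {
    r <- x$reports[[mode]]
    cat(sprintf("  %-11s: accuracy %.4f (%.4f), auc %.4f (%.4f)\n", mode,
                r$mean[["accuracy"]], r$sd[["accuracy"]],
                r$mean[["auc"]], r$sd[["auc"]]))
  }
  invisible(x)
}
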