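# Subject-grouped k-fold cross-validation and the per-fold evaluation
# report (accuracy / recall / F1 / precision / AUC, mean and sd).

#' Build cross-validation folds
#'
#' With `grouping = "by_subject"` (the default, matching cross-subject
#' training and testing) the subjects are partitioned into `k` folds, so no
#' subject contributes windows to both the train and test side of any fold.
#' `"by_window"` partitions windows directly.
#'
#' @param window_set a `window_set`.
#' @param k number of folds (default 5).
#' @param grouping `"by_subject"` or `"by_window"`.
#' @param seed RNG seed for the partition.
#' @return a list of `k` elements, each `list(train, test)` of window
#'   indices; the test sets partition all windows.
#' @export
make_folds <- function(window_set, k = 5, grouping = c("by_subject",
                                                       "by_window"),
                       seed = 1L) {
  grouping <- match.arg(grouping)
  n <- length(window_set$y)
  if (grouping == "by_subject") {
    subjects <- sort(unique(window_set$subject_id))
    if (length(subjects) < k) {
      stopf("%d subject(s) cannot be split into %d subject-grouped folds",
            length(subjects), k)
    }
    assignment <- with_seed(seed, {
      perm <- sample(subjects)
      unname(split(perm, rep_len(seq_len(k), length(perm))))
    })
    lapply(assignment, function(test_subjects) {
      test <- which(window_set$subject_id %in% test_subjects)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  } else {
    assignment <- with_seed(seed, sample(rep_len(seq_len(k), n)))
    lapply(seq_len(k), function(f) {
      test <- which(assignment == f)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  }
}

#' Cross-validated training and evaluation
#'
#' Fits the CNN on each fold's training windows and evaluates the five
#' metrics on the held-out windows, mirroring a per-fold results table with
#' a final mean (standard deviation) row.
#'
#' @param window_set a `window_set`.
#' @param spec a [cnn_spec()].
#' @param k folds (default 5).
#' @param grouping fold grouping, see [make_folds()].
#' @param seed base seed: folds, per-fold initialization and shuffling are
#'   derived from it.
#' @param keep_models keep the fitted per-fold models in the report.
#' @param ... training arguments passed to [spindle_cnn()] (`epochs`,
#'   `lr0`, ...).
#' @return an object of class `spindle_cv`: `per_fold` (data frame of fold
#'   metrics), `mean`, `sd`, `folds`, and per-window `predictions`.
#' @export
cross_validate <- function(window_set, spec = cnn_spec(), k = 5,
                           grouping = "by_subject", seed = 1L,
                           keep_models = FALSE, ...) {
  folds <- make_folds(window_set, k = k, grouping = grouping, seed = seed)
  per_fold <- NULL
  models <- list()
  predictions <- data.frame(window = integer(0), fold = integer(0),
                            label = integer(0), score = numeric(0))
  for (f in seq_along(folds)) {
    train_ws <- window_set[folds[[f]]$train]
    test_ws <- window_set[folds[[f]]$test]
    fit <- spindle_cnn(train_ws, spec = spec,
                       seed = derive_seed(seed, paste0("fold", f)), ...)
    score <- predict(fit, test_ws, type = "score")
    m <- compute_metrics(test_ws$y, score)
    per_fold <- rbind(per_fold, data.frame(fold = f, t(m)))
    predictions <- rbind(predictions, data.frame(
      window = folds[[f]]$test, fold = f, label = test_ws$y, score = score))
    if (keep_models) models[[f]] <- fit
  }
  metric_cols <- c("accuracy", "recall", "f1", "precision", "auc")
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, metric_cols]),
    sd = apply(per_fold[, metric_cols], 2L, stats::sd),
    folds = folds, predictions = predictions,
    models = if (keep_models) models else NULL,
    grouping = grouping, seed = seed
  ), class = "spindle_cv")
}

#' @export
print.spindle_cv <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", nrow(x$per_fold),
              x$grouping))
  tab <- x$per_fold
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat("Average (standard deviation):\n")
  cat(paste(sprintf("  %s %.4f (%.4f)", names(x$mean), x$mean, x$sd),
            collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.spindle_cv <- function(x, ...) x$per_fold
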