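# Balanced window extraction: 3 s positives centred on annotated spindle
# midpoints, and an equal number of 3 s negatives sampled from unannotated
# stretches of the same subject and channel.

new_window_set <- function(x, y, subject_id, channel, start_s, fs, window_s,
                           provenance = list()) {
  structure(list(x = x, y = as.integer(y), subject_id = subject_id,
                 channel = channel, start_s = start_s, fs = fs,
                 window_s = window_s, provenance = provenance),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(paste0("Window set: %d windows of %g s @ %g Hz (%d samples); ",
                     "%d spindle / %d non-spindle; %d subject(s)\n"),
              length(x$y), x$window_s, x$fs, ncol(x$x),
              sum(x$y == 1L), sum(x$y == 0L), length(unique(x$subject_id))))
  invisible(x)
}

#' @export
`[.window_set` <- function(x, i, ...) {
  new_window_set(x$x[i, , drop = FALSE], x$y[i], x$subject_id[i],
                 x$channel[i], x$start_s[i], x$fs, x$window_s, x$provenance)
}

#' @export
length.window_set <- function(x) length(x$y)

# rbind-style combination of window sets with identical geometry
combine_window_sets <- function(sets) {
  sets <- Filter(function(s) length(s$y) > 0L, sets)
  if (!length(sets)) stopf("no windows to combine")
  fs <- unique(vapply(sets, `[[`, 0, "fs"))
  ws <- unique(vapply(sets, `[[`, 0, "window_s"))
  if (length(fs) != 1L || length(ws) != 1L) {
    stopf("window sets have inconsistent fs or window length")
  }
  new_window_set(
    do.call(rbind, lapply(sets, `[[`, "x")),
    unlist(lapply(sets, `[[`, "y")),
    unlist(lapply(sets, `[[`, "subject_id")),
    unlist(lapply(sets, `[[`, "channel")),
    unlist(lapply(sets, `[[`, "start_s")),
    fs, ws
  )
}

#' Extract positive (spindle) windows
#'
#' One window per annotation, centred on the event midpoint
#' `onset + duration / 2` and spanning `window_s` seconds as a half-open
#' sample interval. Annotations whose window would cross a recording
#' boundary are dropped with a warning counting the drops.
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param annotations annotation data frame for this subject (rows for other
#'   channels than the recording's are ignored).
#' @param window_s window length in seconds (default 3).
#' @return a `window_set` of positives (label 1).
#' @export
extract_positives <- function(recording, annotations, window_s = 3) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs_hz
  nw <- round(window_s * fs)
  n <- ncol(recording$signal)
  ann <- annotations[annotations$channel %in% recording$channels, ,
                     drop = FALSE]
  out <- list()
  dropped <- 0L
  keep_x <- list(); keep_meta <- list()
  k <- 0L
  for (j in seq_len(nrow(ann))) {
    mid <- ann$onset_s[j] + ann$duration_s[j] / 2
    i0 <- round(mid * fs) - nw %/% 2L   # 0-based start sample
    if (i0 < 0L || i0 + nw > n) {
      dropped <- dropped + 1L
      next
    }
    k <- k + 1L
    keep_x[[k]] <- recording$signal[ann$channel[j], (i0 + 1L):(i0 + nw)]
    keep_meta[[k]] <- list(channel = ann$channel[j], start_s = i0 / fs)
  }
  if (dropped > 0L) {
    warnf("dropped %d positive window(s) crossing the recording boundary",
          dropped)
  }
  x <- if (k > 0L) do.call(rbind, keep_x) else matrix(0, 0L, nw)
  new_window_set(
    x, rep(1L, k),
    rep(recording$subject_id, k),
    vapply(keep_meta, function(m) m$channel, "", USE.NAMES = FALSE),
    vapply(keep_meta, function(m) m$start_s, 0, USE.NAMES = FALSE),
    fs, window_s
  )
}

# Allowed 0-based start samples for negatives on one channel: the window
# [s, s + nw) must stay >= guard_s away from every annotated event.
allowed_negative_starts <- function(n, nw, fs, onsets, durations, guard_s) {
  ok <- rep(TRUE, n - nw + 1L)  # index i <-> start sample i - 1
  for (j in seq_along(onsets)) {
    lo <- onsets[j] - guard_s          # forbidden interval in seconds
    hi <- onsets[j] + durations[j] + guard_s
    # window [s/fs, s/fs + nw/fs) intersects (lo, hi) iff
    # s/fs < hi and s/fs + nw/fs > lo
    s_lo <- floor(lo * fs - nw) + 1L   # first start beyond "ends before lo"
    s_hi <- ceiling(hi * fs) - 1L      # last start with s/fs < hi
    s_lo <- max(s_lo, 0L)
    s_hi <- min(s_hi, n - nw)
    if (s_lo <= s_hi) ok[(s_lo + 1L):(s_hi + 1L)] <- FALSE
  }
  which(ok) - 1L
}

#' Sample negative (non-spindle) windows
#'
#' Draws `n` windows of `window_s` seconds uniformly (seeded) from the parts
#' of each requested channel lying at least `guard_s` seconds away from
#' every annotated event. Negatives never overlap an event and never
#' overlap each other (drawn without replacement).
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param annotations annotation data frame (events to avoid).
#' @param n number of negatives to draw per call.
#' @param window_s window length in seconds.
#' @param guard_s exclusion margin around events in seconds (default 0.5).
#' @param seed integer RNG seed.
#' @param channel channel to sample from (default: first channel).
#' @return a `window_set` of negatives (label 0).
#' @export
sample_negatives <- function(recording, annotations, n, window_s = 3,
                             guard_s = 0.5, seed = 1L,
                             channel = recording$channels[1]) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs_hz
  nw <- round(window_s * fs)
  nsamp <- ncol(recording$signal)
  ann <- annotations[annotations$channel == channel, , drop = FALSE]
  starts_ok <- allowed_negative_starts(nsamp, nw, fs, ann$onset_s,
                                       ann$duration_s, guard_s)
  chosen <- integer(0)
  with_seed(seed, {
    avail <- starts_ok
    while (length(chosen) < n) {
      if (!length(avail)) {
        stopf(paste0("cannot place %d non-overlapping negatives on channel ",
                     "'%s'; at most ~%d are feasible"),
              n, channel,
              length(chosen) + length(starts_ok) %/% max(1L, nw))
        }
      s <- avail[sample.int(length(avail), 1L)]
      chosen <- c(chosen, s)
      avail <- avail[avail + nw <= s | avail >= s + nw]
    }
  })
  chosen <- sort(chosen)
  x <- if (n > 0L) {
    t(vapply(chosen, function(s) recording$signal[channel, (s + 1L):(s + nw)],
             numeric(nw)))
  } else {
    matrix(0, 0L, nw)
  }
  new_window_set(x, rep(0L, n), rep(recording$subject_id, n),
                 rep(channel, n), chosen / fs, fs, window_s)
}

#' Build the balanced labeled window set for a cohort
#'
#' For every subject and channel: all boundary-respecting positive windows
#' plus an equal number of negatives from the same channel, so the class
#' balance holds per (subject, channel) and hence globally. Negative
#' sampling is seeded per (subject, channel) from `seed`, so the result is
#' deterministic and invariant to subject ordering.
#'
#' @param cohort list of `list(recording, annotations)` pairs (recordings
#'   already preprocessed), as produced by [simulate_cohort()] followed by
#'   [preprocess_recording()].
#' @param window_s window length in seconds (default 3; 300 samples at the
#'   default 100 Hz).
#' @param guard_s negative exclusion margin around events in seconds.
#' @param seed base RNG seed.
#' @param zscore_scope if `"per_window"`, each window is z-scored
#'   individually here; the default assumes recordings were z-scored during
#'   preprocessing.
#' @return a `window_set` with provenance (parameters + seed).
#' @examples
#' cohort <- simulate_cohort(2, generator_config(record_duration_s = 120, seed = 1))
#' cohort <- lapply(cohort, function(s) {
#'   s$recording <- preprocess_recording(s$recording)
#'   s
#' })
#' build_window_set(cohort, seed = 1)
#' @export
build_window_set <- function(cohort, window_s = 3, guard_s = 0.5, seed = 1L,
                             zscore_scope = c("per_channel_recording",
                                              "per_window")) {
  zscore_scope <- match.arg(zscore_scope)
  parts <- list()
  for (subj in cohort) {
    rec <- subj$recording
    ann <- subj$annotations
    for (ch in rec$channels) {
      pos <- extract_positives(
        rec, ann[ann$channel == ch, , drop = FALSE], window_s)
      if (length(pos$y) == 0L) next
      neg <- sample_negatives(
        rec, ann, n = length(pos$y), window_s = window_s, guard_s = guard_s,
        seed = derive_seed(seed, paste(rec$subject_id, ch)), channel = ch)
      parts[[length(parts) + 1L]] <- pos
      parts[[length(parts) + 1L]] <- neg
    }
  }
  ws <- combine_window_sets(parts)
  if (zscore_scope == "per_window") {
    mu <- rowMeans(ws$x)
    sdv <- apply(ws$x, 1L, stats::sd)
    if (any(sdv == 0)) stopf("zero-variance window; cannot z-score per window")
    ws$x <- (ws$x - mu) / sdv
  }
  ws$provenance <- list(window_s = window_s, guard_s = guard_s, seed = seed,
                        zscore_scope = zscore_scope)
  ws
}
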