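make_flat_recording <- function(n_s = 60, fs = 100, subject = "S01") {
  # deterministic ramp so window content identifies its source position
  eeg_recording(rbind(seq_len(n_s * fs), -seq_len(n_s * fs)), fs,
                c("C3", "C4"), subject)
}

ann_row <- function(onset, dur, ch = "C3", subject = "S01") {
  data.frame(subject_id = subject, channel = ch, onset_s = onset,
             duration_s = dur, stringsAsFactors = FALSE)
}

test_that("positive windows are centred on the annotation midpoint", {
  rec <- make_flat_recording()
  ann <- ann_row(10.0, 1.0)   # midpoint 10.5 s -> samples [900, 1200)
  pos <- extract_positives(rec, ann, window_s = 3)
  expect_equal(length(pos$y), 1L)
  expect_equal(ncol(pos$x), 300L)
  expect_equal(pos$start_s, 9.0)
  expect_equal(pos$x[1, ], as.numeric(901:1200))   # 0-based [900, 1200)
  # centring within one sample for fractional midpoints
  ann2 <- ann_row(10.013, 0.5)
  pos2 <- extract_positives(rec, ann2, window_s = 3)
  mid <- ann2$onset_s + ann2$duration_s / 2
  centre <- pos2$start_s + 1.5
  expect_lte(abs(centre - mid) * rec$fs_hz, 1)
})

test_that("boundary-crossing positives are dropped and counted", {
  rec <- make_flat_recording()
  ann <- rbind(ann_row(0.2, 0.4),     # midpoint 0.4 s -> start -1.1 s
               ann_row(10, 1))
  expect_warning(pos <- extract_positives(rec, ann), "1 positive")
  expect_equal(length(pos$y), 1L)
  # without boundary violations the map is one-to-one
  ann_ok <- do.call(rbind, lapply(seq(5, 50, by = 5), ann_row, dur = 1))
  pos_ok <- extract_positives(rec, ann_ok)
  expect_equal(length(pos_ok$y), nrow(ann_ok))
})

test_that("negatives avoid events, the guard margin, and each other", {
  sim <- simulate_recording(test_config(duration = 120, seed = 17))
  rec <- preprocess_recording(sim$recording)
  ann <- sim$annotations
  neg <- sample_negatives(rec, ann, n = 20, guard_s = 0.5, seed = 3,
                          channel = "C3")
  expect_equal(length(neg$y), 20L)
  expect_true(all(neg$y == 0L))
  ev <- ann[ann$channel == "C3", ]
  for (i in seq_len(20)) {
    w_lo <- neg$start_s[i]
    w_hi <- w_lo + 3
    # exhaustive interval check against every event (with guard)
    expect_false(any(w_lo < ev$onset_s + ev$duration_s + 0.5 &
                       w_hi > ev$onset_s - 0.5),
                 info = sprintf("negative %d overlaps an event", i))
  }
  # pairwise non-overlap among negatives
  s <- sort(neg$start_s)
  expect_true(all(diff(s) >= 3))
})

test_that("negatives are unconstrained without annotations and bounded by space", {
  rec <- make_flat_recording(n_s = 60)
  none <- sample_negatives(rec, spindlecnn:::empty_annotations(), n = 10,
                           seed = 1)
  expect_equal(length(none$y), 10L)
  expect_error(
    sample_negatives(rec, spindlecnn:::empty_annotations(), n = 50, seed = 1),
    "feasible")
})

test_that("window sets are balanced per subject-channel and deterministic", {
  cohort <- test_cohort(2, duration = 120, seed = 19)
  ws <- suppressWarnings(build_window_set(cohort, seed = 7))
  tab <- table(paste(ws$subject_id, ws$channel), ws$y)
  expect_true(all(tab[, "0"] == tab[, "1"]))
  expect_equal(sum(ws$y == 0L), sum(ws$y == 1L))
  ws2 <- suppressWarnings(build_window_set(cohort, seed = 7))
  expect_identical(ws$x, ws2$x)
  expect_identical(ws$start_s, ws2$start_s)
  # subject order must not change the multiset of windows
  ws_rev <- suppressWarnings(build_window_set(rev(cohort), seed = 7))
  key <- function(w) sort(paste(w$subject_id, w$channel, w$start_s, w$y))
  expect_identical(key(ws), key(ws_rev))
})

test_that("negative windows never intersect any annotated event", {
  cohort <- test_cohort(2, duration = 120, seed = 23)
  ws <- suppressWarnings(build_window_set(cohort, seed = 11))
  ann_all <- do.call(rbind, lapply(cohort, `[[`, "annotations"))
  neg <- which(ws$y == 0L)
  hits <- 0L
  for (i in neg) {
    ev <- ann_all[ann_all$subject_id == ws$subject_id[i] &
                    ann_all$channel == ws$channel[i], ]
    w_lo <- ws$start_s[i]
    w_hi <- w_lo + ws$window_s
    hits <- hits + sum(w_lo < ev$onset_s + ev$duration_s & w_hi > ev$onset_s)
  }
  expect_equal(hits, 0L)
})

test_that("per-window z-scoring normalizes each window", {
  cohort <- test_cohort(1, duration = 120, seed = 29)
  ws <- suppressWarnings(build_window_set(cohort, seed = 3,
                                          zscore_scope = "per_window"))
  expect_lt(max(abs(rowMeans(ws$x))), 1e-10)
  expect_lt(max(abs(apply(ws$x, 1, stats::sd) - 1)), 1e-10)
})

test_that("window sets subset and combine consistently", {
  ws <- test_window_set(2, duration = 90, seed = 31)
  idx <- which(ws$y == 1L)[1:5]
  sub <- ws[idx]
  expect_equal(length(sub), 5L)
  expect_true(all(sub$y == 1L))
  expect_identical(sub$x, ws$x[idx, , drop = FALSE])
})
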