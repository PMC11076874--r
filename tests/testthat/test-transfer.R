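source_fit <- local({
  ws <- test_window_set(2, duration = 120, seed = 61)
  spindle_cnn(ws, epochs = 2, lr0 = 0.003, seed = 13)
})

test_that("all-conv transfer copies every block and re-initializes the head", {
  tm <- transfer_model(source_fit, mode = "all_conv", seed = 99)
  for (b in 1:5) {
    expect_identical(tm$params$conv[[b]], source_fit$params$conv[[b]])
    expect_identical(tm$params$bn[[b]], source_fit$params$bn[[b]])
  }
  expect_false(identical(tm$params$fc1$W, source_fit$params$fc1$W))
  expect_false(identical(tm$params$fc2$W, source_fit$params$fc2$W))
  expect_identical(tm$trainable$blocks, rep(FALSE, 5))
  expect_true(tm$trainable$head)
})

test_that("first-four transfer re-initializes block 5 and keeps blocks 1-4", {
  tm <- transfer_model(source_fit, mode = "first_four", seed = 99)
  for (b in 1:4) {
    expect_identical(tm$params$conv[[b]], source_fit$params$conv[[b]])
  }
  expect_false(identical(tm$params$conv[[5]], source_fit$params$conv[[5]]))
  expect_identical(tm$trainable$blocks, c(rep(FALSE, 4), TRUE))
})

test_that("all-conv trainable set is strictly contained in first-four's", {
  a <- transfer_model(source_fit, mode = "all_conv")$trainable
  b <- transfer_model(source_fit, mode = "first_four")$trainable
  expect_true(all(which(a$blocks) %in% which(b$blocks)))
  expect_gt(sum(b$blocks), sum(a$blocks))
  expect_true(a$head && b$head)
})

test_that("frozen parameters are bitwise unchanged by finetuning", {
  target <- test_window_set(2, duration = 120, regime = "insomnia",
                            seed = 67)
  for (mode in c("all_conv", "first_four")) {
    tm <- transfer_model(source_fit, mode = mode, seed = 5)
    ft <- finetune(tm, target, epochs = 2, lr0 = 0.003, seed = 8)
    n_frozen <- sum(!tm$trainable$blocks)
    for (b in seq_len(n_frozen)) {
      expect_identical(ft$params$conv[[b]], tm$params$conv[[b]])
      expect_identical(ft$params$bn[[b]], tm$params$bn[[b]])
    }
    # the trainable tail actually moved
    expect_false(identical(ft$params$fc2$W, tm$params$fc2$W))
    if (mode == "first_four") {
      expect_false(identical(ft$params$conv[[5]], tm$params$conv[[5]]))
    }
    # transfer never changes the spec or output shape
    expect_identical(ft$spec, source_fit$spec)
    p <- predict(ft, target$x[1:3, , drop = FALSE])
    expect_equal(dim(p), c(3L, 2L))
  }
})

test_that("unfrozen transfer fine-tunes every block", {
  target <- test_window_set(1, duration = 90, regime = "insomnia", seed = 71)
  tm <- transfer_model(source_fit, mode = "all_conv",
                       freeze_transferred = FALSE, seed = 5)
  expect_true(all(tm$trainable$blocks))
  ft <- finetune(tm, target, epochs = 1, lr0 = 0.003, seed = 8)
  expect_false(identical(ft$params$conv[[1]], tm$params$conv[[1]]))
})

test_that("transfer between incompatible architectures is rejected", {
  tm <- transfer_model(source_fit, mode = "all_conv", seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_spindle_cnn(tm, path)
  expect_error(read_spindle_cnn(path, spec = cnn_spec(hidden = 32)),
               "differs")
})

test_that("a transfer experiment reports a baseline plus one table per mode", {
  source_ws <- test_window_set(2, duration = 120, seed = 73)
  target_ws <- test_window_set(2, duration = 120, regime = "insomnia",
                               seed = 79)
  tr <- transfer_experiment(source_ws, target_ws, k = 2,
                            modes = c("all_conv", "first_four"), seed = 3,
                            source_args = list(epochs = 2, lr0 = 0.003),
                            finetune_args = list(epochs = 1, lr0 = 0.003))
  expect_s3_class(tr, "transfer_report")
  expect_named(tr$reports, c("all_conv", "first_four"))
  expect_equal(nrow(tr$baseline), 2L)
  for (mode in names(tr$reports)) {
    expect_equal(nrow(tr$reports[[mode]]$per_fold), 2L)
  }
  # identical source: both modes share blocks 1-4 before finetuning
  tma <- transfer_model(tr$source_fit, "all_conv", seed = 4)
  tmb <- transfer_model(tr$source_fit, "first_four", seed = 4)
  for (b in 1:4) {
    expect_identical(tma$params$conv[[b]], tmb$params$conv[[b]])
  }
})
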