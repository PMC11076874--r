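test_that("the network outputs a probability distribution of the right shape", {
  m <- spindle_cnn(matrix(rnorm(8 * 300), 8), y = rep(0:1, 4), epochs = 0,
                   seed = 1)
  p <- predict(m, matrix(rnorm(8 * 300), 8))
  expect_equal(dim(p), c(8L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
})

test_that("initialization is deterministic under the seed", {
  x <- matrix(rnorm(4 * 300), 4)
  a <- spindle_cnn(x, y = c(0, 1, 0, 1), epochs = 0, seed = 42)
  b <- spindle_cnn(x, y = c(0, 1, 0, 1), epochs = 0, seed = 42)
  expect_identical(a$params, b$params)
  c <- spindle_cnn(x, y = c(0, 1, 0, 1), epochs = 0, seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("inference is a pure per-window function (batch independence)", {
  m <- spindle_cnn(matrix(rnorm(16 * 300), 16), y = rep(0:1, 8), epochs = 1,
                   lr0 = 0.001, seed = 5)
  x <- matrix(rnorm(4 * 300), 4)
  p1 <- predict(m, x)
  p2 <- predict(m, rbind(x, x))
  expect_lt(max(abs(p2[1:4, ] - p1)), 1e-6)
  expect_lt(max(abs(p2[5:8, ] - p1)), 1e-6)
})

test_that("degenerate constant input stays finite", {
  m <- spindle_cnn(matrix(rnorm(4 * 300), 4), y = c(0, 1, 0, 1), epochs = 0,
                   seed = 2)
  p <- predict(m, matrix(0, 2, 300))
  expect_true(all(is.finite(p)))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
})

test_that("wrong input length is rejected with the expected size", {
  m <- spindle_cnn(matrix(rnorm(4 * 300), 4), y = c(0, 1, 0, 1), epochs = 0,
                   seed = 2)
  expect_error(predict(m, matrix(0, 2, 299)), "300")
})

test_that("spec violations of the 5-block / 2-pool structure are errors", {
  expect_error(cnn_spec(channels = c(16, 32, 64)), "5 conv blocks")
  expect_error(cnn_spec(pool_after = c(1, 3)), "blocks 2 and 4")
  expect_error(cnn_spec(kernels = c(7, 7, 5, 5, 4)), "odd")
  expect_error(cnn_spec(input_len = 302), "divisible by 4")
})

test_that("models save and load bitwise, with spec compatibility checks", {
  m <- spindle_cnn(matrix(rnorm(8 * 300), 8), y = rep(0:1, 4), epochs = 1,
                   lr0 = 0.001, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_spindle_cnn(m, path)
  back <- read_spindle_cnn(path)
  expect_identical(back$params, m$params)
  expect_identical(back$spec, m$spec)
  # incompatible architecture on load
  other <- cnn_spec(kernels = c(9, 7, 5, 5, 3))
  expect_error(read_spindle_cnn(path, spec = other), "differs")
  # corrupted file
  writeLines("not a model", path)
  expect_error(read_spindle_cnn(path), "parse|does not contain")
})

test_that("analytic gradients match finite differences", {
  spec <- tiny_spec()
  ns <- asNamespace("spindlecnn")
  set.seed(31)
  params <- ns$nn_init_params(spec, 11)
  x <- matrix(rnorm(6 * spec$input_len), 6)
  y <- c(0, 1, 1, 0, 1, 0)
  tr <- list(blocks = rep(TRUE, 5), head = TRUE)
  lossf <- function(p) ns$nn_step(p, spec, x, y, training = TRUE,
                                  trainable = tr)$loss
  st <- ns$nn_step(params, spec, x, y, training = TRUE, trainable = tr)
  eps <- 1e-6
  rel_err <- function(num, ana) abs(num - ana) / pmax(1e-8, abs(num) + abs(ana))
  check_tensor <- function(get, set, analytic, n_probe = 5) {
    v <- get(params)
    for (i in sample(length(v), min(n_probe, length(v)))) {
      up <- params; vv <- get(up); vv[i] <- vv[i] + eps; up <- set(up, vv)
      dn <- params; vv <- get(dn); vv[i] <- vv[i] - eps; dn <- set(dn, vv)
      num <- (lossf(up) - lossf(dn)) / (2 * eps)
      expect_lt(rel_err(num, analytic[i]), 1e-5)
    }
  }
  for (b in c(1, 3, 5)) {
    check_tensor(function(p) p$conv[[b]]$W,
                 function(p, v) { p$conv[[b]]$W[] <- v; p }, st$gconv[[b]])
    check_tensor(function(p) p$bn[[b]]$gamma,
                 function(p, v) { p$bn[[b]]$gamma <- v; p },
                 st$gbn_gamma[[b]], 3)
  }
  check_tensor(function(p) p$fc1$W, function(p, v) { p$fc1$W[] <- v; p },
               st$gfc1_w)
  check_tensor(function(p) p$fc2$b, function(p, v) { p$fc2$b <- v; p },
               st$gfc2_b, 2)
})

test_that("temporal downsampling through the network is exactly 4", {
  # 300-sample input reaches the head at 75 positions: the flat dimension
  # of fc1 must be channels[5] * input_len / 4
  spec <- cnn_spec()
  m <- spindle_cnn(matrix(rnorm(2 * 300), 2), y = 0:1, epochs = 0, seed = 1)
  expect_equal(ncol(m$params$fc1$W), spec$channels[5] * spec$input_len / 4)
})
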