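# Differentiation engine: finite-difference checks of every operator used
# by the networks (double-precision kernel path), plus tape mechanics.

ts <- asNamespace("tsgan")

fd_max_err <- function(make_loss, params, eps = 1e-5, n_probe = 4,
                       floor = 1e-6) {
  ts$ag_tape_start()
  root <- make_loss()
  for (p in params) p$grad <- NULL
  ts$ag_backward(root)
  gs <- lapply(params, function(p) p$grad)
  ts$ag_tape_stop()
  errs <- 0
  for (j in seq_along(params)) {
    p <- params[[j]]
    for (i in sample(length(p$value), min(n_probe, length(p$value)))) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps
      ts$ag_tape_start(); f1 <- as.numeric(make_loss()$value); ts$ag_tape_stop()
      p$value[i] <- v0 - eps
      ts$ag_tape_start(); f2 <- as.numeric(make_loss()$value); ts$ag_tape_stop()
      p$value[i] <- v0
      num <- (f1 - f2) / (2 * eps)
      ana <- if (is.null(gs[[j]])) 0 else gs[[j]][i]
      errs <- max(errs, abs(num - ana) / max(floor, abs(num) + abs(ana)))
    }
  }
  errs
}

test_that("convolution and transposed convolution gradients match finite differences", {
  set.seed(1)
  x <- ts$ag_param(array(stats::rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2)))
  w <- ts$ag_param(array(stats::rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3)))
  b <- ts$ag_param(stats::rnorm(3))
  err <- fd_max_err(function()
    ts$ag_mean(ts$ag_tanh(ts$ag_conv2d(x, w, b, 1L, 1L, single = FALSE))),
    list(x, w, b))
  expect_lt(err, 1e-6)
  err2 <- fd_max_err(function()
    ts$ag_mean(ts$ag_abs(ts$ag_conv2d(x, w, b, 2L, 0L, single = FALSE))),
    list(x, w, b))
  expect_lt(err2, 1e-6)
  wt <- ts$ag_param(array(stats::rnorm(2 * 2 * 3 * 2), c(2, 2, 3, 2)))
  bt <- ts$ag_param(stats::rnorm(3))
  err3 <- fd_max_err(function()
    ts$ag_mean(ts$ag_tanh(ts$ag_convt2d(x, wt, bt, 2L, single = FALSE))),
    list(x, wt, bt))
  expect_lt(err3, 1e-6)
})

test_that("fused conv+activation agrees with separate ops and differentiates", {
  set.seed(2)
  x <- ts$ag_param(array(stats::rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2)))
  w <- ts$ag_param(array(stats::rnorm(2 * 2 * 2 * 3), c(2, 2, 2, 3)))
  b <- ts$ag_param(stats::rnorm(3))
  ts$ag_tape_start()
  fused <- ts$ag_conv2d(x, w, b, 2L, 0L, single = FALSE, act = 0.2)
  split <- ts$ag_leaky_relu(ts$ag_conv2d(x, w, b, 2L, 0L, single = FALSE), 0.2)
  expect_equal(fused$value, split$value, tolerance = 1e-12)
  ts$ag_tape_stop()
  err <- fd_max_err(function()
    ts$ag_mean(ts$ag_conv2d(x, w, b, 2L, 0L, single = FALSE, act = 0.2)),
    list(x, w, b))
  expect_lt(err, 1e-6)
})

test_that("batch normalization gradients match finite differences in both modes", {
  set.seed(3)
  x <- ts$ag_param(array(stats::rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3)))
  gamma <- ts$ag_param(c(1.2, 0.7))
  beta <- ts$ag_param(c(0.1, -0.2))
  mk <- function(training) function() {
    ly <- ts$nn_bn(2)   # fresh running stats each evaluation
    ts$ag_mean(ts$ag_abs(ts$ag_bn(x, gamma, beta, ly, training)))
  }
  expect_lt(fd_max_err(mk(TRUE), list(x, gamma, beta)), 1e-6)
  expect_lt(fd_max_err(mk(FALSE), list(x, gamma, beta)), 1e-6)
  # fused activation path
  mk2 <- function() {
    ly <- ts$nn_bn(2)
    ts$ag_mean(ts$ag_bn(x, gamma, beta, ly, TRUE, act_slope = 0.2))
  }
  expect_lt(fd_max_err(mk2, list(x, gamma, beta)), 1e-6)
})

test_that("attention block, softmax and batched matmul differentiate correctly", {
  set.seed(4)
  at <- ts$nn_attention(4)
  at$gamma$value <- 0.5
  xa <- ts$ag_param(array(stats::rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)))
  # larger step and denominator floor absorb float32 forward noise while
  # still catching any structural gradient error
  err <- fd_max_err(function()
    ts$ag_mean(ts$ag_tanh(ts$attn_forward(at, xa, FALSE))),
    c(list(xa), ts$layer_params(at)), eps = 3e-3, n_probe = 3, floor = 0.02)
  expect_lt(err, 0.05)
})

test_that("crop, concat, reflect-pad and per-sample scaling round-trip gradients", {
  set.seed(5)
  x <- ts$ag_param(array(stats::rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  windows <- rbind(c(2, 3), c(1, 1))
  err <- fd_max_err(function() {
    cr <- ts$ag_crop_batch(x, windows, 4L)
    cc <- ts$ag_concat_ch(cr, ts$ag_abs(cr))
    ts$ag_mean(ts$ag_tanh(cc))
  }, list(x))
  expect_lt(err, 1e-6)
  err2 <- fd_max_err(function() {
    pd <- ts$ag_pad_reflect1(x)
    ts$ag_mean(ts$ag_abs(pd))
  }, list(x))
  expect_lt(err2, 1e-6)
})

test_that("segmentation loss differentiates through sigmoid probabilities", {
  set.seed(6)
  pr <- ts$ag_param(array(stats::rnorm(36), c(6, 6, 1, 1)))
  lb <- (array(stats::runif(36), c(6, 6, 1, 1)) > 0.5) * 1
  err <- fd_max_err(function() seg_loss(ts$ag_sigmoid(pr), ts$ag_const(lb)),
                    list(pr))
  expect_lt(err, 1e-6)
})

test_that("frozen parameters receive no gradient", {
  set.seed(7)
  a <- ts$ag_param(matrix(1.5, 2, 2))
  b <- ts$ag_param(matrix(2.0, 2, 2))
  b$frozen <- TRUE
  ts$ag_tape_start()
  loss <- ts$ag_mean(ts$ag_mul(a, b))
  ts$ag_zero_grads(list(a, b))
  ts$ag_backward(loss)
  ts$ag_tape_stop()
  expect_false(is.null(a$grad))
  expect_null(b$grad)
})
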