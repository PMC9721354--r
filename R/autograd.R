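# Reverse-mode automatic differentiation on dense arrays.
#
# A node is an environment holding `value` (an array, tensor layout
# [H, W, C, N]), an accumulated `grad`, its `parents` and a `backward`
# closure mapping the node's gradient to a list of parent gradients.
# Computed nodes are appended to a tape in creation order; ag_backward()
# sweeps the tape in reverse. Parameter nodes live off-tape so their
# gradients persist until the optimizer consumes them.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L
.ag$recording <- FALSE

ag_tape_start <- function() {
  .ag$tape <- vector("list", 1024L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- FALSE
  if (.ag$recording && !is.null(backward)) {
    if (.ag$n >= length(.ag$tape))
      .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$n <- .ag$n + 1L
    .ag$tape[[.ag$n]] <- nd
  }
  nd
}

ag_const <- function(value) ag_node(value)

ag_param <- function(value) {
  nd <- ag_node(value)
  nd$param <- TRUE
  nd
}

is_ag_node <- function(x) is.environment(x)

ag_value <- function(x) if (is.environment(x)) x$value else x

# Detach: a constant leaf carrying the same value, cutting the graph.
ag_detach <- function(x) ag_const(x$value)

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

ag_backward <- function(root, grad = NULL) {
  if (!.ag$recording) stop("ag_backward() called with no active tape")
  n <- .ag$n
  tape <- .ag$tape
  for (i in seq_len(n)) tape[[i]]$grad <- NULL
  root$grad <- if (is.null(grad)) array(1, dim = dim_or1(root$value)) else grad
  for (i in rev(seq_len(n))) {
    nd <- tape[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$backward(nd$grad, nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (isTRUE(p$frozen)) next   # parameters treated as constants
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

dim_or1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

as_nd <- function(x) if (is_ag_node(x)) x else ag_const(x)

## ---- elementwise arithmetic ----

ag_add <- function(a, b) {
  a <- as_nd(a); b <- as_nd(b)
  ag_node(a$value + b$value, list(a, b),
          function(g, nd) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_nd(a); b <- as_nd(b)
  ag_node(a$value - b$value, list(a, b),
          function(g, nd) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_nd(a); b <- as_nd(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b),
          function(g, nd) list(g * bv, g * av))
}

ag_neg <- function(a) {
  ag_node(-a$value, list(a), function(g, nd) list(-g))
}

# multiply by a non-differentiated constant (scalar or conforming array)
ag_scale <- function(a, k) {
  ag_node(a$value * k, list(a), function(g, nd) list(g * k))
}

ag_add_const <- function(a, k) {
  ag_node(a$value + k, list(a), function(g, nd) list(g))
}

# a / s where s is a scalar-valued node (both differentiated)
ag_div_scalar <- function(a, s) {
  av <- a$value; sv <- as.numeric(s$value)
  ag_node(av / sv, list(a, s),
          function(g, nd) list(g / sv, -sum(g * av) / sv^2))
}

# divide sample n by constant scalar k[n] (no gradient through k)
ag_div_per_sample <- function(a, k) {
  d <- dim(a$value)
  scale <- rep(1 / k, each = prod(d[1:3]))
  ag_node(a$value * scale, list(a), function(g, nd) list(g * scale))
}

## ---- activations ----

ag_relu <- function(a) ag_leaky_relu(a, 0)

ag_leaky_relu <- function(a, slope = 0.2) {
  y <- cpp_leaky_fw(a$value, slope)
  ag_node(y, list(a), function(g, nd) list(cpp_leaky_bw(y, g, slope)))
}

ag_tanh <- function(a) {
  y <- tanh(a$value)
  ag_node(y, list(a), function(g, nd) list(g * (1 - y^2)))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ag_node(y, list(a), function(g, nd) list(g * y * (1 - y)))
}

ag_abs <- function(a) {
  s <- sign(a$value)
  ag_node(abs(a$value), list(a), function(g, nd) list(g * s))
}

## ---- reductions ----

ag_sum <- function(a) {
  d <- dim_or1(a$value)
  ag_node(sum(a$value), list(a),
          function(g, nd) list(array(as.numeric(g), dim = d)))
}

ag_mean <- function(a) {
  d <- dim_or1(a$value)
  n <- prod(d)
  ag_node(mean(a$value), list(a),
          function(g, nd) list(array(as.numeric(g) / n, dim = d)))
}

ag_mean_abs_diff <- function(a, b) ag_mean(ag_abs(ag_sub(a, b)))

## ---- convolutions ----

# `single = TRUE` runs the gemm in float32 (training path); the double
# path serves metric filters and small-scale oracle checks. `act` fuses a
# leaky rectifier (slope `act`; 0 = plain rectifier) onto the output.
ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L, single = TRUE,
                      act = NA) {
  y <- cpp_conv2d_fw(x$value, w$value, b$value, stride, pad, single, act)
  xv <- x$value; wv <- w$value
  ag_node(y, list(x, w, b), function(g, nd) {
    bw <- cpp_conv2d_bw(xv, wv, g, stride, pad, single, act,
                        if (is.na(act)) NULL else y)
    list(bw$gx, bw$gw, bw$gb)
  })
}

ag_convt2d <- function(x, w, b, stride = 2L, single = TRUE) {
  y <- cpp_convt2d_fw(x$value, w$value, b$value, stride, single)
  xv <- x$value; wv <- w$value
  ag_node(y, list(x, w, b), function(g, nd) {
    bw <- cpp_convt2d_bw(xv, wv, g, stride, single)
    list(bw$gx, bw$gw, bw$gb)
  })
}

## ---- batch normalization ----

# Batch normalization over (H, W, N) per channel. `ly` carries running
# statistics (rm, rv) updated in training mode and used in eval mode.
# Channel-wise affine maps go through C++ helpers to limit allocation churn.
# `act_slope`: if not NA, a leaky rectifier (slope 0 = plain rectifier) is
# fused onto the normalized output in the same node.
ag_bn <- function(x, gamma, beta, ly, training, act_slope = NA) {
  xv <- x$value
  d <- dim(xv)
  m <- prod(d[c(1, 2, 4)])
  if (training) {
    mu <- cpp_chan_dot(xv, NULL) / m
    va <- pmax(cpp_chan_dot(xv, xv) / m - mu^2, 0)
    ly$rm <- (1 - ly$momentum) * ly$rm + ly$momentum * mu
    ly$rv <- (1 - ly$momentum) * ly$rv + ly$momentum * va * m / max(1, m - 1)
  } else {
    mu <- ly$rm
    va <- ly$rv
  }
  invstd <- 1 / sqrt(va + ly$eps)
  gv <- gamma$value
  a <- gv * invstd
  y <- cpp_chan_affine(xv, a, beta$value - mu * a)
  if (!is.na(act_slope)) y <- cpp_leaky_fw(y, act_slope)
  ag_node(y, list(x, gamma, beta), function(g, nd) {
    if (!is.na(act_slope)) g <- cpp_leaky_bw(y, g, act_slope)
    xhat <- cpp_chan_affine(xv, invstd, -mu * invstd)
    dgamma <- cpp_chan_dot(g, xhat)
    dbeta <- cpp_chan_dot(g, NULL)
    if (training) {
      dx <- cpp_chan_affine(g, a, -a * dbeta / m) -
        cpp_chan_affine(xhat, a * dgamma / m, numeric(d[3]))
    } else {
      dx <- cpp_chan_affine(g, a, numeric(d[3]))
    }
    list(dx, dgamma, dbeta)
  })
}

## ---- shape ops ----

ag_reshape <- function(a, dims) {
  d0 <- dim_or1(a$value)
  v <- a$value
  dim(v) <- dims
  ag_node(v, list(a), function(g, nd) {
    dim(g) <- d0
    list(g)
  })
}

ag_concat_ch <- function(a, b) {
  ca <- dim(a$value)[3]
  cb <- dim(b$value)[3]
  y <- cpp_concat_ch(a$value, b$value)
  ag_node(y, list(a, b), function(g, nd) {
    s <- cpp_split_ch(g, ca, cb)
    list(s$ga, s$gb)
  })
}

ag_sum_channels <- function(a) {
  d <- dim(a$value)
  y <- array(0, dim = c(d[1], d[2], 1L, d[4]))
  for (c in seq_len(d[3])) y <- y + a$value[, , c, , drop = FALSE]
  ag_node(y, list(a), function(g, nd) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[3])) gx[, , c, ] <- g
    list(gx)
  })
}

# Per-sample crop: windows[n, ] = (row_start, col_start), 1-based; size s.
ag_crop_batch <- function(a, windows, size) {
  d <- dim(a$value)
  N <- d[4]
  y <- array(0, dim = c(size, size, d[3], N))
  for (n in seq_len(N)) {
    r <- windows[n, 1]; c0 <- windows[n, 2]
    y[, , , n] <- a$value[r:(r + size - 1), c0:(c0 + size - 1), , n]
  }
  ag_node(y, list(a), function(g, nd) {
    gx <- array(0, dim = d)
    for (n in seq_len(N)) {
      r <- windows[n, 1]; c0 <- windows[n, 2]
      gx[r:(r + size - 1), c0:(c0 + size - 1), , n] <-
        gx[r:(r + size - 1), c0:(c0 + size - 1), , n] + g[, , , n]
    }
    list(gx)
  })
}

ag_pad_reflect1 <- function(a) {
  d <- dim(a$value)
  H <- d[1]; W <- d[2]
  ri <- c(2L, seq_len(H), H - 1L)
  ci <- c(2L, seq_len(W), W - 1L)
  y <- a$value[ri, ci, , , drop = FALSE]
  ag_node(y, list(a), function(g, nd) {
    gx <- g[2:(H + 1), 2:(W + 1), , , drop = FALSE]
    gx[2, , , ] <- gx[2, , , ] + g[1, 2:(W + 1), , ]
    gx[H - 1, , , ] <- gx[H - 1, , , ] + g[H + 2, 2:(W + 1), , ]
    gx[, 2, , ] <- gx[, 2, , ] + g[2:(H + 1), 1, , ]
    gx[, W - 1, , ] <- gx[, W - 1, , ] + g[2:(H + 1), W + 2, , ]
    gx[2, 2, , ] <- gx[2, 2, , ] + g[1, 1, , ]
    gx[2, W - 1, , ] <- gx[2, W - 1, , ] + g[1, W + 2, , ]
    gx[H - 1, 2, , ] <- gx[H - 1, 2, , ] + g[H + 2, 1, , ]
    gx[H - 1, W - 1, , ] <- gx[H - 1, W - 1, , ] + g[H + 2, W + 2, , ]
    list(gx)
  })
}

# Hard threshold with a straight-through (identity) gradient, so edge maps
# remain trainable through the binarization used for discriminator inputs.
ag_binarize_st <- function(a, threshold) {
  y <- (a$value >= threshold) * 1
  dim(y) <- dim_or1(a$value)
  ag_node(y, list(a), function(g, nd) list(g))
}

## ---- batched matrix ops (self-attention) ----

# A: [M, K, N], B: [K, P, N] -> [M, P, N]
ag_bmm <- function(a, b) {
  av <- a$value; bv <- b$value
  y <- cpp_bmm(av, bv)
  ag_node(y, list(a, b), function(g, nd) {
    list(cpp_bmm(g, bv, FALSE, TRUE), cpp_bmm(av, g, TRUE, FALSE))
  })
}

ag_btranspose <- function(a) {
  av <- a$value
  d <- dim(av)
  y <- array(0, dim = c(d[2], d[1], d[3]))
  for (n in seq_len(d[3])) y[, , n] <- t(matrix(av[, , n], d[1], d[2]))
  ag_node(y, list(a), function(g, nd) {
    gx <- array(0, dim = d)
    for (n in seq_len(d[3])) gx[, , n] <- t(matrix(g[, , n], d[2], d[1]))
    list(gx)
  })
}

# row-wise softmax over the second dimension of [M, P, N]
ag_softmax_rows <- function(a) {
  d <- dim(a$value)
  y <- cpp_softmax_rows(a$value)
  ag_node(y, list(a), function(g, nd) {
    gy <- g * y
    rs <- .colSums(aperm(gy, c(2, 1, 3)), d[2], d[1] * d[3])  # sum over P
    rs_full <- aperm(array(rs, c(d[1], d[3], d[2])), c(1, 3, 2))
    list(y * (g - rs_full))
  })
}

## ---- losses as primitive ops ----

# Binary cross-entropy with clipped probabilities; label is constant.
ag_bce <- function(pred, label, clip = 1e-7) {
  p <- pmin(pmax(pred$value, clip), 1 - clip)
  lv <- ag_value(label)
  n <- length(p)
  val <- -mean(lv * log(p) + (1 - lv) * log(1 - p))
  inside <- (pred$value > clip) & (pred$value < 1 - clip)
  ag_node(val, list(pred), function(g, nd) {
    gp <- as.numeric(g) * (p - lv) / (p * (1 - p)) / n * inside
    dim(gp) <- dim_or1(pred$value)
    list(gp)
  })
}
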