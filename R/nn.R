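# Neural-network building blocks on top of the autodiff engine: layer
# constructors (each an environment holding parameter nodes plus buffers),
# spectral normalization by power iteration, the self-attention block, and
# the Adam optimizer.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' @noRd
nn_conv <- function(ci, co, k = 3L, stride = 1L, pad = NULL, sn = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "conv"
  ly$w <- ag_param(he_init(c(k, k, ci, co), fan_in = k * k * ci))
  ly$b <- ag_param(numeric(co))
  ly$stride <- as.integer(stride)
  ly$pad <- if (is.null(pad)) as.integer((k - 1) / 2) else as.integer(pad)
  ly$sn <- sn
  ly$u <- stats::rnorm(k * k * ci)
  ly$u <- ly$u / sqrt(sum(ly$u^2))
  ly
}

nn_convt <- function(ci, co, k = 2L, stride = 2L, sn = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "convt"
  ly$w <- ag_param(he_init(c(k, k, co, ci), fan_in = k * k * ci))
  ly$b <- ag_param(numeric(co))
  ly$stride <- as.integer(stride)
  ly$sn <- sn
  ly$u <- stats::rnorm(k * k * co)
  ly$u <- ly$u / sqrt(sum(ly$u^2))
  ly
}

nn_bn <- function(c) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "bn"
  ly$gamma <- ag_param(rep(1, c))
  ly$beta <- ag_param(numeric(c))
  ly$rm <- numeric(c)
  ly$rv <- rep(1, c)
  ly$eps <- 1e-5
  ly$momentum <- 0.1
  ly
}

# One step of power iteration on the reshaped weight matrix (K x Co);
# returns the current spectral-norm estimate. `update` controls whether the
# persistent left vector u is advanced (training) or left untouched (eval).
sn_sigma <- function(ly, update) {
  wv <- ly$w$value
  d <- dim(wv)
  K <- d[1] * d[2] * d[3]
  Co <- d[4]
  Wm <- matrix(wv, K, Co)
  u <- ly$u
  v <- drop(crossprod(Wm, u))
  v <- v / sqrt(sum(v^2) + 1e-12)
  u2 <- drop(Wm %*% v)
  u2 <- u2 / sqrt(sum(u2^2) + 1e-12)
  if (update) ly$u <- u2
  list(sigma = sum(u2 * (Wm %*% v)), u = u2, v = v)
}

sn_power_iterate <- function(ly, iters = 20L) {
  for (i in seq_len(iters)) sn_sigma(ly, update = TRUE)
  invisible(ly)
}

# Spectrally normalized weight node: w / sigma with sigma = u' W v kept
# differentiable through W (u, v treated as constants, as in the standard
# power-iteration formulation).
sn_weight_node <- function(ly, training) {
  s <- sn_sigma(ly, update = training)
  d <- dim(ly$w$value)
  uv <- array(outer(s$u, s$v), dim = d)
  sigma_node <- ag_sum(ag_mul(ly$w, ag_const(uv)))
  ag_div_scalar(ly$w, sigma_node)
}

layer_forward <- function(ly, x, training, act = NA) {
  if (ly$kind == "conv") {
    w <- if (ly$sn) sn_weight_node(ly, training) else ly$w
    ag_conv2d(x, w, ly$b, ly$stride, ly$pad, act = act)
  } else if (ly$kind == "convt") {
    w <- if (ly$sn) sn_weight_node(ly, training) else ly$w
    ag_convt2d(x, w, ly$b, ly$stride)
  } else {
    stop("unknown layer kind: ", ly$kind)
  }
}

bn_forward <- function(ly, x, training, act = NA)
  ag_bn(x, ly$gamma, ly$beta, ly, training, act)

# Refinement module: a bottleneck path (1x1 reduce -> leaky ReLU -> 3x3 ->
# BN -> leaky ReLU -> 1x1 expand -> BN), residually added to its input when
# `residual` is on. When input channels exceed the output count (decoder
# blocks fed by a skip concatenation) the identity skip takes the first
# `co` channels — the freshly upsampled features — so the module learns the
# self-residual on top of them; a 1x1 projection is only needed when the
# input is narrower than the output (the stem).
nn_resblock <- function(ci, co, residual = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "res"
  mid <- max(2L, co %/% 2L)
  ly$reduce <- nn_conv(ci, mid, k = 1L, pad = 0L)
  ly$conv <- nn_conv(mid, mid, k = 3L)
  ly$bn <- nn_bn(mid)
  ly$expand <- nn_conv(mid, co, k = 1L, pad = 0L)
  ly$bn2 <- nn_bn(co)
  ly$residual <- residual
  ly$ci <- ci; ly$co <- co
  ly$proj <- if (residual && ci < co) nn_conv(ci, co, k = 1L, pad = 0L) else NULL
  ly
}

# Non-residual counterpart (ablation): same bottleneck path, no skip.
nn_plainblock <- function(ci, co) nn_resblock(ci, co, residual = FALSE)

res_forward <- function(ly, x, training, slope = 0.2) {
  h <- layer_forward(ly$reduce, x, training, act = slope)
  h <- bn_forward(ly$bn, layer_forward(ly$conv, h, training), training,
                  act = slope)
  h <- bn_forward(ly$bn2, layer_forward(ly$expand, h, training), training)
  if (ly$residual) {
    skip <- if (!is.null(ly$proj)) {
      layer_forward(ly$proj, x, training)
    } else if (ly$ci == ly$co) {
      x
    } else {
      ag_node(x$value[, , seq_len(ly$co), , drop = FALSE], list(x),
              function(g, nd) {
                gx <- array(0, dim = dim(x$value))
                gx[, , seq_len(ly$co), ] <- g
                list(gx)
              })
    }
    h <- ag_add(h, skip)
  }
  ag_leaky_relu(h, slope)
}

block_forward <- function(ly, x, training) res_forward(ly, x, training)

# Self-attention (query/key/value with a learned zero-initialized gate).
nn_attention <- function(c) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "attn"
  ck <- max(1L, c %/% 8L)
  ly$f <- nn_conv(c, ck, k = 1L, pad = 0L)
  ly$g <- nn_conv(c, ck, k = 1L, pad = 0L)
  ly$h <- nn_conv(c, c, k = 1L, pad = 0L)
  ly$v <- nn_conv(c, c, k = 1L, pad = 0L)
  ly$gamma <- ag_param(0)
  ly$ck <- ck
  ly$c <- c
  ly
}

# multiply an array node by a scalar-valued parameter node
ag_scale_node <- function(a, s) {
  av <- a$value; sv <- as.numeric(s$value)
  ag_node(av * sv, list(a, s),
          function(g, nd) list(g * sv, sum(g * av)))
}

attn_forward <- function(ly, x, training) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  f <- ag_reshape(layer_forward(ly$f, x, training), c(hw, ly$ck, d[4]))
  g <- ag_reshape(layer_forward(ly$g, x, training), c(hw, ly$ck, d[4]))
  h <- ag_reshape(layer_forward(ly$h, x, training), c(hw, ly$c, d[4]))
  att <- ag_softmax_rows(ag_bmm(f, ag_btranspose(g)))
  o <- ag_reshape(ag_bmm(att, h), d)
  o <- layer_forward(ly$v, o, training)
  ag_add(x, ag_scale_node(o, ly$gamma))
}

## ---- parameter bookkeeping ----

layer_params <- function(ly) {
  if (is.null(ly)) return(list())
  switch(ly$kind,
    conv = list(ly$w, ly$b),
    convt = list(ly$w, ly$b),
    bn = list(ly$gamma, ly$beta),
    res = c(layer_params(ly$reduce), layer_params(ly$conv),
            layer_params(ly$bn), layer_params(ly$expand),
            layer_params(ly$bn2), layer_params(ly$proj)),
    attn = c(layer_params(ly$f), layer_params(ly$g), layer_params(ly$h),
             layer_params(ly$v), list(ly$gamma)),
    stop("unknown layer kind")
  )
}

n_params <- function(params) sum(vapply(params, function(p) length(p$value), 0))

## ---- Adam ----

adam_new <- function(params, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) array(0, dim = dim_or1(p$value)))
  st$v <- lapply(params, function(p) array(0, dim = dim_or1(p$value)))
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    p$value <- p$value - st$lr * (st$m[[i]] / bc1) /
      (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(st)
}
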