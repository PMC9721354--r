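#' Network configurations
#'
#' Configuration constructors for the four sub-networks of the
#' tumor-attentive segmentation-guided GAN: the residual U-Net generator
#' `G`, the global discriminator `GD`, the local (tumor-patch)
#' discriminator `LD`, and the auxiliary segmentor `S`.
#'
#' @param image_size side length in pixels of the (square) input slices.
#' @param base_width number of channels at the first encoder level.
#' @param depth number of down/up sampling repetitions.
#' @param use_spectral_norm apply spectral normalization to every sampling
#'   convolution (generator) or every convolution (discriminators).
#' @param use_residual use residual refinement modules; when `FALSE` plain
#'   convolution blocks of the same channel map are used.
#' @param use_attention insert the self-attention module at the decoder
#'   position whose feature maps have side `image_size / 4`.
#' @param in_channels,out_channels input/output channel counts.
#'
#' @return a named list of class `tsgan_netcfg`.
#' @export
generator_config <- function(image_size = 256L, base_width = 64L, depth = 4L,
                             in_channels = 1L, out_channels = 1L,
                             use_spectral_norm = TRUE, use_residual = TRUE,
                             use_attention = TRUE) {
  stopifnot(depth >= 1, image_size %% (2^depth) == 0)
  structure(list(kind = "generator", image_size = as.integer(image_size),
                 base_width = as.integer(base_width), depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 use_spectral_norm = use_spectral_norm,
                 use_residual = use_residual,
                 use_attention = use_attention),
            class = "tsgan_netcfg")
}

#' @param n_layers number of stride-2 body convolutions before the scoring
#'   convolution (4 for the global, 3 for the local discriminator).
#' @param input_size side length of the discriminator input (256 global,
#'   64 local at full scale).
#' @rdname generator_config
#' @export
discriminator_config <- function(input_size = 256L, n_layers = 4L,
                                 base_width = 64L, in_channels = 4L,
                                 use_spectral_norm = TRUE) {
  structure(list(kind = "discriminator", input_size = as.integer(input_size),
                 n_layers = as.integer(n_layers),
                 base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 use_spectral_norm = use_spectral_norm),
            class = "tsgan_netcfg")
}

#' @rdname generator_config
#' @export
segmentor_config <- function(image_size = 256L, base_width = 64L, depth = 5L,
                             in_channels = 1L, out_channels = 1L) {
  stopifnot(depth >= 1, image_size %% (2^depth) == 0)
  structure(list(kind = "segmentor", image_size = as.integer(image_size),
                 base_width = as.integer(base_width), depth = as.integer(depth),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "tsgan_netcfg")
}

# channel width at encoder level i (1-based), growth x2 capped at 8x base
level_width <- function(base, i) base * min(2^(i - 1L), 8L)

#' Build the generator network
#'
#' Residual U-Net with stride-2 2x2 sampling convolutions, batch
#' normalization, leaky-ReLU encoder / ReLU decoder activations,
#' skip concatenations, optional spectral normalization on every sampling
#' convolution, a self-attention module where decoder feature maps have
#' side `image_size / 4`, and a tanh output bounding values to \[-1, 1\].
#'
#' @param cfg a [generator_config()].
#' @return an opaque network object usable with [network_forward()].
#' @export
build_generator <- function(cfg) {
  stopifnot(inherits(cfg, "tsgan_netcfg"), cfg$kind == "generator")
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  b <- cfg$base_width
  d <- cfg$depth
  mkblock <- function(ci, co) {
    if (cfg$use_residual) nn_resblock(ci, co) else nn_plainblock(ci, co)
  }
  net$enc_blocks <- vector("list", d)
  net$downs <- vector("list", d)
  prev <- cfg$in_channels
  for (i in seq_len(d)) {
    ci <- level_width(b, i)
    net$enc_blocks[[i]] <- mkblock(prev, ci)
    net$downs[[i]] <- list(conv = nn_conv(ci, level_width(b, i + 1L), k = 2L,
                                          stride = 2L, pad = 0L,
                                          sn = cfg$use_spectral_norm),
                           bn = nn_bn(level_width(b, i + 1L)))
    prev <- level_width(b, i + 1L)
  }
  net$ups <- vector("list", d)
  net$dec_blocks <- vector("list", d)
  for (i in rev(seq_len(d))) {
    cin <- level_width(b, i + 1L)
    cout <- level_width(b, i)
    net$ups[[i]] <- list(convt = nn_convt(cin, cout, k = 2L, stride = 2L,
                                          sn = cfg$use_spectral_norm),
                         bn = nn_bn(cout))
    net$dec_blocks[[i]] <- mkblock(2L * cout, cout)
  }
  # decoder up at level i outputs side image_size / 2^(i-1); side equals
  # image_size / 4 at level 3, where the self-attention module sits
  if (cfg$use_attention && d >= 3L) {
    net$attn_level <- 3L
    net$attn <- nn_attention(level_width(b, 3L))
  } else {
    net$attn_level <- NA_integer_
    net$attn <- NULL
  }
  net$final <- nn_conv(b, cfg$out_channels, k = 3L)
  # damp the output convolution so the generator starts near mid-gray;
  # stabilizes early adversarial training across seeds
  net$final$w$value <- net$final$w$value * 0.1
  net$layers <- c(net$enc_blocks, lapply(net$downs, `[[`, "conv"),
                  lapply(net$downs, `[[`, "bn"),
                  lapply(net$ups, `[[`, "convt"), lapply(net$ups, `[[`, "bn"),
                  net$dec_blocks,
                  if (!is.null(net$attn)) list(net$attn),
                  list(net$final))
  net$params <- unlist(lapply(net$layers, layer_params), recursive = FALSE)
  class(net) <- "tsgan_network"
  net
}

generator_forward <- function(net, x, training = FALSE) {
  cfg <- net$cfg
  d <- cfg$depth
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    h <- block_forward(net$enc_blocks[[i]], h, training)
    skips[[i]] <- h
    dn <- net$downs[[i]]
    h <- bn_forward(dn$bn, layer_forward(dn$conv, h, training), training,
                    act = 0.2)
  }
  for (i in rev(seq_len(d))) {
    up <- net$ups[[i]]
    h <- bn_forward(up$bn, layer_forward(up$convt, h, training), training,
                    act = 0)
    h <- ag_concat_ch(h, skips[[i]])
    h <- block_forward(net$dec_blocks[[i]], h, training)
    if (!is.na(net$attn_level) && i == net$attn_level)
      h <- attn_forward(net$attn, h, training)
  }
  ag_tanh(layer_forward(net$final, h, training))
}

#' Build a discriminator
#'
#' PatchGAN-style conditional discriminator: `n_layers` stride-2 2x2
#' convolutions with leaky ReLU (and optional spectral normalization)
#' followed by one stride-2 scoring convolution producing an unbounded
#' score grid. The forward pass returns both the score grid and the
#' penultimate feature map used for feature matching. The four input
#' channels are ordered (conditioning image, conditioning edge map,
#' candidate image, candidate edge map).
#'
#' @param cfg a [discriminator_config()].
#' @return an opaque network object.
#' @export
build_discriminator <- function(cfg) {
  stopifnot(inherits(cfg, "tsgan_netcfg"), cfg$kind == "discriminator")
  if (cfg$input_size < 2^(cfg$n_layers + 1L))
    stop("discriminator input of ", cfg$input_size, " px cannot support ",
         cfg$n_layers, " stride-2 layers plus the scoring convolution")
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  b <- cfg$base_width
  prev <- cfg$in_channels
  net$convs <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    co <- level_width(b, i)
    net$convs[[i]] <- nn_conv(prev, co, k = 2L, stride = 2L, pad = 0L,
                              sn = cfg$use_spectral_norm)
    prev <- co
  }
  net$score <- nn_conv(prev, 1L, k = 2L, stride = 2L, pad = 0L,
                       sn = cfg$use_spectral_norm)
  net$layers <- c(net$convs, list(net$score))
  net$params <- unlist(lapply(net$layers, layer_params), recursive = FALSE)
  class(net) <- "tsgan_network"
  net
}

discriminator_forward <- function(net, x, training = FALSE) {
  if (dim(x$value)[3] != net$cfg$in_channels)
    stop("discriminator expects ", net$cfg$in_channels, " input channels, got ",
         dim(x$value)[3])
  h <- x
  for (conv in net$convs)
    h <- layer_forward(conv, h, training, act = 0.2)
  list(score = layer_forward(net$score, h, training), features = h)
}

#' Build the segmentor
#'
#' Standard U-Net with `depth` down/up sampling levels built from stride-2
#' 2x2 convolutions (transposed on the way up), batch normalization and
#' leaky ReLU, skip concatenations, and a sigmoid probability output.
#' No spectral normalization anywhere.
#'
#' @param cfg a [segmentor_config()].
#' @return an opaque network object.
#' @export
build_segmentor <- function(cfg) {
  stopifnot(inherits(cfg, "tsgan_netcfg"), cfg$kind == "segmentor")
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  b <- cfg$base_width
  d <- cfg$depth
  prev <- cfg$in_channels
  net$downs <- vector("list", d)
  for (i in seq_len(d)) {
    co <- level_width(b, i)
    net$downs[[i]] <- list(conv = nn_conv(prev, co, k = 2L, stride = 2L,
                                          pad = 0L),
                           bn = nn_bn(co))
    prev <- co
  }
  net$ups <- vector("list", d)
  for (j in seq_len(d)) {
    lev <- d - j + 1L                    # decodes level `lev` back up
    cout <- if (lev > 1L) level_width(b, lev - 1L) else b
    net$ups[[j]] <- list(convt = nn_convt(prev, cout, k = 2L, stride = 2L),
                         bn = nn_bn(cout))
    prev <- if (lev > 1L) 2L * cout else cout  # concat skip below bottleneck
  }
  net$final <- nn_conv(prev, cfg$out_channels, k = 1L, pad = 0L)
  net$layers <- c(lapply(net$downs, `[[`, "conv"), lapply(net$downs, `[[`, "bn"),
                  lapply(net$ups, `[[`, "convt"), lapply(net$ups, `[[`, "bn"),
                  list(net$final))
  net$params <- unlist(lapply(net$layers, layer_params), recursive = FALSE)
  class(net) <- "tsgan_network"
  net
}

segmentor_forward <- function(net, x, training = FALSE) {
  d <- net$cfg$depth
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    dn <- net$downs[[i]]
    h <- bn_forward(dn$bn, layer_forward(dn$conv, h, training), training,
                    act = 0.2)
    skips[[i]] <- h
  }
  for (j in seq_len(d)) {
    lev <- d - j + 1L
    up <- net$ups[[j]]
    h <- bn_forward(up$bn, layer_forward(up$convt, h, training), training,
                    act = 0.2)
    if (lev > 1L) h <- ag_concat_ch(h, skips[[lev - 1L]])
  }
  ag_sigmoid(layer_forward(net$final, h, training))
}

#' Run a network forward on a plain numeric array
#'
#' Convenience evaluation-mode forward pass outside any training loop.
#' `x` is an array `[H, W, C, N]` (or `[H, W]` for a single slice).
#'
#' @param net a network from one of the `build_*` functions.
#' @param x input array.
#' @return output array (for discriminators, a list with `score` and
#'   `features` arrays).
#' @export
network_forward <- function(net, x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  started <- !.ag$recording
  if (started) ag_tape_start()
  on.exit(if (started) ag_tape_stop())
  xn <- ag_const(x)
  out <- switch(net$cfg$kind,
    generator = generator_forward(net, xn, training = FALSE),
    discriminator = discriminator_forward(net, xn, training = FALSE),
    segmentor = segmentor_forward(net, xn, training = FALSE))
  if (is.list(out)) lapply(out, ag_value) else ag_value(out)
}

#' Number of trainable parameters of a network
#' @param net a network object.
#' @export
network_n_params <- function(net) n_params(net$params)

#' Receptive field of a stack of strided convolutions
#'
#' Standard recursion: starting from `rf = 1` and unit jump, each layer with
#' kernel `k` and stride `s` grows the field by `(k - 1) * jump` and
#' multiplies the jump by `s`.
#'
#' @param kernels,strides integer vectors, one entry per layer.
#' @return the receptive-field side length in input pixels.
#' @export
receptive_field <- function(kernels, strides) {
  rf <- 1
  jump <- 1
  for (i in seq_along(kernels)) {
    rf <- rf + (kernels[i] - 1) * jump
    jump <- jump * strides[i]
  }
  rf
}

# Freeze/unfreeze a network's parameters: frozen parameters are treated as
# constants by the backward sweep (no gradient accumulates), which is how the
# segmentor and the discriminators enter the generator's objective.
network_freeze <- function(net, frozen = TRUE) {
  for (p in net$params) p$frozen <- frozen
  invisible(net)
}

## ---- network state (checkpointing) ----

bn_layers_of <- function(net) {
  Filter(function(l) !is.null(l) && l$kind == "bn",
         unlist(lapply(net$layers, function(l) {
           switch(l$kind,
                  res = list(l$bn, l$bn2),
                  bn = list(l),
                  list())
         }), recursive = FALSE))
}

sn_layers_of <- function(net) {
  grab <- function(l) {
    if (is.null(l)) return(list())
    switch(l$kind,
           conv = if (l$sn) list(l) else list(),
           convt = if (l$sn) list(l) else list(),
           res = c(grab(l$reduce), grab(l$conv), grab(l$expand),
                   grab(l$proj)),
           attn = c(grab(l$f), grab(l$g), grab(l$h), grab(l$v)),
           list())
  }
  unlist(lapply(net$layers, grab), recursive = FALSE)
}

network_state <- function(net) {
  list(params = lapply(net$params, function(p) p$value),
       bn = lapply(bn_layers_of(net), function(l) list(rm = l$rm, rv = l$rv)),
       sn_u = lapply(sn_layers_of(net), function(l) l$u))
}

network_load_state <- function(net, state) {
  for (i in seq_along(net$params)) net$params[[i]]$value <- state$params[[i]]
  bns <- bn_layers_of(net)
  for (i in seq_along(bns)) {
    bns[[i]]$rm <- state$bn[[i]]$rm
    bns[[i]]$rv <- state$bn[[i]]$rv
  }
  sns <- sn_layers_of(net)
  for (i in seq_along(sns)) sns[[i]]$u <- state$sn_u[[i]]
  invisible(net)
}
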