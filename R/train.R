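# Adversarial training of the four networks. Update order per step:
# (a) both discriminators by the hinge loss on detached synthesized
# images, (b) the segmentor by BCE + Dice on target ceT1 only, (c) the
# generator by the adversarial terms plus the seven-term L1 objective with
# the epoch-curriculum weight. Each party's Adam optimizer touches only
# its own parameters; the other networks are frozen (treated as
# constants) while the generator's objective is differentiated.

#' Fit a tumor-attentive segmentation-guided GAN
#'
#' Trains the generator, the global and local discriminators, and the
#' auxiliary segmentor on normalized slice pairs. `pairs` come from
#' [make_slice_pairs()]; all slices must share one square size.
#'
#' @param pairs list of [slice_pair()]s (training set, normalized to
#'   \[-1, 1\], each with a nonempty tumor mask).
#' @param epochs number of training epochs (curriculum epochs count
#'   from 1).
#' @param batch_size mini-batch size.
#' @param base_width generator/discriminator channel width at the first
#'   level; the `tiny_profile` flag sets 8.
#' @param weights a [loss_weights()].
#' @param learning_rate,betas Adam settings shared by all parties.
#' @param use_spectral_norm,use_local_discriminator,use_edge_maps,
#'   use_segmentor ablation flags; disabling a component removes its loss
#'   terms (logged as `NA`) without changing any tensor shape.
#' @param use_residual,use_attention generator structure flags.
#' @param patch_size side of the tumor-centered patch fed to the local
#'   discriminator; defaults to a quarter of the image side (64 at 256).
#' @param seed integer; fixes initialization, shuffling and augmentation.
#' @param validation_pairs optional held-out pairs; whole-FOV and
#'   tumor-patch L1 to the target are recorded per epoch.
#' @param normalizer optional `normalization_spec`, stored for later
#'   denormalization of synthesized slices.
#' @param augment randomly flip pairs vertically during training.
#' @param checkpoint_dir if non-`NULL`, a checkpoint is written there
#'   after every epoch.
#' @param tiny_profile convenience switch for desk-scale runs
#'   (`base_width = 8`).
#' @param verbose print a line per epoch.
#'
#' @return an object of class `tsgan` with the trained networks, the
#'   per-step loss log (`$log`), per-epoch validation errors
#'   (`$validation`), and a snapshot of the generator after epoch 1
#'   (`$epoch1_state`).
#' @export
tsgan <- function(pairs, epochs = 30L, batch_size = 10L, base_width = 64L,
                  weights = loss_weights(), learning_rate = 2e-4,
                  betas = c(0.5, 0.999), use_spectral_norm = TRUE,
                  use_local_discriminator = TRUE, use_edge_maps = TRUE,
                  use_segmentor = TRUE, use_residual = TRUE,
                  use_attention = TRUE, patch_size = NULL, seed = 1L,
                  validation_pairs = NULL, normalizer = NULL,
                  augment = TRUE, checkpoint_dir = NULL,
                  tiny_profile = FALSE, verbose = FALSE) {
  if (length(pairs) == 0) stop("empty training set")
  if (epochs < 1) stop("epochs must be >= 1")
  for (p in pairs) if (sum(p$mask) < 1) stop("all pairs need tumor masks")
  if (tiny_profile) base_width <- 8L
  image_size <- nrow(pairs[[1]]$pre)
  # the 3-layer local discriminator plus its scoring convolution needs at
  # least a 16-pixel patch
  if (is.null(patch_size)) patch_size <- max(16L, image_size %/% 4L)
  if (patch_size > image_size) stop("patch_size exceeds the image size")
  set.seed(seed)

  gcfg <- generator_config(image_size, base_width,
                           use_spectral_norm = use_spectral_norm,
                           use_residual = use_residual,
                           use_attention = use_attention)
  gdcfg <- discriminator_config(image_size, n_layers = 4L,
                                base_width = base_width,
                                use_spectral_norm = use_spectral_norm)
  ldcfg <- discriminator_config(patch_size, n_layers = 3L,
                                base_width = base_width,
                                use_spectral_norm = use_spectral_norm)
  scfg <- segmentor_config(image_size, base_width,
                           depth = min(5L, as.integer(log2(image_size)) - 1L))
  G <- build_generator(gcfg)
  GD <- build_discriminator(gdcfg)
  LD <- if (use_local_discriminator) build_discriminator(ldcfg) else NULL
  S <- if (use_segmentor) build_segmentor(scfg) else NULL

  opt_g <- adam_new(G$params, learning_rate, betas[1], betas[2])
  opt_gd <- adam_new(GD$params, learning_rate, betas[1], betas[2])
  opt_ld <- if (!is.null(LD)) adam_new(LD$params, learning_rate, betas[1], betas[2])
  opt_s <- if (!is.null(S)) adam_new(S$params, learning_rate, betas[1], betas[2])

  n <- length(pairs)
  log_rows <- list()
  validation <- list()
  epoch1_state <- NULL
  model <- structure(list(G = G, GD = GD, LD = LD, S = S, configs = list(
    generator = gcfg, gd = gdcfg, ld = ldcfg, segmentor = scfg),
    weights = weights, patch_size = patch_size, image_size = image_size,
    normalizer = normalizer, seed = seed,
    flags = list(use_spectral_norm = use_spectral_norm,
                 use_local_discriminator = use_local_discriminator,
                 use_edge_maps = use_edge_maps,
                 use_segmentor = use_segmentor)), class = "tsgan")

  prep <- lapply(pairs, prep_pair, patch_size = patch_size)
  for (epoch in seq_len(epochs)) {
    lam <- curriculum_lambda(epoch, weights)
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:min(starts[b] + batch_size - 1, n)]
      batch <- lapply(prep[idx], function(p) {
        if (augment && stats::runif(1) < 0.5) p$f else p$o
      })
      row <- tsgan_step(model, batch, lam, opt_g, opt_gd, opt_ld, opt_s)
      row$epoch <- epoch
      row$step <- b
      row$lambda_curr <- lam
      log_rows[[length(log_rows) + 1L]] <- row
    }
    if (!is.null(validation_pairs))
      validation[[epoch]] <- validation_errors(model, validation_pairs)
    if (epoch == 1L) epoch1_state <- network_state(G)
    if (!is.null(checkpoint_dir)) {
      model$log <- do.call(rbind, lapply(log_rows, as.data.frame))
      save_tsgan(model, file.path(checkpoint_dir,
                                  sprintf("epoch%03d.rds", epoch)))
    }
    if (verbose) {
      lg <- log_rows[[length(log_rows)]]
      message(sprintf("epoch %d/%d  g=%.3f d=%.3f", epoch, epochs,
                      lg$total_g, lg$d_global))
    }
  }
  model$log <- do.call(rbind, lapply(log_rows, as.data.frame))
  model$validation <- if (length(validation))
    do.call(rbind, lapply(seq_along(validation), function(e)
      cbind(epoch = e, as.data.frame(validation[[e]])))) else NULL
  model$epoch1_state <- epoch1_state
  model$epochs <- epochs
  model
}

# Precompute the target-side constants of one slice pair for both flip
# orientations: binarized edge maps of preT1 and ceT1, the soft ceT1 edge
# map, the tumor window, and the tumor patches of preT1/ceT1 with their
# edge maps. Only the synthesized image's edges need runtime
# differentiation, so everything real-sided is computed once up front.
prep_pair <- function(pair, patch_size) {
  one <- function(p) {
    win <- tumor_window(p$mask, patch_size)
    rows <- win[1]:(win[1] + patch_size - 1)
    cols <- win[2]:(win[2] + patch_size - 1)
    xp <- p$pre[rows, cols]
    yp <- p$ce[rows, cols]
    yp_soft <- edge_soft(yp)
    list(pre = p$pre, ce = p$ce, mask = p$mask, win = win, xp = xp,
         xe = edge_binarize(edge_soft(p$pre), 0.4),
         ye = edge_binarize(edge_soft(p$ce), 0.4),
         y_soft = edge_soft(p$ce),
         xp_eb = edge_binarize(edge_soft(xp), 0.4),
         yp_soft = yp_soft,
         yp_eb = edge_binarize(yp_soft, 0.4))
  }
  list(o = one(pair), f = one(augment_flip(pair, force = TRUE)))
}

# one optimization step on a batch of prepared pairs; returns the log row
tsgan_step <- function(model, batch, lam, opt_g, opt_gd, opt_ld, opt_s) {
  G <- model$G; GD <- model$GD; LD <- model$LD; S <- model$S
  w <- model$weights
  use_edge <- model$flags$use_edge_maps
  ps <- model$patch_size
  N <- length(batch)
  H <- model$image_size
  arr <- function(field, side = H) {
    a <- array(0, dim = c(side, side, 1L, N))
    for (i in seq_len(N)) a[, , 1, i] <- batch[[i]][[field]]
    a
  }
  xv <- arr("pre"); yv <- arr("ce")
  windows <- t(vapply(batch, function(p) p$win, numeric(2)))
  masks <- arr("mask")

  ag_tape_start()
  on.exit(ag_tape_stop())
  x <- ag_const(xv); y <- ag_const(yv)
  xe <- ag_const(arr("xe"))
  ye <- ag_const(arr("ye"))
  y_soft <- ag_const(arr("y_soft"))
  xp <- ag_const(arr("xp", ps))
  xe_p <- ag_const(arr("xp_eb", ps))
  ye_p <- ag_const(arr("yp_eb", ps))
  yp_soft <- ag_const(arr("yp_soft", ps))

  fake <- generator_forward(G, x, training = TRUE)
  fake_soft <- ag_sobel_soft(fake)
  fake_eb <- ag_binarize_st(fake_soft, 0.4)
  y_patch <- ag_crop_batch(y, windows, ps)
  fake_patch <- ag_crop_batch(fake, windows, ps)
  fake_patch_soft <- ag_sobel_soft(fake_patch)
  fe_p <- ag_binarize_st(fake_patch_soft, 0.4)

  ## (a) discriminators on detached fakes
  fake_d <- ag_detach(fake)
  fake_eb_d <- ag_detach(fake_eb)
  gd_real <- discriminator_forward(GD, dis_input(x, xe, y, ye, use_edge),
                                   training = TRUE)
  gd_fake <- discriminator_forward(GD, dis_input(x, xe, fake_d, fake_eb_d,
                                                 use_edge), training = TRUE)
  d_gd <- hinge_d_loss(gd_real$score, gd_fake$score)
  d_total <- d_gd
  d_ld_val <- NA_real_
  ld_real <- NULL
  if (!is.null(LD)) {
    fp <- ag_detach(fake_patch)
    fep <- ag_detach(fe_p)
    ld_real <- discriminator_forward(LD, dis_input(xp, xe_p, y_patch, ye_p,
                                                   use_edge), training = TRUE)
    ld_fake <- discriminator_forward(LD, dis_input(xp, xe_p, fp, fep,
                                                   use_edge), training = TRUE)
    d_ld <- hinge_d_loss(ld_real$score, ld_fake$score)
    d_ld_val <- as.numeric(d_ld$value)
    d_total <- ag_add(d_total, d_ld)
  }
  ag_zero_grads(GD$params)
  if (!is.null(LD)) ag_zero_grads(LD$params)
  network_freeze(G, TRUE)
  ag_backward(d_total)
  network_freeze(G, FALSE)
  adam_step(opt_gd)
  if (!is.null(LD)) adam_step(opt_ld)

  ## (b) segmentor on target ceT1 only
  s_val <- NA_real_
  if (!is.null(S)) {
    s_pred <- segmentor_forward(S, y, training = TRUE)
    s_l <- seg_loss(s_pred, ag_const(masks))
    s_val <- as.numeric(s_l$value)
    ag_zero_grads(S$params)
    ag_backward(s_l)
    adam_step(opt_s)
  }

  ## (c) generator: adversarial + seven-term L1, others frozen. The
  ## feature-matching targets are the real-pair features from phase (a).
  for (net in list(GD, LD, S)) if (!is.null(net)) network_freeze(net, TRUE)
  gd_fake_g <- discriminator_forward(GD, dis_input(x, xe, fake, fake_eb,
                                                   use_edge),
                                     training = FALSE)
  g_adv <- hinge_g_loss(gd_fake_g$score)
  ld_fake_g <- NULL
  if (!is.null(LD)) {
    ld_fake_g <- discriminator_forward(LD, dis_input(xp, xe_p, fake_patch,
                                                     fe_p, use_edge),
                                       training = FALSE)
    g_adv <- ag_add(g_adv, hinge_g_loss(ld_fake_g$score))
  }
  l1 <- ag_generator_l1(x, y, fake, windows, ps, S, GD, LD, w, lam,
                        use_edge = use_edge, x_edge_b = xe, y_edge_b = ye,
                        fake_edge_b = fake_eb,
                        cache = list(
                          y_soft = y_soft, fake_soft = fake_soft,
                          y_patch = y_patch, fake_patch = fake_patch,
                          xp = xp, xe_p = xe_p, ye_p = ye_p, fe_p = fe_p,
                          y_patch_soft = yp_soft,
                          fake_patch_soft = fake_patch_soft,
                          gd_real_features = ag_detach(gd_real$features),
                          gd_fake = gd_fake_g,
                          ld_real_features = if (!is.null(ld_real))
                            ag_detach(ld_real$features),
                          ld_fake = ld_fake_g))
  g_total <- ag_add(ag_scale(g_adv, w$lambda_adv), l1$total)
  ag_zero_grads(G$params)
  ag_backward(g_total)
  adam_step(opt_g)
  for (net in list(GD, LD, S)) if (!is.null(net)) network_freeze(net, FALSE)

  c(list(d_global = as.numeric(d_gd$value), d_local = d_ld_val,
         s_loss = s_val, g_adv = as.numeric(g_adv$value),
         total_g = as.numeric(g_total$value)),
    as.list(l1$terms))
}

#' Held-out L1 errors of a fitted model
#'
#' Mean absolute error between synthesized and target ceT1 on the whole
#' field of view and on tumor-centered patches.
#'
#' @param model a fitted [tsgan()] object.
#' @param pairs held-out [slice_pair()]s.
#' @return list with `full_l1` and `tumor_l1`.
#' @export
validation_errors <- function(model, pairs) {
  pre <- vapply(pairs, function(p) p$pre, matrix(0, model$image_size,
                                                 model$image_size))
  synth <- synthesize(model, pre)
  full <- mean(vapply(seq_along(pairs), function(i)
    mean(abs(pairs[[i]]$ce - synth[, , i])), 0))
  tum <- mean(vapply(seq_along(pairs), function(i) {
    w <- tumor_window(pairs[[i]]$mask, model$patch_size)
    rows <- w[1]:(w[1] + model$patch_size - 1)
    cols <- w[2]:(w[2] + model$patch_size - 1)
    mean(abs(pairs[[i]]$ce[rows, cols] - synth[rows, cols, i]))
  }, 0))
  list(full_l1 = full, tumor_l1 = tum)
}

#' Model as of the end of epoch 1
#'
#' Rebuilds the generator from the snapshot stored after the first
#' training epoch, for before/after comparisons.
#'
#' @param model a fitted [tsgan()] object (fitted with the default
#'   snapshotting).
#' @return a `tsgan` object whose generator holds the epoch-1 weights.
#' @export
epoch1_generator <- function(model) {
  if (is.null(model$epoch1_state)) stop("model holds no epoch-1 snapshot")
  G1 <- build_generator(model$configs$generator)
  network_load_state(G1, model$epoch1_state)
  model$G <- G1
  model
}

#' Synthesize ceT1 slices from preT1 slices
#'
#' Deterministic evaluation-mode forward pass of the trained generator.
#'
#' @param model a fitted [tsgan()] object.
#' @param pre a matrix (one slice), a 3D array `[H, W, n]`, or a list of
#'   matrices, already normalized to \[-1, 1\].
#' @param denormalize map outputs back to raw intensities with the stored
#'   normalizer (requires one in the model).
#' @return array `[H, W, n]` of synthesized slices (matrix for a single
#'   input slice).
#' @export
synthesize <- function(model, pre, denormalize = FALSE) {
  stopifnot(inherits(model, "tsgan"))
  single <- is.matrix(pre)
  if (is.list(pre)) pre <- simplify2array(pre)
  if (is.matrix(pre)) dim(pre) <- c(dim(pre), 1L)
  n <- dim(pre)[3]
  out <- array(0, dim = dim(pre))
  chunk <- 8L
  for (s in seq(1, n, by = chunk)) {
    ix <- s:min(s + chunk - 1, n)
    xb <- array(pre[, , ix], dim = c(dim(pre)[1:2], 1L, length(ix)))
    yb <- network_forward(model$G, xb)
    out[, , ix] <- yb[, , 1, ]
  }
  if (denormalize) {
    if (is.null(model$normalizer)) stop("model stores no normalization spec")
    out <- invert_normalizer(out, model$normalizer)
  }
  if (single) out[, , 1] else out
}

#' @export
predict.tsgan <- function(object, newdata, denormalize = FALSE, ...) {
  synthesize(object, newdata, denormalize = denormalize)
}

#' @export
print.tsgan <- function(x, ...) {
  cat("Tumor-attentive segmentation-guided GAN\n")
  cat(sprintf("  image size : %d x %d, tumor patch %d\n", x$image_size,
              x$image_size, x$patch_size))
  cat(sprintf("  generator  : %s parameters\n",
              format(network_n_params(x$G), big.mark = ",")))
  cat(sprintf("  epochs     : %d, final curriculum weight %g\n",
              x$epochs, curriculum_lambda(x$epochs, x$weights)))
  fl <- x$flags
  cat(sprintf("  components : SN=%s LD=%s edges=%s segmentor=%s\n",
              fl$use_spectral_norm, fl$use_local_discriminator,
              fl$use_edge_maps, fl$use_segmentor))
  invisible(x)
}

#' @export
summary.tsgan <- function(object, ...) {
  print(object)
  lg <- object$log
  last <- lg[lg$epoch == max(lg$epoch), ]
  cat("\nFinal-epoch mean losses:\n")
  for (col in c("d_global", "d_local", "s_loss", "g_adv", "global_l1",
                "patch_l1", "total_g")) {
    v <- suppressWarnings(mean(last[[col]]))
    if (is.finite(v)) cat(sprintf("  %-12s %.4f\n", col, v))
  }
  if (!is.null(object$validation)) {
    v <- object$validation
    cat(sprintf("\nHeld-out L1 (epoch %d): full %.4f, tumor %.4f\n",
                max(v$epoch), v$full_l1[nrow(v)], v$tumor_l1[nrow(v)]))
  }
  invisible(object)
}

#' @export
plot.tsgan <- function(x, ...) {
  lg <- x$log
  byep <- stats::aggregate(cbind(total_g, d_global) ~ epoch, lg, mean)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(byep$epoch, byep$total_g, type = "l", xlab = "epoch",
                 ylab = "generator loss", main = "Generator")
  graphics::plot(byep$epoch, byep$d_global, type = "l", xlab = "epoch",
                 ylab = "discriminator loss", main = "Global discriminator")
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint holds every network's parameters and buffers, the
#' configurations, loss weights, normalizer and seed; a JSON sidecar with
#' the configuration is written next to it.
#'
#' @param model a `tsgan` object.
#' @param path destination `.rds` path.
#' @export
save_tsgan <- function(model, path) {
  states <- list(G = network_state(model$G), GD = network_state(model$GD),
                 LD = if (!is.null(model$LD)) network_state(model$LD),
                 S = if (!is.null(model$S)) network_state(model$S))
  payload <- list(states = states, configs = model$configs,
                  weights = unclass(model$weights),
                  patch_size = model$patch_size,
                  image_size = model$image_size, flags = model$flags,
                  normalizer = model$normalizer, seed = model$seed,
                  epochs = model$epochs, log = model$log,
                  epoch1_state = model$epoch1_state)
  saveRDS(payload, path)
  sidecar <- list(image_size = model$image_size,
                  patch_size = model$patch_size, seed = model$seed,
                  epochs = model$epochs, flags = model$flags,
                  weights = unclass(model$weights),
                  clip_max = model$normalizer$clip_max)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @param path checkpoint path written by [save_tsgan()].
#' @rdname save_tsgan
#' @export
load_tsgan <- function(path) {
  p <- readRDS(path)
  G <- build_generator(p$configs$generator)
  network_load_state(G, p$states$G)
  GD <- build_discriminator(p$configs$gd)
  network_load_state(GD, p$states$GD)
  LD <- NULL
  if (!is.null(p$states$LD)) {
    LD <- build_discriminator(p$configs$ld)
    network_load_state(LD, p$states$LD)
  }
  S <- NULL
  if (!is.null(p$states$S)) {
    S <- build_segmentor(p$configs$segmentor)
    network_load_state(S, p$states$S)
  }
  structure(list(G = G, GD = GD, LD = LD, S = S, configs = p$configs,
                 weights = do.call(loss_weights, p$weights),
                 patch_size = p$patch_size, image_size = p$image_size,
                 normalizer = p$normalizer, seed = p$seed, flags = p$flags,
                 epochs = p$epochs, log = p$log,
                 epoch1_state = p$epoch1_state),
            class = "tsgan")
}
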