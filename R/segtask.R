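# Downstream validity study: an independent 2D U-Net tumor segmenter
# (four down/up sampling levels, BCE + Dice loss) trained on ceT1 or on a
# 1:1 mix of real and synthetic ceT1, then evaluated with Dice, BCE and
# average symmetric surface distance after excluding small tumors.

#' Dice similarity coefficient
#'
#' @param pred,label binary masks of equal shape.
#' @return `2|P n L| / (|P| + |L|)`; 1 when both masks are empty.
#' @export
dice_coef <- function(pred, label) {
  sp <- sum(pred); sl <- sum(label)
  if (sp + sl == 0) return(1)
  2 * sum(pred * label) / (sp + sl)
}

# boundary pixels: mask minus its 4-connected erosion (image border counts
# as outside, so masks touching the border have boundary there)
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  er <- pad[2:(H + 1), 2:(W + 1)] * pad[1:H, 2:(W + 1)] *
    pad[3:(H + 2), 2:(W + 1)] * pad[2:(H + 1), 1:W] * pad[2:(H + 1), 3:(W + 2)]
  which(m == 1 & er == 0, arr.ind = TRUE)
}

#' Average symmetric surface distance
#'
#' Boundary pixels are the mask minus its 4-connected erosion; distances
#' are exact Euclidean distances between boundary pixel centers, scaled
#' by the pixel spacing. ASSD averages every boundary pixel's distance to
#' the nearest boundary pixel of the other mask, symmetrically:
#' `(sum_a d(a, B) + sum_b d(b, A)) / (|A| + |B|)`.
#'
#' @param pred,label binary masks of equal shape.
#' @param spacing_mm pixel spacing in mm.
#' @return ASSD in mm; 0 for identical masks; `NA` when either mask is
#'   empty (no boundary pairing exists).
#' @export
assd <- function(pred, label, spacing_mm = 1) {
  a <- mask_boundary(pred)
  b <- mask_boundary(label)
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  da <- sqrt(apply(d2, 1, min))
  db <- sqrt(apply(d2, 2, min))
  spacing_mm * (sum(da) + sum(db)) / (nrow(a) + nrow(b))
}

#' Train the independent segmentation network
#'
#' Standard 2D U-Net with four down/up sampling levels trained with
#' BCE + Dice. In mixed mode the training set holds real and synthetic
#' ceT1 slices in an exact 1:1 ratio (each with the real tumor label).
#'
#' @param images list of 2D ceT1 slices (normalized).
#' @param masks list of matching binary tumor masks.
#' @param synthetic_images optional list of synthesized ceT1 slices for
#'   mixed training; must have exactly the same length as `images`.
#' @param epochs,batch_size,base_width,learning_rate training settings.
#' @param seed RNG seed (initialization and shuffling).
#' @param verbose print a line per epoch.
#' @return an object of class `segtask` holding the trained network.
#' @export
segtask_train <- function(images, masks, synthetic_images = NULL,
                          epochs = 10L, batch_size = 8L, base_width = 8L,
                          learning_rate = 2e-4, seed = 1L, verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) > 0)
  mixed <- !is.null(synthetic_images)
  if (mixed && length(synthetic_images) != length(images))
    stop("mixed training requires a 1:1 ratio of real and synthetic slices")
  set.seed(seed)
  H <- nrow(images[[1]])
  depth <- min(4L, as.integer(log2(H)) - 1L)
  cfg <- segmentor_config(H, base_width, depth = depth)
  net <- build_segmentor(cfg)
  opt <- adam_new(net$params, learning_rate, 0.5, 0.999)
  xs <- c(images, if (mixed) synthetic_images)
  ys <- c(masks, if (mixed) masks)
  n <- length(xs)
  losses <- numeric(0)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      xb <- array(0, dim = c(H, H, 1L, length(idx)))
      yb <- array(0, dim = c(H, H, 1L, length(idx)))
      for (i in seq_along(idx)) {
        xb[, , 1, i] <- xs[[idx[i]]]
        yb[, , 1, i] <- ys[[idx[i]]]
      }
      ag_tape_start()
      pred <- segmentor_forward(net, ag_const(xb), training = TRUE)
      l <- seg_loss(pred, ag_const(yb))
      losses <- c(losses, as.numeric(l$value))
      ag_zero_grads(net$params)
      ag_backward(l)
      adam_step(opt)
      ag_tape_stop()
    }
    if (verbose)
      message(sprintf("segtask epoch %d/%d loss %.4f", epoch, epochs,
                      losses[length(losses)]))
  }
  structure(list(net = net, cfg = cfg, losses = losses, mixed = mixed,
                 seed = seed), class = "segtask")
}

#' Predict tumor probability maps
#'
#' @param object a [segtask_train()] model.
#' @param newdata list of slices or a 3D array.
#' @param ... unused.
#' @return list of probability matrices.
#' @export
predict.segtask <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  if (is.array(newdata) && length(dim(newdata)) == 3)
    newdata <- lapply(seq_len(dim(newdata)[3]), function(i) newdata[, , i])
  lapply(newdata, function(m) network_forward(object$net, m)[, , 1, 1])
}

#' Evaluate the independent segmentation task
#'
#' Slices whose true tumor area falls below `min_area_cm2` are excluded
#' (at 1 mm isotropic pixels, 3.6 cm^2 equals 360 pixels; inclusion uses
#' `>=`). Per kept slice the 0.5-thresholded prediction is scored with
#' Dice and ASSD, and the raw probabilities with BCE. An empty prediction
#' against a nonempty label scores Dice 0 with ASSD undefined (`NA`),
#' flagged in `assd_defined`.
#'
#' @param model a [segtask_train()] model.
#' @param images,masks held-out slices and labels.
#' @param min_area_cm2 exclusion threshold for small tumors.
#' @param spacing_mm isotropic pixel spacing of the slices.
#' @param threshold probability binarization threshold.
#' @return data.frame of per-slice records of class `segtask_eval`.
#' @export
segtask_evaluate <- function(model, images, masks, min_area_cm2 = 3.6,
                             spacing_mm = 1, threshold = 0.5) {
  stopifnot(length(images) == length(masks))
  min_px <- min_area_cm2 * 100 / spacing_mm^2
  probs <- predict(model, images)
  rows <- lapply(seq_along(images), function(i) {
    label <- masks[[i]]
    if (sum(label) < min_px) return(NULL)
    p <- probs[[i]]
    pred <- (p >= threshold) * 1
    data.frame(slice = i,
               dsc = dice_coef(pred, label),
               bce = bce_loss(p, label),
               assd_mm = assd(pred, label, spacing_mm),
               assd_defined = !(sum(pred) == 0 && sum(label) > 0))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(slice = integer(), dsc = numeric(), bce = numeric(),
                      assd_mm = numeric(), assd_defined = logical())
  class(out) <- c("segtask_eval", class(out))
  out
}

#' Aggregate a segmentation evaluation
#'
#' @param ev a [segtask_evaluate()] result.
#' @return one-row data.frame of mean (sd) per metric.
#' @export
segtask_summary <- function(ev) {
  data.frame(n = nrow(ev),
             dsc_mean = mean(ev$dsc), dsc_sd = stats::sd(ev$dsc),
             bce_mean = mean(ev$bce), bce_sd = stats::sd(ev$bce),
             assd_mean = mean(ev$assd_mm[ev$assd_defined]),
             assd_sd = stats::sd(ev$assd_mm[ev$assd_defined]))
}
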