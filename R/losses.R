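# The composite objective: hinge adversarial losses for both
# discriminators, the segmentor's BCE + Dice loss, the epoch-curriculum
# weight, and the generator's seven-term L1 objective (whole-FOV L1, edge
# L1, tumor-patch L1, segmentor-masked L1, patch-edge L1, and feature
# matching against both discriminators). Each public function accepts
# plain numeric arrays; the ag_* twins operate on autodiff nodes inside
# the training loop and share the same algebra.

#' Loss weights and curriculum schedule
#'
#' Weight set of the generator objective: `lambda_global` and
#' `lambda_edge` scale the whole-image and edge L1 terms, the curriculum
#' weight for tumor-focused terms rises by `lambda_curr_slope` per epoch
#' until `lambda_curr_cap`, `lambda_adv` scales the generator's
#' adversarial terms and `lambda_fm` the two feature-matching terms.
#'
#' @param lambda_global,lambda_edge,lambda_curr_cap,lambda_curr_slope
#'   nonnegative scalars.
#' @param lambda_adv,lambda_fm nonnegative scalars.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_global = 300, lambda_edge = 20,
                         lambda_curr_cap = 100, lambda_curr_slope = 5,
                         lambda_adv = 5, lambda_fm = 1) {
  w <- list(lambda_global = lambda_global, lambda_edge = lambda_edge,
            lambda_curr_cap = lambda_curr_cap,
            lambda_curr_slope = lambda_curr_slope,
            lambda_adv = lambda_adv, lambda_fm = lambda_fm)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

#' Curriculum weight for tumor-focused loss terms
#'
#' `min(slope * epoch, cap)`: the tumor terms are weighted up linearly
#' over early epochs (whole-breast synthesis first) and saturate at the
#' cap (tumor focus later).
#'
#' @param epoch nonnegative integer (vectorized).
#' @param weights a [loss_weights()].
#' @return the curriculum weight(s).
#' @export
curriculum_lambda <- function(epoch, weights = loss_weights()) {
  if (any(epoch < 0)) stop("epoch must be nonnegative")
  pmin(weights$lambda_curr_slope * epoch, weights$lambda_curr_cap)
}

#' Hinge discriminator loss
#'
#' `mean(max(0, 1 - real)) + mean(max(0, 1 + fake))`, the algebraic
#' equivalent of `-E[min(0, -1 + D(real))] - E[min(0, -1 - D(fake))]`.
#'
#' @param real_scores,fake_scores numeric score grids of equal shape (or
#'   autodiff nodes inside a training step).
#' @return scalar loss.
#' @export
hinge_d_loss <- function(real_scores, fake_scores) {
  if (is_ag_node(real_scores)) {
    ag_add(ag_mean(ag_relu(ag_add_const(ag_neg(real_scores), 1))),
           ag_mean(ag_relu(ag_add_const(fake_scores, 1))))
  } else {
    mean(pmax(0, 1 - real_scores)) + mean(pmax(0, 1 + fake_scores))
  }
}

#' Hinge generator (non-saturating) adversarial loss
#'
#' `-mean(fake_scores)`.
#'
#' @param fake_scores numeric score grid or autodiff node.
#' @return scalar loss.
#' @export
hinge_g_loss <- function(fake_scores) {
  if (is_ag_node(fake_scores)) ag_neg(ag_mean(fake_scores))
  else -mean(fake_scores)
}

#' Segmentation loss: binary cross-entropy plus Dice loss
#'
#' `BCE(l, p) + 1 - (2 * sum(l * p) + eps) / (sum(l) + sum(p) + eps)`,
#' with probabilities clipped to `[1e-7, 1 - 1e-7]` inside the BCE.
#'
#' @param pred_prob predicted probabilities in \[0, 1\].
#' @param label binary ground-truth mask of the same shape.
#' @param eps Dice smoothing constant.
#' @return scalar loss.
#' @export
seg_loss <- function(pred_prob, label, eps = 1e-6) {
  if (is_ag_node(pred_prob)) {
    lv <- ag_value(label)
    bce <- ag_bce(pred_prob, lv)
    inter <- ag_sum(ag_mul(pred_prob, ag_const(lv)))
    denom <- ag_add_const(ag_sum(pred_prob), sum(lv) + eps)
    dice <- ag_add_const(ag_neg(ag_div_scalar(
      ag_add_const(ag_scale(inter, 2), eps), denom)), 1)
    ag_add(bce, dice)
  } else {
    if (!identical(dim_or1(pred_prob), dim_or1(label)))
      stop("prediction and label shapes differ")
    dice <- 1 - (2 * sum(label * pred_prob) + eps) /
      (sum(label) + sum(pred_prob) + eps)
    bce_loss(pred_prob, label) + dice
  }
}

#' Binary cross-entropy on probabilities
#'
#' Mean BCE with probabilities clipped to `[clip, 1 - clip]`.
#'
#' @param pred_prob probabilities in \[0, 1\].
#' @param label binary array of the same shape.
#' @param clip clipping bound.
#' @return scalar.
#' @export
bce_loss <- function(pred_prob, label, clip = 1e-7) {
  p <- pmin(pmax(pred_prob, clip), 1 - clip)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

# ---- generator L1 objective ----

# Differentiable core. All inputs are nodes: x, y, fake are [H,W,1,N];
# windows is the per-sample tumor window matrix; nets may be NULL when the
# corresponding ablation flag removed them. Returns list(total = node,
# terms = named numeric vector of the unweighted term values).
ag_generator_l1 <- function(x, y, fake, windows, patch_size, S, GD, LD,
                            weights, lambda_curr, use_edge = TRUE,
                            x_edge_b = NULL, y_edge_b = NULL,
                            fake_edge_b = NULL, cache = list()) {
  terms <- c(global_l1 = NA_real_, edge_l1 = NA_real_, patch_l1 = NA_real_,
             seg_masked_l1 = NA_real_, patch_edge_l1 = NA_real_,
             gd_fm = NA_real_, ld_fm = NA_real_)
  pieces <- list()
  add <- function(name, node, lambda) {
    terms[[name]] <<- as.numeric(node$value)
    if (lambda > 0) pieces[[length(pieces) + 1L]] <<- ag_scale(node, lambda)
  }

  add("global_l1", ag_mean_abs_diff(y, fake), weights$lambda_global)

  if (use_edge) {
    y_soft <- if (!is.null(cache$y_soft)) cache$y_soft else ag_sobel_soft(y)
    fake_soft <- if (!is.null(cache$fake_soft)) cache$fake_soft
                 else ag_sobel_soft(fake)
    add("edge_l1", ag_mean_abs_diff(y_soft, fake_soft), weights$lambda_edge)
  }

  y_patch <- if (!is.null(cache$y_patch)) cache$y_patch
             else ag_crop_batch(y, windows, patch_size)
  fake_patch <- if (!is.null(cache$fake_patch)) cache$fake_patch
                else ag_crop_batch(fake, windows, patch_size)
  add("patch_l1", ag_mean_abs_diff(y_patch, fake_patch), lambda_curr)

  if (!is.null(S)) {
    sy <- segmentor_forward(S, y, training = FALSE)
    sf <- segmentor_forward(S, fake, training = FALSE)
    add("seg_masked_l1",
        ag_mean_abs_diff(ag_mul(sy, y), ag_mul(sf, fake)), lambda_curr)
  }

  if (use_edge) {
    yps <- if (!is.null(cache$y_patch_soft)) cache$y_patch_soft
           else ag_sobel_soft(y_patch)
    fps <- if (!is.null(cache$fake_patch_soft)) cache$fake_patch_soft
           else ag_sobel_soft(fake_patch)
    add("patch_edge_l1", ag_mean_abs_diff(yps, fps), weights$lambda_edge)
  }

  if (!is.null(GD)) {
    real_feat <- if (!is.null(cache$gd_real_features)) cache$gd_real_features
    else ag_detach(discriminator_forward(
      GD, dis_input(x, x_edge_b, y, y_edge_b, use_edge),
      training = FALSE)$features)
    gd_fake <- if (!is.null(cache$gd_fake)) cache$gd_fake
    else discriminator_forward(
      GD, dis_input(x, x_edge_b, fake, fake_edge_b, use_edge),
      training = FALSE)
    add("gd_fm", ag_mean_abs_diff(real_feat, gd_fake$features),
        weights$lambda_fm)
  }

  if (!is.null(LD)) {
    xp <- if (!is.null(cache$xp)) cache$xp
          else ag_crop_batch(x, windows, patch_size)
    xe_p <- if (!use_edge) NULL else if (!is.null(cache$xe_p)) cache$xe_p
            else ag_binarize_st(ag_sobel_soft(xp), 0.4)
    ye_p <- if (!use_edge) NULL else if (!is.null(cache$ye_p)) cache$ye_p
            else ag_binarize_st(ag_sobel_soft(y_patch), 0.4)
    fe_p <- if (!use_edge) NULL else if (!is.null(cache$fe_p)) cache$fe_p
            else ag_binarize_st(ag_sobel_soft(fake_patch), 0.4)
    real_feat_l <- if (!is.null(cache$ld_real_features)) cache$ld_real_features
    else ag_detach(discriminator_forward(
      LD, dis_input(xp, xe_p, y_patch, ye_p, use_edge),
      training = FALSE)$features)
    ld_fake <- if (!is.null(cache$ld_fake)) cache$ld_fake
    else discriminator_forward(
      LD, dis_input(xp, xe_p, fake_patch, fe_p, use_edge), training = FALSE)
    add("ld_fm", ag_mean_abs_diff(real_feat_l, ld_fake$features),
        weights$lambda_fm)
  }

  total <- if (length(pieces) == 0) ag_const(0) else Reduce(ag_add, pieces)
  list(total = total, terms = terms)
}

# assemble the 4-channel discriminator input (conditioning image,
# conditioning edge, candidate image, candidate edge); zero edge channels
# when the edge component is ablated
dis_input <- function(cond, cond_edge, cand, cand_edge, use_edge) {
  zero_like <- function(a) ag_const(array(0, dim = dim(a$value)))
  if (!use_edge) {
    cond_edge <- zero_like(cond)
    cand_edge <- zero_like(cand)
  }
  ag_concat_ch(ag_concat_ch(cond, cond_edge), ag_concat_ch(cand, cand_edge))
}

#' Generator L1 objective (seven weighted terms)
#'
#' Computes the weighted sum of (1) whole-FOV L1 between target and
#' synthesized image, (2) whole-FOV L1 between their soft edge maps,
#' (3) L1 between tumor-centered patches, (4) L1 between the
#' segmentor-masked products `S(y) * y` and `S(G(x)) * G(x)` with the
#' segmentor's parameters treated as constants, (5) L1 between patch edge
#' maps, and the feature-matching L1 against the penultimate features of
#' (6) the global and (7) the local discriminator.
#'
#' @param pair a [slice_pair()] (or list with `pre`, `ce`, `mask`).
#' @param synthesized matrix: the generator output for `pair$pre`.
#' @param S,GD,LD networks from the `build_*` functions (any may be `NULL`,
#'   dropping the corresponding terms).
#' @param weights a [loss_weights()].
#' @param epoch training epoch (sets the curriculum weight).
#' @param patch_size tumor patch side length.
#' @return list with `total` (scalar) and `terms` (named vector of the
#'   seven unweighted term values; `NA` for dropped terms).
#' @export
generator_l1_loss <- function(pair, synthesized, S = NULL, GD = NULL,
                              LD = NULL, weights = loss_weights(), epoch = 1,
                              patch_size = 64L) {
  if (sum(pair$mask) < 1) stop("tumor mask required for the patch terms")
  started <- !.ag$recording
  if (started) ag_tape_start()
  on.exit(if (started) ag_tape_stop())
  as_batch <- function(m) {
    a <- as.array(m)
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L, 1L)
    a
  }
  x <- ag_const(as_batch(pair$pre))
  y <- ag_const(as_batch(pair$ce))
  fake <- ag_const(as_batch(synthesized))
  win <- matrix(tumor_window(as.matrix(pair$mask), patch_size), nrow = 1)
  xe <- ag_binarize_st(ag_sobel_soft(x), 0.4)
  ye <- ag_binarize_st(ag_sobel_soft(y), 0.4)
  fe <- ag_binarize_st(ag_sobel_soft(fake), 0.4)
  lam <- curriculum_lambda(epoch, weights)
  out <- ag_generator_l1(x, y, fake, win, patch_size, S, GD, LD, weights,
                         lam, use_edge = TRUE, x_edge_b = xe, y_edge_b = ye,
                         fake_edge_b = fe)
  list(total = as.numeric(out$total$value), terms = out$terms,
       lambda_curr = lam)
}

#' Total objective of each optimized party
#'
#' Combines precomputed components into the quantity each network
#' minimizes: both discriminators their hinge losses, the segmentor its
#' BCE + Dice loss, and the generator
#' `lambda_adv * (hinge_g(GD) + hinge_g(LD)) + L1_total`.
#'
#' @param components list with any of `gd_real`, `gd_fake`, `ld_real`,
#'   `ld_fake` (score grids), `seg_pred`, `seg_label`, `g_l1_total`.
#' @param weights a [loss_weights()].
#' @return list with `d_global`, `d_local`, `s`, `g` (NA where inputs are
#'   missing).
#' @export
total_objective <- function(components, weights = loss_weights()) {
  g_adv <- 0
  d_global <- d_local <- s <- NA_real_
  if (!is.null(components$gd_real)) {
    d_global <- hinge_d_loss(components$gd_real, components$gd_fake)
    g_adv <- g_adv + hinge_g_loss(components$gd_fake)
  }
  if (!is.null(components$ld_real)) {
    d_local <- hinge_d_loss(components$ld_real, components$ld_fake)
    g_adv <- g_adv + hinge_g_loss(components$ld_fake)
  }
  if (!is.null(components$seg_pred))
    s <- seg_loss(components$seg_pred, components$seg_label)
  l1 <- if (is.null(components$g_l1_total)) 0 else components$g_l1_total
  list(d_global = d_global, d_local = d_local, s = s,
       g = weights$lambda_adv * g_adv + l1)
}
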