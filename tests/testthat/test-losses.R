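# Loss algebra: hinge forms, segmentation loss, curriculum schedule, the
# seven-term generator objective, total objective composition.

test_that("hinge discriminator loss reproduces hand arithmetic and the min(0, .) form", {
  expect_equal(hinge_d_loss(matrix(1, 8, 8), matrix(-1, 8, 8)), 0)
  expect_equal(hinge_d_loss(matrix(0, 8, 8), matrix(0, 8, 8)), 2)
  set.seed(31)
  for (rep in 1:1000) {
    r <- matrix(stats::rnorm(16, sd = 2), 4)
    f <- matrix(stats::rnorm(16, sd = 2), 4)
    literal <- -mean(pmin(0, -1 + r)) - mean(pmin(0, -1 - f))
    expect_equal(hinge_d_loss(r, f), literal, tolerance = 1e-12)
  }
})

test_that("generator hinge loss is the negated mean and is linear", {
  expect_equal(hinge_g_loss(matrix(0, 4, 4)), 0)
  expect_equal(hinge_g_loss(matrix(3, 4, 4)), -3)
  set.seed(32)
  for (rep in 1:20) {
    s <- matrix(stats::rnorm(64), 8)
    a <- stats::runif(1, -3, 3)
    expect_equal(hinge_g_loss(a * s), a * hinge_g_loss(s), tolerance = 1e-12)
  }
})

test_that("segmentation loss: perfect, constant and disjoint predictions", {
  lab <- matrix(0, 8, 8); lab[3:6, 3:6] <- 1
  near <- pmin(pmax(lab, 1e-9), 1 - 1e-9)
  expect_lt(seg_loss(near, lab), 1e-6)           # BCE -> 0, Dice -> 0
  half <- matrix(0.5, 8, 8)
  lab_half <- matrix(rep(c(0, 1), each = 32), 8)
  bce_part <- seg_loss(half, lab_half) -
    (1 - (2 * sum(lab_half * half) + 1e-6) /
       (sum(lab_half) + sum(half) + 1e-6))
  expect_equal(bce_part, log(2), tolerance = 1e-9)
  disjoint <- matrix(0, 8, 8); disjoint[1, 1:2] <- 1
  lab2 <- matrix(0, 8, 8); lab2[8, 7:8] <- 1
  dice_part <- seg_loss(disjoint, lab2) - bce_loss(disjoint, lab2)
  expect_equal(dice_part, 1 - 1e-6 / (4 + 1e-6), tolerance = 1e-9)
  expect_error(seg_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("curriculum weight is min(5 epoch, 100), exhaustively over 0..200", {
  expect_equal(curriculum_lambda(4), 20)
  expect_equal(curriculum_lambda(20), 100)
  expect_equal(curriculum_lambda(50), 100)
  e <- 0:200
  expect_equal(curriculum_lambda(e), pmin(5 * e, 100))
  expect_true(all(diff(curriculum_lambda(e)) >= 0))
  expect_error(curriculum_lambda(-1), "nonnegative")
})

test_that("generator L1 objective vanishes at identity and scales hand examples", {
  fx <- tiny_phantom_pairs(1, image_size = 32, seed = 33)
  p <- fx$pairs[[1]]
  out <- generator_l1_loss(p, p$ce, weights = loss_weights(), epoch = 2,
                           patch_size = 8)
  expect_equal(out$terms[["global_l1"]], 0)
  expect_equal(out$terms[["edge_l1"]], 0)
  expect_equal(out$terms[["patch_l1"]], 0)
  expect_equal(out$terms[["patch_edge_l1"]], 0)
  expect_equal(out$total, 0)
  # constant offset: term 1 = lambda_global * 0.1 = 30
  shifted <- p$ce + 0.1
  out2 <- generator_l1_loss(p, shifted, epoch = 2, patch_size = 8)
  expect_equal(out2$terms[["global_l1"]], 0.1, tolerance = 1e-12)
  expect_equal(300 * out2$terms[["global_l1"]], 30)
  expect_equal(out2$lambda_curr, 10)
})

test_that("all seven terms match a brute-force recomputation with stub networks", {
  set.seed(34)
  n <- 16
  pre <- matrix(stats::rnorm(n * n, sd = 0.4), n)
  ce <- matrix(stats::rnorm(n * n, sd = 0.4), n)
  mask <- disk_mask(n, c(8, 9), 3)
  pair <- slice_pair(pmin(pmax(pre, -1), 1), pmin(pmax(ce, -1), 1), mask)
  synth <- pmin(pmax(ce + 0.05 * matrix(stats::rnorm(n * n), n), -1), 1)
  ps <- 8L
  S <- build_segmentor(segmentor_config(n, 4, depth = 2))
  GD <- build_discriminator(discriminator_config(n, 2, 4))
  LD <- build_discriminator(discriminator_config(ps, 1, 4))
  w <- loss_weights()
  epoch <- 3
  out <- generator_l1_loss(pair, synth, S = S, GD = GD, LD = LD,
                           weights = w, epoch = epoch, patch_size = ps)

  # independent recomputation
  l1 <- function(a, b) mean(abs(a - b))
  win <- tsgan:::tumor_window(mask, ps)
  cropw <- function(m) m[win[1]:(win[1] + ps - 1), win[2]:(win[2] + ps - 1)]
  sy <- network_forward(S, pair$ce)[, , 1, 1]
  sf <- network_forward(S, synth)[, , 1, 1]
  din <- function(cand) abind4(
    array(pair$pre, c(n, n, 1, 1)),
    array(edge_binarize(edge_soft(pair$pre)), c(n, n, 1, 1)),
    array(cand, c(n, n, 1, 1)),
    array(edge_binarize(edge_soft(cand)), c(n, n, 1, 1)))
  dinp <- function(cand) abind4(
    array(cropw(pair$pre), c(ps, ps, 1, 1)),
    array(edge_binarize(edge_soft(cropw(pair$pre))), c(ps, ps, 1, 1)),
    array(cand, c(ps, ps, 1, 1)),
    array(edge_binarize(edge_soft(cand)), c(ps, ps, 1, 1)))
  expected <- c(
    global_l1 = l1(pair$ce, synth),
    edge_l1 = l1(edge_soft(pair$ce), edge_soft(synth)),
    patch_l1 = l1(cropw(pair$ce), cropw(synth)),
    seg_masked_l1 = l1(sy * pair$ce, sf * synth),
    patch_edge_l1 = l1(edge_soft(cropw(pair$ce)), edge_soft(cropw(synth))),
    gd_fm = l1(network_forward(GD, din(pair$ce))$features,
               network_forward(GD, din(synth))$features),
    ld_fm = l1(network_forward(LD, dinp(cropw(pair$ce)))$features,
               network_forward(LD, dinp(cropw(synth)))$features))
  for (nm in names(expected))
    expect_equal(out$terms[[nm]], expected[[nm]], tolerance = 1e-6,
                 label = nm)
  lam <- curriculum_lambda(epoch, w)
  total_expected <- w$lambda_global * expected["global_l1"] +
    w$lambda_edge * expected["edge_l1"] + lam * expected["patch_l1"] +
    lam * expected["seg_masked_l1"] +
    w$lambda_edge * expected["patch_edge_l1"] +
    w$lambda_fm * expected["gd_fm"] + w$lambda_fm * expected["ld_fm"]
  expect_equal(out$total, as.numeric(total_expected), tolerance = 1e-6)
})

test_that("total objective composes parties linearly and respects lambda_adv", {
  set.seed(35)
  comp <- list(gd_real = matrix(stats::rnorm(16), 4),
               gd_fake = matrix(stats::rnorm(16), 4),
               ld_real = matrix(stats::rnorm(16), 4),
               ld_fake = matrix(stats::rnorm(16), 4),
               seg_pred = matrix(stats::runif(16), 4),
               seg_label = matrix(rep(c(0, 1), 8), 4),
               g_l1_total = 12.5)
  w <- loss_weights()
  obj <- total_objective(comp, w)
  expect_equal(obj$d_global, hinge_d_loss(comp$gd_real, comp$gd_fake))
  expect_equal(obj$s, seg_loss(comp$seg_pred, comp$seg_label))
  adv <- hinge_g_loss(comp$gd_fake) + hinge_g_loss(comp$ld_fake)
  expect_equal(obj$g, 5 * adv + 12.5)
  w2 <- loss_weights(lambda_adv = 10)
  obj2 <- total_objective(comp, w2)
  expect_equal(obj2$g - 12.5, 2 * (obj$g - 12.5))
  # zero components give a zero generator objective
  z <- total_objective(list(gd_fake = matrix(0, 2, 2),
                            gd_real = matrix(1, 2, 2), g_l1_total = 0), w)
  expect_equal(z$g, 0)
})
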