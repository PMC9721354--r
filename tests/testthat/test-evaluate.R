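# Evaluation: four-metric suite on whole FOV and tumor crops, profiles,
# error maps, permutation tests.

test_that("metric identities hold for identical and shifted images", {
  set.seed(41)
  img <- matrix(stats::rnorm(32 * 32), 32)
  m <- disk_mask(32, c(16, 16), 4)
  rows <- metric_suite(img, img, m, patch_size = 16)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$nrmse, c(0, 0))
  expect_equal(rows$ssim, c(1, 1), tolerance = 1e-9)
  expect_equal(rows$cc, c(1, 1), tolerance = 1e-12)
  expect_true(all(is.infinite(rows$psnr_db)))
  shifted <- metric_suite(img, img + 0.3, m, patch_size = 16)
  expect_equal(shifted$cc, c(1, 1), tolerance = 1e-12)
  expect_true(all(shifted$nrmse > 0))
})

test_that("constant targets are flagged undefined rather than silently zero", {
  flat <- matrix(1, 16, 16)
  other <- matrix(stats::rnorm(256), 16)
  expect_true(is.na(nrmse(flat, other)))
  expect_true(is.na(psnr(flat, other)))
  expect_true(is.na(ssim(flat, other)))
  expect_true(is.na(pearson_cc(flat, other)))
})

test_that("the four metrics match an independent brute-force computation", {
  # 4x4 hand example: two-level target, synthesized off by 0.5 on one quadrant
  target <- rbind(matrix(0, 2, 4), matrix(1, 2, 4))
  synth <- target
  synth[1:2, 1:2] <- synth[1:2, 1:2] + 0.5
  expect_equal(nrmse(target, synth),
               100 * sqrt(4 * 0.25 / 16) / 1, tolerance = 1e-12)
  expect_equal(psnr(target, synth), 10 * log10(1 / (4 * 0.25 / 16)),
               tolerance = 1e-12)
  expect_equal(pearson_cc(target, synth),
               stats::cor(as.vector(target), as.vector(synth)),
               tolerance = 1e-12)
  # SSIM against a literal reimplementation (3x3 window on a 4x4 image)
  w <- tsgan:::gaussian_window(3, 1.5)
  vals <- c()
  for (i in 1:2) for (j in 1:2) {
    tw <- target[i:(i + 2), j:(j + 2)]; sw <- synth[i:(i + 2), j:(j + 2)]
    mu1 <- sum(w * tw); mu2 <- sum(w * sw)
    v1 <- sum(w * tw^2) - mu1^2; v2 <- sum(w * sw^2) - mu2^2
    cv <- sum(w * tw * sw) - mu1 * mu2
    C1 <- 0.01^2; C2 <- 0.03^2
    vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
                ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2)))
  }
  expect_equal(ssim(target, synth), mean(vals), tolerance = 1e-12)
})

test_that("tumor metrics on crops equal whole-image metrics for centered 64x64 input", {
  set.seed(42)
  t64 <- matrix(stats::rnorm(64 * 64), 64)
  s64 <- t64 + 0.1 * matrix(stats::rnorm(64 * 64), 64)
  m <- disk_mask(64, c(33, 33), 5)
  rows <- metric_suite(t64, s64, m, patch_size = 64)
  expect_equal(rows$nrmse[1], rows$nrmse[2])
  expect_equal(rows$ssim[1], rows$ssim[2])
  expect_equal(rows$cc[1], rows$cc[2])
})

test_that("aggregates equal brute-force recomputation from per-slice rows", {
  set.seed(43)
  rows <- do.call(rbind, lapply(1:6, function(i) {
    t <- matrix(stats::rnorm(256), 16)
    s <- t + 0.2 * matrix(stats::rnorm(256), 16)
    metric_suite(t, s, disk_mask(16, c(8, 8), 3), patch_size = 8,
                 slice = i)
  }))
  agg <- aggregate_metrics(rows)
  whole <- rows[rows$region == "whole", ]
  expect_equal(agg$mean[agg$region == "whole" & agg$metric == "nrmse"],
               mean(whole$nrmse))
  expect_equal(agg$sd[agg$region == "whole" & agg$metric == "cc"],
               stats::sd(whole$cc))
})

test_that("intensity profile is the centroid column and error maps are signed", {
  img <- matrix(seq_len(20 * 20), 20)
  m <- disk_mask(20, c(9, 13), 2)
  prof <- intensity_profile(img, m)
  expect_length(prof, 20)
  expect_equal(prof, img[, 13])
  expect_equal(intensity_profile(matrix(2, 10, 10), disk_mask(10, c(5, 5), 2)),
               rep(2, 10))
  a <- matrix(stats::rnorm(16), 4); b <- matrix(stats::rnorm(16), 4)
  em <- error_map(a, b)
  expect_equal(em, a - b)
  expect_equal(mean(em), mean(a) - mean(b))
  expect_equal(which.max(abs(em)), which.max(abs(a - b)))
})

test_that("permutation test: exact null, exhaustive enumeration and calibration", {
  a <- stats::rnorm(12)
  expect_equal(paired_permutation_test(a, a, n_perm = 200, seed = 1), 1)
  expect_error(paired_permutation_test(1:3, 1:4), "equal length")
  # n = 10: Monte-Carlo p matches exhaustive sign enumeration within 0.02
  set.seed(44)
  x <- stats::rnorm(10, mean = 0.4)
  y <- stats::rnorm(10)
  d <- x - y
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  t_all <- abs(signs %*% d) / 10
  p_exact <- (1 + sum(t_all >= abs(mean(d)) - 1e-12)) / (1 + nrow(signs))
  p_mc <- paired_permutation_test(x, y, n_perm = 10000, seed = 2)
  expect_lt(abs(p_mc - p_exact), 0.02)
  # calibration: p-values uniform under a symmetric null
  set.seed(45)
  ps <- replicate(500, {
    d0 <- stats::rnorm(15)
    paired_permutation_test(d0, rep(0, 15), n_perm = 199)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))  # discrete p grid ties
  expect_gt(ks$p.value, 0.01)
})
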