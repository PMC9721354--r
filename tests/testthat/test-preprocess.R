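# Preprocessing: resampling, slice selection, normalization, augmentation,
# tumor-centered cropping.

test_that("resampling at native spacing is an identity and preserves constants", {
  v <- tsgan_volume(array(0.7, c(12, 12, 6)), c(1, 1, 1), "preT1")
  out <- resample_isotropic(v, 1)
  expect_equal(dim(out$data), c(12L, 12L, 6L))
  expect_equal(out$data, v$data, tolerance = 1e-12)
  # anisotropic constant volume stays constant after cubic interpolation
  v2 <- tsgan_volume(array(1.3, c(10, 10, 4)), c(1, 1, 2.5), "ceT1")
  out2 <- resample_isotropic(v2, 1)
  expect_equal(dim(out2$data), c(10L, 10L, 10L))
  expect_equal(max(abs(out2$data - 1.3)), 0, tolerance = 1e-9)
})

test_that("2 mm to 1 mm resampling doubles each axis extent", {
  v <- tsgan_volume(array(stats::runif(8 * 8 * 8), c(8, 8, 8)),
                    rep(2, 3), "preT1")
  out <- resample_isotropic(v, 1)
  expect_equal(dim(out$data), c(16L, 16L, 16L))
  m <- tsgan_volume((array(stats::runif(8^3), c(8, 8, 8)) > 0.5) * 1,
                    rep(2, 3), "mask")
  mo <- resample_isotropic(m, 1)
  expect_true(all(mo$data %in% c(0, 1)))
})

test_that("tumor slice selection equals a brute-force per-slice scan", {
  set.seed(42)
  m <- array(0, c(10, 10, 8))
  m[4:6, 4:6, 3:5] <- 1
  expect_equal(select_tumor_slices(tsgan_volume(m, rep(1, 3), "mask")), 3:5)
  expect_equal(select_tumor_slices(tsgan_volume(array(0, c(4, 4, 4)),
                                                rep(1, 3), "mask")),
               integer(0))
  r <- array(stats::rbinom(10 * 10 * 8, 1, 0.02), c(10, 10, 8))
  oracle <- which(sapply(1:8, function(s) any(r[, , s] > 0)))
  expect_equal(select_tumor_slices(r), oracle)
})

test_that("normalizer clips at the training ceT1 maximum and maps onto [-1, 1]", {
  s1 <- matrix(c(0, 1, 3), 1); s2 <- matrix(c(2, 7.5), 1)
  spec <- fit_normalizer(list(s1, s2))
  expect_equal(spec$clip_max, 7.5)
  expect_equal(apply_normalizer(7.5, spec), 1)
  expect_equal(apply_normalizer(0, spec), -1)
  expect_equal(apply_normalizer(7.5 / 2, spec), 0)
  expect_equal(apply_normalizer(15, spec), 1)          # clipped
  expect_error(apply_normalizer(-0.1, spec), "nonnegative")
  expect_error(fit_normalizer(list()), "at least one")
  # round trip below the clip level is exact
  x <- matrix(stats::runif(64, 0, 7.5), 8)
  expect_equal(invert_normalizer(apply_normalizer(x, spec), spec), x,
               tolerance = 1e-12)
  # brute-force maximum oracle
  expect_equal(spec$clip_max, max(c(s1, s2)))
})

test_that("flip augmentation is an involution applied identically to all channels", {
  fx <- tiny_phantom_pairs(1, image_size = 24, seed = 3)
  p <- fx$pairs[[1]]
  f2 <- augment_flip(augment_flip(p, force = TRUE), force = TRUE)
  expect_identical(f2$pre, p$pre)
  expect_identical(f2$mask, p$mask)
  f1 <- augment_flip(p, force = TRUE)
  ctr0 <- tsgan:::mask_centroid(p$mask, round_result = FALSE)
  ctr1 <- tsgan:::mask_centroid(f1$mask, round_result = FALSE)
  expect_equal(ctr1[[1]], nrow(p$mask) + 1 - ctr0[[1]])
  # marker pattern: geometric transform identical across channels
  expect_identical(f1$pre[1, ], p$pre[nrow(p$pre), ])
  expect_identical(f1$ce[1, ], p$ce[nrow(p$ce), ])
})

test_that("random flips occur at frequency 0.5", {
  fx <- tiny_phantom_pairs(1, image_size = 24, seed = 4)
  p <- fx$pairs[[1]]
  set.seed(77)
  flips <- replicate(10000, !identical(augment_flip(p)$pre, p$pre))
  expect_lt(abs(mean(flips) - 0.5), 0.02)
})

test_that("tumor patch window arithmetic, clamping and content are exact", {
  img <- matrix(stats::rnorm(256 * 256), 256)
  m <- disk_mask(256, c(129, 129), 5)     # centroid 129 (0-based 128)
  p <- crop_tumor_patch(img, m, 64)
  expect_identical(p, img[97:160, 97:160])  # 0-based rows 96..159
  m2 <- disk_mask(256, c(6, 6), 3)
  p2 <- crop_tumor_patch(img, m2, 64)
  expect_identical(p2, img[1:64, 1:64])     # clamped to the corner
  expect_equal(dim(p2), c(64L, 64L))
  # window oracle on the mask itself
  pm <- crop_tumor_patch(m, m, 64)
  w <- tsgan:::tumor_window(m, 64)
  expect_equal(sum(pm), sum(m[w[1]:(w[1] + 63), w[2]:(w[2] + 63)]))
  expect_error(crop_tumor_patch(img, matrix(0, 256, 256), 64), "empty")
})

test_that("slice pairs are normalized, resized and keep nonempty masks", {
  fx <- tiny_phantom_pairs(2, image_size = 24, seed = 6)
  sub <- fx$subjects[[1]]
  pairs <- make_slice_pairs(sub$pre, sub$ce, sub$mask, fx$spec, size = 32,
                            subject_id = "a")
  expect_gt(length(pairs), 0)
  for (p in pairs[1:2]) {
    expect_equal(dim(p$pre), c(32L, 32L))
    expect_true(all(p$pre >= -1 & p$pre <= 1))
    expect_true(all(p$mask %in% c(0, 1)))
    expect_gte(sum(p$mask), 1)
  }
})
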