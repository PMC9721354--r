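# Dual-region evaluation: NRMSE, PSNR, SSIM and Pearson correlation on the
# whole field of view and on tumor-centered crops, plus intensity
# profiles, signed error maps and paired permutation tests.

#' Normalized root-mean-square error
#'
#' `100 * RMSE / norm`, where the normalizer is the target dynamic range
#' (default), the target mean, or the target Euclidean norm.
#'
#' @param target,synthesized numeric arrays of equal shape.
#' @param normalization one of `"range"`, `"mean"`, `"euclidean"`.
#' @return scalar; `NA` if the chosen normalizer is zero.
#' @export
nrmse <- function(target, synthesized,
                  normalization = c("range", "mean", "euclidean")) {
  normalization <- match.arg(normalization)
  rmse <- sqrt(mean((target - synthesized)^2))
  denom <- switch(normalization,
                  range = diff(range(target)),
                  mean = mean(target),
                  euclidean = sqrt(mean(target^2)))
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  100 * rmse / denom
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(R^2 / MSE)`; identical images give `Inf`.
#'
#' @param target,synthesized numeric arrays of equal shape.
#' @param dynamic_range peak-to-peak reference `R`; defaults to the
#'   target's own range (`NA` if constant). Use 2 for \[-1, 1\] data.
#' @return scalar dB value.
#' @export
psnr <- function(target, synthesized, dynamic_range = NULL) {
  R <- if (is.null(dynamic_range)) diff(range(target)) else dynamic_range
  if (!is.finite(R) || R == 0) return(NA_real_)
  mse <- mean((target - synthesized)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

gaussian_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- outer(stats::dnorm(-half:half, sd = sigma),
             stats::dnorm(-half:half, sd = sigma))
  g / sum(g)
}

#' Structural similarity index
#'
#' Mean local SSIM with a Gaussian window (default 11x11, sigma 1.5),
#' stabilizers `K1 = 0.01`, `K2 = 0.03`, computed over valid window
#' positions. The window shrinks to the image when the image is smaller
#' than 11 pixels.
#'
#' @param target,synthesized numeric matrices of equal shape.
#' @param dynamic_range reference `L`; defaults to the target range.
#' @param K1,K2 stabilizer constants.
#' @param window_size,sigma Gaussian window parameters.
#' @return scalar in \[-1, 1\]; `NA` for a constant target with no
#'   explicit dynamic range.
#' @export
ssim <- function(target, synthesized, dynamic_range = NULL, K1 = 0.01,
                 K2 = 0.03, window_size = 11L, sigma = 1.5) {
  L <- if (is.null(dynamic_range)) diff(range(target)) else dynamic_range
  if (!is.finite(L) || L == 0) return(NA_real_)
  ws <- min(window_size, dim(target))
  if (ws %% 2 == 0) ws <- ws - 1L
  g <- gaussian_window(ws, sigma)
  gw <- array(g, dim = c(ws, ws, 1L, 1L))
  filt <- function(m) {
    a <- array(m, dim = c(dim(m), 1L, 1L))
    cpp_conv2d_fw(a, gw, 0, 1L, 0L)[, , 1, 1]
  }
  mu1 <- filt(target); mu2 <- filt(synthesized)
  s11 <- filt(target^2) - mu1^2
  s22 <- filt(synthesized^2) - mu2^2
  s12 <- filt(target * synthesized) - mu1 * mu2
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
}

#' Pearson correlation over pixels
#'
#' @param target,synthesized numeric arrays of equal shape.
#' @return scalar in \[-1, 1\]; `NA` when either image is constant.
#' @export
pearson_cc <- function(target, synthesized) {
  if (stats::sd(target) == 0 || stats::sd(synthesized) == 0) return(NA_real_)
  stats::cor(as.vector(target), as.vector(synthesized))
}

#' Dual-region metric suite
#'
#' Computes NRMSE, PSNR, SSIM and Pearson correlation for the whole field
#' of view and for tumor-centered crops of side `patch_size`.
#'
#' @param target,synthesized matrices of equal shape (normalized units).
#' @param mask binary tumor mask (same shape, nonempty for the tumor row).
#' @param patch_size crop side for the tumor region.
#' @param subject,slice identifiers carried into the rows.
#' @param nrmse_normalization passed to [nrmse()].
#' @param dynamic_range optional fixed range for PSNR/SSIM (e.g. 2 for
#'   \[-1, 1\] data); default uses each region's target range.
#' @return data.frame with rows `whole` and `tumor`.
#' @export
metric_suite <- function(target, synthesized, mask, patch_size = 64L,
                         subject = "subject", slice = 1L,
                         nrmse_normalization = "range",
                         dynamic_range = NULL) {
  stopifnot(identical(dim(target), dim(synthesized)))
  one <- function(t, s, region) {
    data.frame(subject = subject, slice = slice, region = region,
               nrmse = nrmse(t, s, nrmse_normalization),
               psnr_db = psnr(t, s, dynamic_range),
               ssim = ssim(t, s, dynamic_range),
               cc = pearson_cc(t, s))
  }
  rows <- one(target, synthesized, "whole")
  if (sum(mask) >= 1) {
    tp <- crop_tumor_patch(target, mask, patch_size)
    sp <- crop_tumor_patch(synthesized, mask, patch_size)
    rows <- rbind(rows, one(tp, sp, "tumor"))
  }
  rows
}

#' Aggregate per-slice metrics
#'
#' @param df data.frame of [metric_suite()] rows.
#' @return data.frame of mean and standard deviation per region/metric.
#' @export
aggregate_metrics <- function(df) {
  num <- c("nrmse", "psnr_db", "ssim", "cc")
  do.call(rbind, lapply(split(df, df$region), function(d) {
    data.frame(region = d$region[1],
               metric = num,
               mean = vapply(num, function(m)
                 mean(d[[m]][is.finite(d[[m]])]), 0),
               sd = vapply(num, function(m)
                 stats::sd(d[[m]][is.finite(d[[m]])]), 0),
               row.names = NULL)
  }))
}

#' Vertical intensity profile through the tumor center
#'
#' @param img matrix.
#' @param mask nonempty binary mask locating the tumor.
#' @return numeric vector of length `nrow(img)`: the image column at the
#'   tumor centroid.
#' @export
intensity_profile <- function(img, mask) {
  ctr <- mask_centroid(mask)
  img[, ctr[2]]
}

#' Signed error map
#'
#' @param target,synthesized matrices of equal shape.
#' @return `target - synthesized`.
#' @export
error_map <- function(target, synthesized) {
  stopifnot(identical(dim(target), dim(synthesized)))
  target - synthesized
}

#' Paired permutation test by sign flipping
#'
#' Two-sided test of the mean paired difference: under the null the sign
#' of each paired difference is exchangeable, so the observed mean is
#' compared with `n_perm` random sign-flipped means;
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`.
#'
#' @param metric_a,metric_b equal-length paired per-slice metric vectors.
#' @param n_perm number of permutations (>= 100).
#' @param seed optional seed for the flips.
#' @return the two-sided p-value.
#' @export
paired_permutation_test <- function(metric_a, metric_b, n_perm = 10000L,
                                    seed = NULL) {
  if (length(metric_a) != length(metric_b))
    stop("paired vectors must have equal length")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  d <- metric_a - metric_b
  t_obs <- abs(mean(d))
  n <- length(d)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    if (abs(mean(signs * d)) >= t_obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}
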