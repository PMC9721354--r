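# Sobel edge maps: the normalized sum of the magnitudes of the horizontal
# and vertical Sobel responses, normalized by the per-image maximum so the
# fixed binarization threshold stays meaningful across slices of differing
# dynamic range. Borders are reflect-padded.

sobel_kernels <- function() {
  kx <- cbind(c(-1, -2, -1), c(0, 0, 0), c(1, 2, 1))
  w <- array(0, dim = c(3, 3, 1, 2))
  w[, , 1, 1] <- kx
  w[, , 1, 2] <- t(kx)
  w
}

#' Soft Sobel edge map
#'
#' Computes `(|Sobel_h| + |Sobel_v|) / max(.)` with reflective border
#' padding; the maximum is taken per image, and an all-constant image maps
#' to an all-zero edge map.
#'
#' @param img 2D numeric matrix.
#' @return matrix of the same size with values in \[0, 1\].
#' @export
edge_soft <- function(img) {
  stopifnot(is.matrix(img))
  x <- array(img, dim = c(dim(img), 1L, 1L))
  H <- dim(img)[1]; W <- dim(img)[2]
  p <- x[c(2L, seq_len(H), H - 1L), c(2L, seq_len(W), W - 1L), , , drop = FALSE]
  g <- cpp_conv2d_fw(p, sobel_kernels(), c(0, 0), 1L, 0L)
  soft <- abs(g[, , 1, 1]) + abs(g[, , 2, 1])
  m <- max(soft)
  if (m > 0) soft <- soft / m
  soft
}

#' Binarize a soft edge map
#'
#' @param soft matrix in \[0, 1\].
#' @param threshold scalar in (0, 1); pixels with `soft >= threshold`
#'   become 1.
#' @return binary matrix.
#' @export
edge_binarize <- function(soft, threshold = 0.4) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  (soft >= threshold) * 1
}

#' Soft and binarized edge maps of a slice
#'
#' @param img 2D numeric matrix.
#' @param threshold binarization threshold.
#' @return list of class `tsgan_edge_map` with `soft`, `binary`,
#'   `threshold`.
#' @export
edge_map <- function(img, threshold = 0.4) {
  soft <- edge_soft(img)
  structure(list(soft = soft, binary = edge_binarize(soft, threshold),
                 threshold = threshold),
            class = "tsgan_edge_map")
}

# Differentiable batched soft edge map [H,W,1,N] -> [H,W,1,N]; per-sample
# max treated as a constant during backprop.
ag_sobel_soft <- function(x) {
  g <- ag_conv2d(ag_pad_reflect1(x), ag_const(sobel_kernels()),
                 ag_const(c(0, 0)), 1L, 0L, single = FALSE)
  a <- ag_sum_channels(ag_abs(g))
  d <- dim(a$value)
  m <- apply(a$value, 4, max)
  ag_div_per_sample(a, pmax(m, 1e-12))
}
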