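# Preprocessing: isotropic resampling, tumor-slice selection, intensity
# normalization (clip to the training-set ceT1 maximum, then linear map to
# [-1, 1]), flip augmentation, and tumor-centered patch extraction.

#' Resample a volume to isotropic spacing
#'
#' Images are interpolated with a separable cubic (Keys) kernel; masks use
#' nearest-neighbour interpolation and remain binary. Output extents are
#' `round(n * spacing / target)` per axis.
#'
#' @param v a [tsgan_volume()].
#' @param target_spacing target isotropic spacing in mm.
#' @return a resampled [tsgan_volume()].
#' @export
resample_isotropic <- function(v, target_spacing = 1) {
  stopifnot(inherits(v, "tsgan_volume"))
  if (any(!is.finite(v$spacing)) || any(v$spacing <= 0))
    stop("volume spacing must be known and positive")
  method <- if (v$modality == "mask") "nearest" else "cubic"
  out <- cpp_resample3d(v$data, v$spacing, target_spacing, method)
  # cubic interpolation may overshoot slightly; magnitudes stay nonnegative
  out <- if (v$modality == "mask") (out >= 0.5) * 1 else pmax(out, 0)
  tsgan_volume(out, rep(target_spacing, 3), v$modality)
}

#' Indices of slices containing tumor
#'
#' @param mask a binary mask [tsgan_volume()] or 3D array.
#' @return ascending integer vector of axial (third-axis) indices whose
#'   slice has at least one positive pixel; empty if the mask is empty.
#' @export
select_tumor_slices <- function(mask) {
  m <- if (inherits(mask, "tsgan_volume")) mask$data else mask
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  which(apply(m, 3, function(s) any(s > 0)))
}

#' Fit the intensity normalizer
#'
#' The clip level is the global maximum over all training-set ceT1 slices;
#' the same specification is then applied to both preT1 and ceT1 so
#' cross-phase enhancement is preserved.
#'
#' @param training_ce_slices list of 2D slices (or arrays) of nonnegative
#'   ceT1 intensities.
#' @return list of class `normalization_spec` with element `clip_max`.
#' @export
fit_normalizer <- function(training_ce_slices) {
  if (length(training_ce_slices) == 0) stop("need at least one ceT1 slice")
  clip_max <- max(vapply(training_ce_slices, max, 0))
  if (clip_max <= 0) stop("ceT1 maximum must be positive")
  structure(list(clip_max = clip_max), class = "normalization_spec")
}

#' Apply the intensity normalizer
#'
#' Maps `img` to `2 * min(img, clip_max) / clip_max - 1`, i.e. linearly
#' onto \[-1, 1\] with clipping at the training ceT1 maximum.
#'
#' @param img nonnegative numeric array.
#' @param spec a `normalization_spec` from [fit_normalizer()].
#' @return array of the same shape in \[-1, 1\].
#' @export
apply_normalizer <- function(img, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  if (any(img < 0)) stop("raw intensities must be nonnegative")
  2 * pmin(img, spec$clip_max) / spec$clip_max - 1
}

#' Invert the intensity normalizer
#'
#' Exact inverse of [apply_normalizer()] for intensities below the clip
#' level.
#'
#' @param img array in \[-1, 1\].
#' @param spec a `normalization_spec`.
#' @return array of raw intensities.
#' @export
invert_normalizer <- function(img, spec) {
  stopifnot(inherits(spec, "normalization_spec"))
  (img + 1) / 2 * spec$clip_max
}

#' Construct a slice pair
#'
#' @param pre,ce normalized 2D slices in \[-1, 1\].
#' @param mask binary 2D mask with at least one positive pixel.
#' @param subject_id,slice_index identity of the slice.
#' @return list of class `slice_pair`.
#' @export
slice_pair <- function(pre, ce, mask, subject_id = "subject", slice_index = 1L) {
  stopifnot(identical(dim(pre), dim(ce)), identical(dim(pre), dim(mask)))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (sum(mask) < 1) stop("slice pair requires a nonempty tumor mask")
  structure(list(pre = pre, ce = ce, mask = mask, subject_id = subject_id,
                 slice_index = as.integer(slice_index)),
            class = "slice_pair")
}

#' Random vertical flip augmentation
#'
#' With probability 0.5 (drawn from the R random stream) the pair is
#' flipped up-down, identically for pre, ce, and mask.
#'
#' @param pair a [slice_pair()].
#' @param force `NULL` for a random draw, or `TRUE`/`FALSE` to force the
#'   outcome (used in tests and deterministic pipelines).
#' @return the (possibly flipped) pair.
#' @export
augment_flip <- function(pair, force = NULL) {
  do_flip <- if (is.null(force)) stats::runif(1) < 0.5 else isTRUE(force)
  if (!do_flip) return(pair)
  fl <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  pair$pre <- fl(pair$pre)
  pair$ce <- fl(pair$ce)
  pair$mask <- fl(pair$mask)
  pair
}

# centroid of a binary mask: arithmetic mean of pixel coordinates,
# rounded half-up (1-based)
mask_centroid <- function(mask, round_result = TRUE) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0) stop("mask is empty")
  ctr <- colMeans(w)
  if (round_result) floor(ctr + 0.5) else ctr
}

# 1-based start (row, col) of the size x size window centered on the mask
# centroid, clamped inside the image
tumor_window <- function(mask, size) {
  d <- dim(mask)
  ctr <- mask_centroid(mask)
  start <- ctr - size %/% 2
  pmin(pmax(start, 1), d - size + 1)
}

#' Tumor-centered patch
#'
#' Extracts the `size x size` window centered on the tumor-mask centroid
#' (arithmetic mean of mask coordinates, rounded half-up), clamping the
#' window inside the image so the patch never needs padding.
#'
#' @param img 2D image the window is read from.
#' @param mask binary mask defining the centroid (same shape).
#' @param size patch side length.
#' @return `size x size` matrix.
#' @export
crop_tumor_patch <- function(img, mask, size = 64L) {
  stopifnot(identical(dim(img), dim(mask)))
  if (any(dim(img) < size)) stop("image smaller than requested patch")
  s <- tumor_window(mask, size)
  img[s[1]:(s[1] + size - 1), s[2]:(s[2] + size - 1), drop = FALSE]
}

#' Build normalized slice pairs from paired volumes
#'
#' Selects tumor-bearing slices, optionally resizes to a square target
#' (bilinear for images, nearest for masks), and normalizes both phases
#' with the supplied specification.
#'
#' @param pre,ce,mask [tsgan_volume()]s of one subject (identical shapes).
#' @param spec a `normalization_spec` (fitted on training ceT1 slices).
#' @param size target side length, or `NULL` to keep the native size.
#' @param subject_id identifier stored in each pair.
#' @return list of [slice_pair()]s.
#' @export
make_slice_pairs <- function(pre, ce, mask, spec, size = NULL,
                             subject_id = "subject") {
  stopifnot(identical(dim(pre$data), dim(ce$data)),
            identical(dim(pre$data), dim(mask$data)))
  idx <- select_tumor_slices(mask)
  lapply(idx, function(s) {
    p <- pre$data[, , s]
    y <- ce$data[, , s]
    m <- mask$data[, , s]
    if (!is.null(size) && !all(dim(p) == size)) {
      p <- cpp_resize2d(p, size, size, "linear")
      y <- cpp_resize2d(y, size, size, "linear")
      m <- (cpp_resize2d(m, size, size, "nearest") >= 0.5) * 1
    }
    if (sum(m) < 1) return(NULL)
    slice_pair(apply_normalizer(p, spec), apply_normalizer(y, spec), m,
               subject_id, s)
  }) -> pairs
  Filter(Negate(is.null), pairs)
}

#' Collect ceT1 tumor slices of a cohort (for normalizer fitting)
#'
#' @param subjects list of subjects as from [phantom_dataset()].
#' @return list of 2D ceT1 slices restricted to tumor-bearing indices.
#' @export
collect_ce_slices <- function(subjects) {
  unlist(lapply(subjects, function(sub) {
    idx <- select_tumor_slices(sub$mask)
    lapply(idx, function(s) sub$ce$data[, , s])
  }), recursive = FALSE)
}
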