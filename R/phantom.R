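# Synthetic breast-MRI phantoms: paired preT1/ceT1 volumes sharing anatomy,
# with a contrast-enhancing textured tumor, mild diffuse background
# enhancement, and additive acquisition noise on the enhanced image. The
# phantom emulates the statistical structure the synthesis network assumes
# (an anatomy/air partition, a single tumor ROI per subject, ceT1 brighter
# than preT1) without claiming pharmacokinetic realism.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom generation parameters
#'
#' Parameters of the paired preT1/ceT1 phantom generator. The contrast
#' model is `ceT1 = E * preT1 + noise`, where the enhancement field `E`
#' equals `tumor_enhancement_ratio` inside the (smoothly bordered) tumor,
#' `background_enhancement_ratio` in breast/chest tissue and 1 in air.
#'
#' @param image_size pixels per side of each square slice.
#' @param n_subjects number of subjects to generate.
#' @param slices_per_subject axial slices per volume.
#' @param tumor_radius_range range (pixels) the spherical tumor radius is
#'   drawn from; default scales with the image so the tumor occupies a
#'   mass-like fraction of the breast (9--19 px at 256, i.e. 0.9--1.9 cm
#'   at 1 mm spacing).
#' @param tumor_enhancement_ratio multiplicative contrast gain inside the
#'   tumor; must exceed `background_enhancement_ratio`.
#' @param background_enhancement_ratio gain in non-tumor tissue; `>= 1`.
#' @param texture_scale correlation length (pixels) of the tissue texture.
#' @param noise_sigma standard deviation of the additive noise on ceT1.
#' @param spacing voxel spacing in mm (isotropic in-plane and through-plane).
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical phantoms.
#'
#' @return a list of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 256L, n_subjects = 10L,
                           slices_per_subject = 12L,
                           tumor_radius_range = NULL,
                           tumor_enhancement_ratio = 2.0,
                           background_enhancement_ratio = 1.1,
                           texture_scale = max(2, round(image_size / 32)),
                           noise_sigma = 0.02, spacing = 1, seed = 1L) {
  if (image_size <= 0 || n_subjects <= 0 || slices_per_subject <= 0)
    stop("image_size, n_subjects and slices_per_subject must be positive")
  if (background_enhancement_ratio < 1)
    stop("background_enhancement_ratio must be >= 1")
  if (tumor_enhancement_ratio < background_enhancement_ratio ||
      (tumor_enhancement_ratio == background_enhancement_ratio &&
       tumor_enhancement_ratio != 1))
    stop("tumor_enhancement_ratio must exceed background_enhancement_ratio ",
         "(identity phantoms with both ratios 1 are the only exception)")
  if (is.null(tumor_radius_range))
    tumor_radius_range <- pmax(3, round(image_size * c(0.035, 0.075)))
  if (any(tumor_radius_range <= 0)) stop("tumor radii must be positive")
  structure(list(image_size = as.integer(image_size),
                 n_subjects = as.integer(n_subjects),
                 slices_per_subject = as.integer(slices_per_subject),
                 tumor_radius_range = tumor_radius_range,
                 tumor_enhancement_ratio = tumor_enhancement_ratio,
                 background_enhancement_ratio = background_enhancement_ratio,
                 texture_scale = texture_scale,
                 noise_sigma = noise_sigma,
                 spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' A simple volume container
#'
#' @param data 3D numeric array (rows, columns, slices).
#' @param spacing voxel spacing in mm per axis (length 3, positive).
#' @param modality one of `"preT1"`, `"ceT1"`, `"mask"`.
#' @return a list of class `tsgan_volume`.
#' @export
tsgan_volume <- function(data, spacing, modality = c("preT1", "ceT1", "mask")) {
  modality <- match.arg(modality)
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(length(dim(data)) == 3L, all(spacing > 0))
  if (modality == "mask" && !all(data %in% c(0, 1)))
    stop("mask volumes must contain only 0/1")
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "tsgan_volume")
}

# smooth band-limited 2D texture, zero mean and unit sd
smooth_texture <- function(H, W, scale) {
  z <- matrix(stats::rnorm(H * W), H, W)
  k <- max(1L, round(scale))
  g <- stats::dnorm(seq(-2 * k, 2 * k), sd = k / 1.5)
  g <- g / sum(g)
  z <- apply(z, 2, function(col) stats::filter(c(rev(col), col, rev(col)),
                                               g, sides = 2)[(H + 1):(2 * H)])
  z <- t(apply(z, 1, function(row) stats::filter(c(rev(row), row, rev(row)),
                                                 g, sides = 2)[(W + 1):(2 * W)]))
  z <- z - mean(z)
  z / max(stats::sd(z), 1e-12)
}

#' Generate one phantom subject
#'
#' Builds paired preT1/ceT1 volumes and a binary tumor mask. The breast is
#' modeled as a half-ellipsoid over a chest-wall band (so the field of view
#' keeps an air background, as in whole-FOV evaluation); tissue carries
#' band-limited texture; the spherical tumor has internal texture and a
#' border smoothed over about 2 pixels lying outside the binary mask, so
#' the mean enhancement over the mask equals the nominal tumor ratio.
#'
#' @param params a [phantom_params()].
#' @param subject_index 1-based subject number (selects the subject's seed).
#' @return list with elements `pre`, `ce`, `mask` ([tsgan_volume]s) and
#'   `subject_id`.
#' @export
generate_subject <- function(params, subject_index = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  H <- params$image_size; W <- params$image_size; S <- params$slices_per_subject
  with_seed(params$seed + 7919L * as.integer(subject_index), {
    # breast half-ellipsoid anchored at the chest wall (bottom rows)
    chest_row <- ceiling(0.9 * H)
    c0 <- W / 2 + stats::runif(1, -0.03, 0.03) * W
    s0 <- (S + 1) / 2
    a_r <- 0.80 * chest_row * stats::runif(1, 0.95, 1.05)
    a_c <- 0.40 * W * stats::runif(1, 0.95, 1.05)
    a_s <- 0.60 * S
    rr <- slice.index(array(0, c(H, W, S)), 1)
    cc <- slice.index(array(0, c(H, W, S)), 2)
    ss <- slice.index(array(0, c(H, W, S)), 3)
    ell <- ((rr - chest_row) / a_r)^2 + ((cc - c0) / a_c)^2 + ((ss - s0) / a_s)^2
    breast <- ell <= 1 & rr <= chest_row
    chest <- rr > chest_row
    tissue <- breast | chest
    pre <- array(0, c(H, W, S))
    for (s in seq_len(S)) {
      tex <- smooth_texture(H, W, params$texture_scale)
      base <- ifelse(chest[, , s], 0.65, 0.5)
      sl <- (base + 0.12 * tex) * tissue[, , s]
      pre[, , s] <- pmax(sl, 0)
    }
    # tumor: sphere fully inside the breast, preferring central candidates
    radius <- stats::runif(1, params$tumor_radius_range[1],
                           params$tumor_radius_range[2])
    fits <- function(ctr) {
      d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2 + ((ss - ctr[3]) * 1)^2
      all(breast[d2 <= (radius + 2)^2])
    }
    center <- c(chest_row - 0.45 * a_r, c0, s0)
    for (try in seq_len(60)) {
      cand <- center + c(stats::runif(1, -0.25, 0.25) * a_r,
                         stats::runif(1, -0.5, 0.5) * a_c,
                         stats::runif(1, -0.3, 0.3) * a_s)
      if (fits(cand)) { center <- cand; break }
    }
    while (!fits(center) && radius > 2) radius <- radius - 1
    d <- sqrt((rr - center[1])^2 + (cc - center[2])^2 + (ss - center[3])^2)
    mask <- (d <= radius) * 1
    # enhancement field: ratio_t on the mask, smooth 2-px shoulder outside it,
    # background ratio elsewhere in tissue, 1 in air
    tum_tex <- array(0, c(H, W, S))
    for (s in seq_len(S)) tum_tex[, , s] <- smooth_texture(H, W, 2)
    tum_tex <- pmax(pmin(tum_tex, 2), -2)
    inside <- mask == 1
    if (any(inside)) tum_tex <- tum_tex - mean(tum_tex[inside])
    rt <- params$tumor_enhancement_ratio
    rb <- params$background_enhancement_ratio
    shoulder <- pmin(pmax((d - radius) / 2, 0), 1)   # 0 on mask -> 1 at +2 px
    blend <- 1 - shoulder^2 * (3 - 2 * shoulder)     # smoothstep down
    E <- ifelse(tissue, rb + (rt - rb) * blend, 1)
    # internal texture amplitude scales with the enhancement excess so the
    # identity phantom (both ratios 1) reproduces preT1 exactly; the
    # texture is mask-mean-centered, keeping the mean enhancement at rt
    E[inside] <- rt * (1 + 0.04 * min(rt - 1, 1) * tum_tex[inside])
    ce <- E * pre
    if (params$noise_sigma > 0)
      ce <- ce + stats::rnorm(length(ce), sd = params$noise_sigma)
    ce <- pmax(ce, 0)
    sp <- rep(params$spacing, 3L)
    list(pre = tsgan_volume(pre, sp, "preT1"),
         ce = tsgan_volume(ce, sp, "ceT1"),
         mask = tsgan_volume(mask, sp, "mask"),
         subject_id = sprintf("phantom%03d", as.integer(subject_index)))
  })
}

#' Generate a full phantom cohort
#'
#' @param params a [phantom_params()].
#' @return list of subjects as returned by [generate_subject()].
#' @export
phantom_dataset <- function(params) {
  lapply(seq_len(params$n_subjects), function(i) generate_subject(params, i))
}

#' Write a phantom cohort to NIfTI files plus a JSON manifest
#'
#' Writes `<id>_preT1.nii.gz`, `<id>_ceT1.nii.gz`, `<id>_mask.nii.gz` per
#' subject and a `manifest.json` listing file paths, subject ids and the
#' tumor centroid (arithmetic mean of mask pixel coordinates, 1-based
#' row/column) for every slice that intersects the tumor.
#'
#' @param subjects list of subjects from [phantom_dataset()].
#' @param directory output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_phantom_dataset <- function(subjects, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(subjects, function(sub) {
    files <- sapply(c("preT1", "ceT1", "mask"), function(mod) {
      file.path(directory, paste0(sub$subject_id, "_", mod, ".nii.gz"))
    })
    vols <- list(preT1 = sub$pre, ceT1 = sub$ce, mask = sub$mask)
    for (mod in names(vols)) {
      v <- vols[[mod]]
      img <- RNifti::asNifti(v$data)
      RNifti::pixdim(img) <- v$spacing
      ok <- tryCatch({ RNifti::writeNifti(img, files[[mod]]); TRUE },
                     error = function(e) e)
      if (!isTRUE(ok))
        stop("failed writing ", files[[mod]], ": ", conditionMessage(ok))
    }
    msk <- sub$mask$data
    sl <- which(apply(msk, 3, sum) > 0)
    centroids <- lapply(sl, function(s) {
      w <- which(msk[, , s] == 1, arr.ind = TRUE)
      list(slice = s, row = mean(w[, 1]), col = mean(w[, 2]))
    })
    list(subject_id = sub$subject_id,
         files = as.list(files),
         spacing = sub$pre$spacing,
         tumor_slices = sl,
         centroids = centroids)
  })
  manifest <- list(n_subjects = length(subjects), subjects = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom cohort written by [write_phantom_dataset()]
#'
#' @param directory directory containing `manifest.json`.
#' @return list of subjects with `pre`, `ce`, `mask` volumes.
#' @export
read_phantom_dataset <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(seq_len(manifest$n_subjects), function(i) {
    entry <- manifest$subjects[i, ]
    sp <- unlist(entry$spacing)
    rd <- function(path, mod) {
      img <- RNifti::readNifti(path)
      arr <- array(as.numeric(img), dim = dim(img))   # drop NIfTI attributes
      tsgan_volume(arr, sp, mod)
    }
    list(pre = rd(entry$files$preT1, "preT1"),
         ce = rd(entry$files$ceT1, "ceT1"),
         mask = rd(entry$files$mask, "mask"),
         subject_id = entry$subject_id)
  })
}
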