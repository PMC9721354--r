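# Shared fixtures: small phantom cohorts and slice pairs built in code.

tiny_phantom_pairs <- function(n_subjects = 4, image_size = 32,
                               slices = 6, seed = 101, noise = 0.02) {
  pp <- phantom_params(image_size = image_size, n_subjects = n_subjects,
                       slices_per_subject = slices, noise_sigma = noise,
                       seed = seed)
  subs <- phantom_dataset(pp)
  spec <- fit_normalizer(collect_ce_slices(subs))
  pairs <- unlist(lapply(subs, function(s)
    make_slice_pairs(s$pre, s$ce, s$mask, spec, subject_id = s$subject_id)),
    recursive = FALSE)
  list(pairs = pairs, spec = spec, subjects = subs, params = pp)
}

# independent brute-force 3x3 cross-correlation with reflective padding
brute_conv3 <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  ref <- function(i, n) if (i < 1) 1 + (1 - i) else if (i > n) n - (i - n) else i
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1)
      acc <- acc + kern[di + 2, dj + 2] * img[ref(i + di, H), ref(j + dj, W)]
    out[i, j] <- acc
  }
  out
}

# stack single-channel [H,W,1,N] arrays along the channel axis
abind4 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(d[1], d[2], length(parts), d[4]))
  for (i in seq_along(parts)) out[, , i, ] <- parts[[i]]
  out
}

# binary disk mask
disk_mask <- function(size, center, radius) {
  rr <- row(matrix(0, size, size)); cc <- col(matrix(0, size, size))
  ((rr - center[1])^2 + (cc - center[2])^2 <= radius^2) * 1
}
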