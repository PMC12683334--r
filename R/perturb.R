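#' Perturbation parameter grid
#'
#' The four perturbation modes and their discrete parameter sets:
#' in-plane translation magnitudes in pixels, in-plane rotation angles,
#' additive-noise multipliers of the estimated native noise level, and the
#' randomized-contour displacement field (smoothing sigma and amplitude,
#' both in voxels). `n_realizations` random combinations are drawn per
#' patient; 60 combinations is the default.
#'
#' @param translations_px set of in-plane shift magnitudes.
#' @param rotations_deg set of in-plane rotation angles (degrees).
#' @param noise_multipliers set of noise-level multipliers.
#' @param contour_smooth_sigma_vox Gaussian sigma of the displacement-field
#'   smoothing, in voxels.
#' @param contour_amplitude_vox RMS displacement of the randomized contour,
#'   in voxels (0 disables contour randomization).
#' @param n_realizations number of random combinations to draw.
#' @return A `perturbation_grid` object.
#' @export
perturbation_grid <- function(translations_px = c(0, 0.4, 0.8),
                              rotations_deg = c(-20, 0, 20),
                              noise_multipliers = c(0, 1, 2, 5),
                              contour_smooth_sigma_vox = 10,
                              contour_amplitude_vox = 1,
                              n_realizations = 60L) {
  if (!length(translations_px) || !length(rotations_deg) ||
      !length(noise_multipliers))
    stopf("all parameter sets must be non-empty")
  if (contour_smooth_sigma_vox <= 0)
    stopf("contour_smooth_sigma_vox must be > 0")
  if (n_realizations < 1) stopf("n_realizations must be >= 1")
  structure(list(translations_px = translations_px,
                 rotations_deg = rotations_deg,
                 noise_multipliers = noise_multipliers,
                 contour_smooth_sigma_vox = contour_smooth_sigma_vox,
                 contour_amplitude_vox = contour_amplitude_vox,
                 n_realizations = as.integer(n_realizations)),
            class = "perturbation_grid")
}

#' Sample random perturbation realizations
#'
#' Each realization combines one independent uniform draw (with
#' replacement) from every parameter set: per-axis in-plane translations,
#' a rotation angle, a noise multiplier, plus fresh seeds for the noise
#' field and the contour displacement field.
#'
#' @param grid a [perturbation_grid()].
#' @param seed RNG seed; the sequence is deterministic given the seed.
#' @return Data frame with one row per realization: `realization`, `tx_px`,
#'   `ty_px`, `angle_deg`, `noise_multiplier`, `noise_seed`, `contour_seed`.
#' @export
sample_realizations <- function(grid, seed = 1L) {
  stopifnot(inherits(grid, "perturbation_grid"))
  n <- grid$n_realizations
  pick <- function(set) set[sample.int(length(set), n, replace = TRUE)]
  with_seed(seed, data.frame(
    realization = seq_len(n),
    tx_px = pick(grid$translations_px),
    ty_px = pick(grid$translations_px),
    angle_deg = pick(grid$rotations_deg),
    noise_multiplier = pick(grid$noise_multipliers),
    noise_seed = sample.int(.Machine$integer.max, n),
    contour_seed = sample.int(.Machine$integer.max, n)))
}

#' Rigid in-plane transform of a volume and its mask
#'
#' Rotates in-plane about the mask centroid, then translates in-plane;
#' the slice direction is left unperturbed (thick-slice convention).
#' The image is resampled with trilinear interpolation; the mask is
#' interpolated linearly and thresholded at 0.5 so it stays binary.
#' The identity transform is a bit-exact no-op.
#'
#' @param vm a [volume_with_mask()].
#' @param tx_px,ty_px in-plane translation in pixels.
#' @param angle_deg in-plane rotation in degrees (|angle| <= 180).
#' @param fill_hu value for voxels sampled outside the grid (air).
#' @return The transformed [volume_with_mask()] on the same grid.
#' @export
rigid_transform <- function(vm, tx_px, ty_px, angle_deg, fill_hu = -1000) {
  stopifnot(inherits(vm, "volume_with_mask"))
  if (abs(angle_deg) > 180) stopf("|angle_deg| must be <= 180")
  if (sum(vm$mask) == 0) stopf("empty mask: no centroid to rotate about")
  if (tx_px == 0 && ty_px == 0 && angle_deg == 0) return(vm)
  d <- dim(vm$image)
  ctr <- mask_centroid(vm)
  th <- angle_deg * pi / 180
  t_idx <- c(tx_px, ty_px, 0)
  if (angle_deg == 0) {
    # pure translation: keep the map exact so integer shifts copy voxels
    M <- diag(3)
    off <- -t_idx
  } else {
    # backward map in index space: src = S^-1 R(-theta) S (dst - c - t) + c
    S <- diag(vm$spacing_mm)
    R <- rbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
    M <- solve(S) %*% R %*% S
    off <- as.numeric(ctr - M %*% (ctr + t_idx))
  }
  img <- affine_sample_cpp(vm$image, d, d, M, off, fill_hu)
  msk <- affine_sample_cpp(array(as.numeric(vm$mask), d), d, d, M, off, 0)
  msk <- array(as.integer(msk >= 0.5), d)
  if (sum(msk) == 0)
    stopf("rigid transform moved the mask out of the grid")
  volume_with_mask(img, msk, vm$spacing_mm, vm$origin_mm)
}

#' Estimate the native acquisition-noise level
#'
#' Robust estimate of the standard deviation of additive white Gaussian
#' noise: the median absolute deviation of a 3D Laplacian (high-pass)
#' residual over interior body voxels, divided by the filter's noise gain
#' `sqrt(42)`. The high-pass step removes constant offsets and slowly
#' varying anatomy; the MAD makes the estimate robust to edges.
#'
#' @param vm a [volume_with_mask()].
#' @param air_threshold_hu voxels above this HU count as body.
#' @return Estimated noise standard deviation in HU.
#' @export
estimate_noise <- function(vm, air_threshold_hu = -300) {
  stopifnot(inherits(vm, "volume_with_mask"))
  d <- dim(vm$image)
  body <- vm$image > air_threshold_hu
  if (sum(body) < 1000)
    stopf("too few body voxels (%d < 1000) for noise estimation", sum(body))
  lap <- array(0, d)
  k <- c(1, -2, 1)
  for (axis in 0:2) lap <- lap + conv_axis_cpp(vm$image, d, k, axis, 0L)
  # interior body voxels: all 6 neighbours are body (edges corrupt the MAD)
  interior <- body
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  shift_ok <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    do.call(`[`, c(list(m), idx))
  }
  for (ax in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift_ok(body, ax, by)
  res <- lap[interior]
  if (!length(res)) stopf("no interior body voxels")
  mad(res) / sqrt(42)
}

#' Add scaled Gaussian noise to the image
#'
#' Adds i.i.d. Gaussian noise with standard deviation
#' `multiplier * sigma_hu` to every voxel. The mask is untouched and a
#' multiplier of 0 returns the input unchanged.
#'
#' @param vm a [volume_with_mask()].
#' @param multiplier noise-level multiplier (>= 0).
#' @param sigma_hu native noise standard deviation in HU (>= 0).
#' @param seed RNG seed.
#' @return The noise-injected [volume_with_mask()].
#' @export
add_noise <- function(vm, multiplier, sigma_hu, seed = 1L) {
  stopifnot(inherits(vm, "volume_with_mask"))
  if (multiplier < 0 || sigma_hu < 0) stopf("multiplier and sigma must be >= 0")
  if (multiplier == 0 || sigma_hu == 0) return(vm)
  d <- dim(vm$image)
  img <- vm$image +
    with_seed(seed, array(rnorm(prod(d), 0, multiplier * sigma_hu), d))
  out <- vm
  out$image <- img
  out
}

# Smoothed, RMS-normalized random displacement field on a region.
# Raw components ~ U(-1,1); the z-component is constant within each slice
# (slice-by-slice contouring convention). Default order: smooth, then
# RMS-normalize, then scale by amplitude. `literal_order` normalizes the
# raw field before smoothing instead.
contour_field <- function(region_dim, smooth_sigma_vox, amplitude_vox, seed,
                          literal_order = FALSE) {
  n <- prod(region_dim)
  with_seed(seed, {
    fx <- array(runif(n, -1, 1), region_dim)
    fy <- array(runif(n, -1, 1), region_dim)
    fz_slice <- runif(region_dim[3], -1, 1)
    fz <- array(rep(fz_slice, each = region_dim[1] * region_dim[2]),
                region_dim)
    norm_rms <- function(a) {
      r <- sqrt(mean(a^2))
      if (r == 0) a else a / r
    }
    proc <- function(a) {
      if (literal_order) {
        gaussian_smooth(norm_rms(a), smooth_sigma_vox) * amplitude_vox
      } else {
        norm_rms(gaussian_smooth(a, smooth_sigma_vox)) * amplitude_vox
      }
    }
    list(dx = proc(fx), dy = proc(fy), dz = proc(fz))
  })
}

#' Randomize the tumour contour
#'
#' Deforms the mask by a smooth random displacement field to mimic
#' inter-observer segmentation variability: per-voxel components are drawn
#' from U(-1, 1) (the z-component constant within each slice), Gaussian
#' smoothed, RMS-normalized per component and scaled to `amplitude_vox`.
#' The mask is backward-warped with linear interpolation and thresholded
#' at 0.5; the image is untouched. Amplitude 0 is a no-op.
#'
#' @param vm a [volume_with_mask()].
#' @param smooth_sigma_vox smoothing sigma of the field, voxels.
#' @param amplitude_vox RMS displacement per component, voxels.
#' @param seed RNG seed for the field.
#' @param literal_order normalize the raw field before smoothing instead of
#'   after (yields near-zero displacements at large sigma; off by default).
#' @return The [volume_with_mask()] with a deformed mask.
#' @export
randomize_contour <- function(vm, smooth_sigma_vox = 10, amplitude_vox = 1,
                              seed = 1L, literal_order = FALSE) {
  stopifnot(inherits(vm, "volume_with_mask"))
  if (sum(vm$mask) == 0) stopf("empty mask")
  if (amplitude_vox == 0) return(vm)
  d <- dim(vm$mask)
  margin <- as.integer(ceiling(2 * smooth_sigma_vox + 3 * amplitude_vox))
  box <- mask_bbox(vm$mask, pad = margin)
  rd <- box$hi - box$lo + 1L
  fld <- contour_field(rd, smooth_sigma_vox, amplitude_vox, seed,
                       literal_order)
  sub <- array(as.numeric(crop_box(vm$mask, box)), rd)
  warped <- warp_sample_cpp(sub, rd, fld$dx, fld$dy, fld$dz, 0)
  newsub <- array(as.integer(warped >= 0.5), rd)
  if (sum(newsub) == 0)
    stopf("contour randomization (seed %s, amplitude %.2f) emptied the mask",
          seed, amplitude_vox)
  msk <- vm$mask
  msk[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- newsub
  out <- vm
  out$mask <- msk
  out
}

#' Apply one perturbation realization
#'
#' Fixed composition order: rigid transform, then noise injection, then
#' contour randomization. The identity realization (zero shifts, zero
#' angle, multiplier 0, zero contour amplitude) returns the input
#' bit-identical.
#'
#' @param vm a [volume_with_mask()].
#' @param r one realization: a single row of [sample_realizations()] output
#'   (or an equivalent named list).
#' @param sigma_hu native noise level (HU) that the multiplier scales.
#' @param contour_smooth_sigma_vox,contour_amplitude_vox contour-field
#'   parameters from the grid.
#' @param fill_hu out-of-grid fill value for the rigid transform.
#' @return The perturbed [volume_with_mask()].
#' @export
apply_realization <- function(vm, r, sigma_hu,
                              contour_smooth_sigma_vox = 10,
                              contour_amplitude_vox = 1,
                              fill_hu = -1000) {
  vm <- rigid_transform(vm, r$tx_px, r$ty_px, r$angle_deg, fill_hu)
  vm <- add_noise(vm, r$noise_multiplier, sigma_hu,
                  seed = r$noise_seed %||% r$contour_seed)
  randomize_contour(vm, contour_smooth_sigma_vox, contour_amplitude_vox,
                    seed = r$contour_seed)
}
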