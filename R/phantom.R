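#' Specification for a synthetic CT phantom
#'
#' Describes a body-like soft-tissue background with an embedded ellipsoid
#' tumour whose interior carries a smoothed Gaussian random-field texture
#' (so texture features are non-degenerate) plus white acquisition noise.
#' The defaults mimic an axial head-and-neck CT: anisotropic voxels with
#' thick slices and a soft-tissue-range tumour.
#'
#' @param grid_shape voxels per axis `(x, y, z)`.
#' @param spacing_mm voxel size per axis in mm.
#' @param tumor_axes_mm ellipsoid semi-axes in mm.
#' @param tumor_center_mm physical centre of the tumour; default grid centre.
#' @param background_hu body soft-tissue value (HU).
#' @param tumor_mean_hu mean tumour value (HU).
#' @param texture_scale_mm correlation length of the intratumoral texture.
#' @param texture_amplitude_hu standard deviation of the texture component.
#' @param noise_sigma_hu standard deviation of the white acquisition noise.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 64),
                         spacing_mm = c(1, 1, 3),
                         tumor_axes_mm = c(12, 12, 12),
                         tumor_center_mm = NULL,
                         background_hu = 40,
                         tumor_mean_hu = 60,
                         texture_scale_mm = 4,
                         texture_amplitude_hu = 20,
                         noise_sigma_hu = 15,
                         seed = 1L) {
  if (any(spacing_mm <= 0)) stopf("all spacings must be positive")
  if (any(tumor_axes_mm <= 0)) stopf("tumor semi-axes must be positive")
  if (noise_sigma_hu < 0) stopf("noise_sigma_hu must be >= 0")
  if (texture_amplitude_hu < 0) stopf("texture_amplitude_hu must be >= 0")
  extent <- (grid_shape - 1) * spacing_mm
  if (is.null(tumor_center_mm)) tumor_center_mm <- extent / 2
  # tumour must fit inside the grid with a >= 5-voxel margin per axis
  margin <- 5 * spacing_mm
  if (any(tumor_center_mm - tumor_axes_mm < margin) ||
      any(tumor_center_mm + tumor_axes_mm > extent - margin))
    stopf("tumour exceeds the grid (needs a 5-voxel margin per axis)")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 tumor_axes_mm = as.numeric(tumor_axes_mm),
                 tumor_center_mm = as.numeric(tumor_center_mm),
                 background_hu = background_hu,
                 tumor_mean_hu = tumor_mean_hu,
                 texture_scale_mm = texture_scale_mm,
                 texture_amplitude_hu = texture_amplitude_hu,
                 noise_sigma_hu = noise_sigma_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Physical voxel-centre coordinates along one axis
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

#' Generate a synthetic CT phantom
#'
#' Builds the body background (an elliptic cylinder of soft tissue in air),
#' carves the exact ellipsoid tumour mask, fills the tumour interior with
#' `tumor_mean_hu` plus a Gaussian random field smoothed at
#' `texture_scale_mm`, and adds white Gaussian noise of `noise_sigma_hu`
#' over the whole volume. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume_with_mask()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; sp <- spec$spacing_mm
  xs <- axis_coords(d[1], sp[1]); ys <- axis_coords(d[2], sp[2])
  zs <- axis_coords(d[3], sp[3])
  extent <- (d - 1) * sp
  # body: elliptic cylinder through all slices
  bx <- 0.45 * extent[1]; by <- 0.45 * extent[2]
  r2 <- outer(((xs - extent[1] / 2) / bx)^2, ((ys - extent[2] / 2) / by)^2, "+")
  body2d <- r2 <= 1
  image <- array(-1000, dim = d)
  image[rep(body2d, d[3])] <- spec$background_hu
  # exact ellipsoid indicator at voxel centres
  cx <- spec$tumor_center_mm; ax <- spec$tumor_axes_mm
  e2 <- outer(outer(((xs - cx[1]) / ax[1])^2, ((ys - cx[2]) / ax[2])^2, "+"),
              ((zs - cx[3]) / ax[3])^2, "+")
  mask <- array(as.integer(e2 <= 1), dim = d)
  image[mask > 0] <- spec$tumor_mean_hu
  with_seed(spec$seed, {
    if (spec$texture_amplitude_hu > 0) {
      tex <- array(rnorm(prod(d)), dim = d)
      tex <- gaussian_smooth(tex, spec$texture_scale_mm / sp)
      tex <- tex / sd(tex)
      image[mask > 0] <- image[mask > 0] +
        spec$texture_amplitude_hu * tex[mask > 0]
    }
    if (spec$noise_sigma_hu > 0)
      image <- image + array(rnorm(prod(d), 0, spec$noise_sigma_hu), dim = d)
  })
  volume_with_mask(image, mask, sp)
}

#' Default per-patient variation ranges for synthetic cohorts
#'
#' Each entry is a `c(lo, hi)` range sampled uniformly per patient:
#' tumour semi-axes 8-20 mm, tumour mean 20-100 HU, texture correlation
#' length 3-6 mm, texture amplitude 10-30 HU, acquisition noise 10-20 HU.
#'
#' @return Named list of ranges.
#' @export
cohort_ranges <- function() {
  list(tumor_axes_mm = c(8, 20),
       tumor_mean_hu = c(20, 100),
       texture_scale_mm = c(3, 6),
       texture_amplitude_hu = c(10, 30),
       noise_sigma_hu = c(10, 20))
}

#' Generate a cohort of synthetic phantoms
#'
#' Per-patient tumour size, intensity, texture and noise level are drawn
#' uniformly from `ranges`; per-patient seeds are derived hierarchically
#' from `seed`, so extending the cohort never changes earlier patients.
#'
#' @param n number of patients (>= 1).
#' @param ranges named list of `c(lo, hi)` ranges, see [cohort_ranges()].
#' @param seed master RNG seed.
#' @param grid_shape,spacing_mm grid geometry shared by all patients.
#' @return A list of [volume_with_mask()] objects; each carries its
#'   `phantom_spec` as attribute `"spec"`, and the list carries the drawn
#'   per-patient parameters as attribute `"params"` (a data frame).
#' @export
generate_cohort <- function(n, ranges = cohort_ranges(), seed = 1L,
                            grid_shape = c(96, 96, 64),
                            spacing_mm = c(1, 1, 3)) {
  if (n < 1) stopf("n must be >= 1")
  base <- cohort_ranges()
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stopf("invalid range for '%s'", nm)
    base[[nm]] <- r
  }
  ranges <- base
  seeds <- derive_seeds(seed, n)
  draw <- function(s, r, k = 1) with_seed(s, runif(k, r[1], r[2]))
  param_seeds <- derive_seeds(seed + 1L, n)
  cohort <- vector("list", n)
  params <- data.frame(id = sprintf("p%03d", seq_len(n)))
  for (i in seq_len(n)) {
    p <- with_seed(param_seeds[i], {
      list(axes = runif(3, ranges$tumor_axes_mm[1], ranges$tumor_axes_mm[2]),
           mean_hu = runif(1, ranges$tumor_mean_hu[1], ranges$tumor_mean_hu[2]),
           tex_scale = runif(1, ranges$texture_scale_mm[1],
                             ranges$texture_scale_mm[2]),
           tex_amp = runif(1, ranges$texture_amplitude_hu[1],
                           ranges$texture_amplitude_hu[2]),
           noise = runif(1, ranges$noise_sigma_hu[1], ranges$noise_sigma_hu[2]),
           jitter = runif(2, -5, 5))
    })
    extent <- (grid_shape - 1) * spacing_mm
    center <- extent / 2
    center[1:2] <- center[1:2] + p$jitter
    spec <- phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                         tumor_axes_mm = p$axes, tumor_center_mm = center,
                         tumor_mean_hu = p$mean_hu,
                         texture_scale_mm = p$tex_scale,
                         texture_amplitude_hu = p$tex_amp,
                         noise_sigma_hu = p$noise, seed = seeds[i])
    vm <- generate_phantom(spec)
    attr(vm, "spec") <- spec
    attr(vm, "id") <- params$id[i]
    cohort[[i]] <- vm
    params$volume_mm3[i] <- 4 / 3 * pi * prod(p$axes)
    params$tumor_mean_hu[i] <- p$mean_hu
    params$texture_amplitude_hu[i] <- p$tex_amp
    params$noise_sigma_hu[i] <- p$noise
  }
  names(cohort) <- params$id
  attr(cohort, "params") <- params
  cohort
}

#' Simulate survival outcomes linked to features
#'
#' Event times follow an exponential proportional-hazards model
#' `h(t) = baseline_hazard * exp(beta' z)` on z-scored features, with
#' independent exponential censoring; the recorded event indicator is 1
#' when the event time precedes the censoring time.
#'
#' @param features data frame or matrix (patients x named features).
#' @param beta named coefficient vector; names must exist in `features`.
#' @param baseline_hazard baseline event rate.
#' @param censor_rate rate of the independent exponential censoring process
#'   (0 disables censoring).
#' @param seed RNG seed.
#' @return Data frame with columns `time` and `event`.
#' @export
simulate_survival <- function(features, beta, baseline_hazard = 0.1,
                              censor_rate = 0.05, seed = 1L) {
  features <- as.data.frame(features)
  missing <- setdiff(names(beta), names(features))
  if (length(missing))
    stopf("unknown feature(s) in beta: %s", paste(missing, collapse = ", "))
  n <- nrow(features)
  z <- scale(as.matrix(features[names(beta)]))
  z[is.nan(z)] <- 0  # constant feature: no contribution
  lp <- as.numeric(z %*% beta)
  with_seed(seed, {
    t_event <- rexp(n, rate = baseline_hazard * exp(lp))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  })
}
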