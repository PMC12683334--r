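shape_feature_names <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
  "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
  "Elongation", "Flatness")

#' Morphological (shape) features of a binary mask
#'
#' The 14 shape descriptors: mesh volume and surface area from a
#' marching-tetrahedra triangulation of the 0.5 isosurface, voxel-counting
#' volume, surface/volume ratio, sphericity, maximum 3D diameter, maximum
#' in-plane/2D diameters per fixed axis, and the principal-axis lengths
#' (4*sqrt(eigenvalue) of the voxel-coordinate covariance) with elongation
#' and flatness. Shape depends only on the mask geometry, never on image
#' intensities.
#'
#' @param mask 3D binary array.
#' @param spacing_mm voxel spacing in mm.
#' @return Named numeric vector of 14 values. For a single-voxel (or
#'   otherwise axis-degenerate) mask the axis-ratio features are `NaN`.
#' @export
shape_features <- function(mask, spacing_mm) {
  d <- dim(mask)
  mk <- array(as.integer(mask > 0), d)
  nvox <- sum(mk)
  if (nvox == 0) stopf("empty mask")
  # mesh the 0.5 isosurface of a lightly smoothed indicator: interpolated
  # crossings on the smooth field remove the voxel staircase that inflates
  # the surface area of a raw binary triangulation
  smooth_mk <- gaussian_smooth(array(as.numeric(mk), d), 0.7)
  av <- mesh_area_volume_cpp(smooth_mk, d, spacing_mm, 0.5)
  area <- av[1]; mesh_vol <- av[2]
  voxel_vol <- nvox * prod(spacing_mm)
  bd <- boundary_voxels_cpp(mk, d)
  dm <- max_diameters_cpp(bd, spacing_mm)
  idx <- which(mk > 0, arr.ind = TRUE)
  phys <- sweep(idx - 1, 2, spacing_mm, `*`)
  if (nrow(phys) > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NaN
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NaN
  out <- c(mesh_vol, voxel_vol, area, area / mesh_vol,
           (36 * pi * mesh_vol^2)^(1 / 3) / area,
           dm[1], dm[2], dm[3], dm[4],
           axes[1], axes[2], axes[3], elong, flat)
  names(out) <- shape_feature_names
  out
}
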