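#' Volume with aligned tumour mask
#'
#' The unit of data flowing through the perturbation and extraction stages:
#' a 3D image in Hounsfield units plus a binary tumour mask on the same
#' voxel grid, with per-axis voxel spacing. Arrays use R's column-major
#' layout with dimensions `(x, y, z)`; `spacing_mm` follows the same order,
#' so an axial CT with 3 mm slices has `spacing_mm = c(1, 1, 3)`.
#'
#' @param image 3D numeric array of HU values.
#' @param mask 3D array (logical or 0/1) on the same grid; must contain at
#'   least one foreground voxel.
#' @param spacing_mm positive numeric vector of length 3, voxel size in mm.
#' @param origin_mm physical coordinate of voxel (1,1,1), default `c(0,0,0)`.
#' @return An object of class `volume_with_mask`.
#' @export
volume_with_mask <- function(image, mask, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(image)) != 3) stopf("image must be a 3D array")
  if (!identical(dim(image), dim(mask)))
    stopf("image and mask grids differ: %s vs %s",
          paste(dim(image), collapse = "x"), paste(dim(mask), collapse = "x"))
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0))
    stopf("spacing_mm must be 3 positive values")
  m <- array(as.integer(mask > 0), dim = dim(mask))
  if (sum(m) < 1) stopf("mask has no foreground voxels")
  structure(list(image = image, mask = m,
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "volume_with_mask")
}

#' @export
print.volume_with_mask <- function(x, ...) {
  cat(sprintf("<volume_with_mask> %s voxels @ (%s) mm, %d mask voxels\n",
              paste(dim(x$image), collapse = "x"),
              paste(format(x$spacing_mm, trim = TRUE), collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

# Mask centroid in 0-based index coordinates (x, y, z)
mask_centroid <- function(vm) {
  idx <- which(vm$mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("mask is empty: no centroid")
  colMeans(idx) - 1
}

#' Crop a volume to the tumour neighbourhood
#'
#' Restricts the grid to the mask bounding box plus a physical margin.
#' Large grids cost the perturbation chain time it spends on voxels far
#' from the tumour; mask-local analyses (e.g. shape-feature robustness)
#' can run on the cropped volume instead. Note the perturbation RNG
#' stream depends on the grid, so cropped and uncropped runs are two
#' (equally valid) realizations of the same stochastic pipeline, not
#' bit-identical ones.
#'
#' @param vm a [volume_with_mask()].
#' @param pad_mm margin kept around the mask bounding box, in mm.
#' @return The cropped [volume_with_mask()].
#' @export
crop_volume <- function(vm, pad_mm = 20) {
  stopifnot(inherits(vm, "volume_with_mask"))
  pad <- as.integer(ceiling(pad_mm / vm$spacing_mm))
  box <- mask_bbox(vm$mask, pad = pad)
  d <- dim(vm$mask)
  volume_with_mask(crop_box(vm$image, box), crop_box(vm$mask, box),
                   vm$spacing_mm, vm$origin_mm)
}

#' Dice overlap of two binary masks
#'
#' @param a,b binary arrays of identical dimension.
#' @return Dice similarity coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
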