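#' Feature-extraction configuration
#'
#' Controls the IBSI-style preprocessing and the image-type set: isotropic
#' resampling target, HU resegmentation window, fixed bin count, LoG
#' sigmas, wavelet, and the enabled feature classes.
#'
#' @param target_spacing_mm isotropic resampling target, default 1 mm.
#' @param resegment_window_hu HU window `(lo, hi)` outside which voxels are
#'   removed from the intensity mask (shape keeps the morphological mask).
#' @param bin_count fixed number of gray-level bins (>= 2).
#' @param log_sigmas_mm Laplacian-of-Gaussian scales in mm.
#' @param enabled_classes subset of
#'   `c("shape","firstorder","glcm","glrlm","glszm","gldm","ngtdm")`.
#' @param image_types subset of `c("original", "log", "wavelet")` for the
#'   first-order/texture classes.
#' @param pad_vox padding around the mask bounding box kept for filtering.
#' @return An `extraction_config` object.
#' @export
extraction_config <- function(target_spacing_mm = c(1, 1, 1),
                              resegment_window_hu = c(-150, 180),
                              bin_count = 30L,
                              log_sigmas_mm = 1:6,
                              enabled_classes = c("shape", "firstorder",
                                                  "glcm", "glrlm", "glszm",
                                                  "gldm", "ngtdm"),
                              image_types = c("original", "log", "wavelet"),
                              pad_vox = 10L) {
  if (length(target_spacing_mm) == 1)
    target_spacing_mm <- rep(target_spacing_mm, 3)
  if (bin_count < 2) stopf("bin_count must be >= 2")
  if (resegment_window_hu[1] >= resegment_window_hu[2])
    stopf("resegment window lower bound must be below upper bound")
  if (any(log_sigmas_mm <= 0)) stopf("LoG sigmas must be positive")
  all_classes <- c("shape", "firstorder", "glcm", "glrlm", "glszm",
                   "gldm", "ngtdm")
  enabled_classes <- match.arg(enabled_classes, all_classes, several.ok = TRUE)
  image_types <- match.arg(image_types, c("original", "log", "wavelet"),
                           several.ok = TRUE)
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 resegment_window_hu = as.numeric(resegment_window_hu),
                 bin_count = as.integer(bin_count),
                 log_sigmas_mm = as.numeric(log_sigmas_mm),
                 enabled_classes = enabled_classes,
                 image_types = image_types,
                 pad_vox = as.integer(pad_vox)),
            class = "extraction_config")
}

# Resample a 3D array to a new spacing (grid origins aligned at voxel 1).
resample_array <- function(arr, spacing_in, spacing_out, fill, mask = FALSE) {
  d <- dim(arr)
  if (isTRUE(all.equal(spacing_in, spacing_out))) return(arr)
  outdim <- as.integer(floor((d - 1) * spacing_in / spacing_out) + 1)
  M <- diag(spacing_out / spacing_in)
  out <- affine_sample_cpp(array(as.numeric(arr), d), d, outdim, M,
                           c(0, 0, 0), fill)
  if (mask) array(as.integer(out >= 0.5), outdim) else out
}

#' Resample and resegment a volume before extraction
#'
#' Resamples image (trilinear) and mask (trilinear + 0.5 threshold) to the
#' isotropic target spacing, then removes mask voxels whose HU lies
#' outside the resegmentation window from the *intensity* mask. Shape
#' features keep the full morphological mask.
#'
#' @param vm a [volume_with_mask()].
#' @param cfg an [extraction_config()].
#' @param crop crop to the mask bounding box (plus the filtering pad)
#'   before resampling; trilinear resampling is local, so this is a pure
#'   optimization used by [extract_all()]. Default `FALSE` keeps the full
#'   grid.
#' @return A [volume_with_mask()] at target spacing with an extra
#'   `intensity_mask` element (omitted when only shape features are
#'   enabled).
#' @export
preprocess <- function(vm, cfg = extraction_config(), crop = FALSE) {
  stopifnot(inherits(vm, "volume_with_mask"))
  shape_only <- identical(cfg$enabled_classes, "shape")
  if (crop) {
    pad <- as.integer(ceiling((cfg$pad_vox + 2) * cfg$target_spacing_mm /
                                vm$spacing_mm))
    box <- mask_bbox(vm$mask, pad = pad)
    vm <- volume_with_mask(crop_box(vm$image, box), crop_box(vm$mask, box),
                           vm$spacing_mm, vm$origin_mm)
  }
  msk <- resample_array(vm$mask, vm$spacing_mm, cfg$target_spacing_mm, 0,
                        mask = TRUE)
  if (sum(msk) == 0) stopf("mask empty after resampling")
  if (shape_only) {
    img <- array(0, dim(msk))  # intensities are irrelevant to shape
    return(volume_with_mask(img, msk, cfg$target_spacing_mm, vm$origin_mm))
  }
  img <- resample_array(vm$image, vm$spacing_mm, cfg$target_spacing_mm, -1000)
  out <- volume_with_mask(img, msk, cfg$target_spacing_mm, vm$origin_mm)
  w <- cfg$resegment_window_hu
  imask <- msk
  imask[img < w[1] | img > w[2]] <- 0L
  if (sum(imask) == 0)
    stopf("resegmentation window [%g, %g] HU removed every mask voxel",
          w[1], w[2])
  out$intensity_mask <- imask
  out
}

#' Fixed-bin-count gray-level discretization
#'
#' Maps ROI intensities into `bin_count` equal-width bins spanning the ROI
#' `[min, max]`; the maximum maps to `bin_count`. A constant ROI collapses
#' to bin 1 and is flagged degenerate.
#'
#' @param image 3D numeric array.
#' @param roi_mask binary array marking the intensity ROI.
#' @param bin_count number of bins.
#' @return Integer array of bin labels (0 outside the ROI), with attribute
#'   `degenerate` TRUE when the ROI is constant.
#' @export
discretize <- function(image, roi_mask, bin_count = 30L) {
  d <- dim(image)
  inroi <- roi_mask > 0
  if (!any(inroi)) stopf("intensity mask is empty")
  v <- image[inroi]
  lo <- min(v); hi <- max(v)
  labels <- array(0L, d)
  if (hi == lo) {
    labels[inroi] <- 1L
    attr(labels, "degenerate") <- TRUE
    return(labels)
  }
  w <- (hi - lo) / bin_count
  labels[inroi] <- pmin(as.integer(floor((v - lo) / w)) + 1L,
                        as.integer(bin_count))
  attr(labels, "degenerate") <- FALSE
  labels
}

#' Laplacian-of-Gaussian filter at a physical scale
#'
#' Separable LoG response with sigma in mm (converted per axis to voxels).
#' Implemented as the sum over axes of a second-derivative-of-Gaussian
#' kernel along that axis and Gaussian kernels along the others, with
#' replicate boundaries; the kernels are zero/unit-sum corrected so a
#' constant image gives exactly zero response.
#'
#' @param image 3D numeric array.
#' @param spacing_mm voxel spacing.
#' @param sigma_mm filter scale in mm.
#' @return Filtered array of the same dimension.
#' @export
log_filter <- function(image, spacing_mm, sigma_mm) {
  d <- dim(image)
  sv <- sigma_mm / spacing_mm
  if (any(sv < 1))
    warning(sprintf("LoG sigma %g mm is below the voxel size; computed anyway",
                    sigma_mm))
  g <- lapply(sv, gaussian_kernel)
  # second-derivative kernels in physical units (per mm^2)
  d2 <- lapply(seq_len(3),
               function(a) gaussian_d2_kernel(sv[a]) / spacing_mm[a]^2)
  # shared partial smoothings keep this to 7 passes
  gz <- conv_axis_cpp(image, d, g[[3]], 2L, 0L)
  t1 <- conv_axis_cpp(conv_axis_cpp(gz, d, g[[2]], 1L, 0L), d, d2[[1]], 0L, 0L)
  t2 <- conv_axis_cpp(conv_axis_cpp(gz, d, d2[[2]], 1L, 0L), d, g[[1]], 0L, 0L)
  dz <- conv_axis_cpp(image, d, d2[[3]], 2L, 0L)
  t3 <- conv_axis_cpp(conv_axis_cpp(dz, d, g[[2]], 1L, 0L), d, g[[1]], 0L, 0L)
  t1 + t2 + t3
}

# Coiflet-1 analysis filters, scaled so the low-pass sums to 1 (the
# undecimated transform then conserves total energy across the 8 subbands
# under periodic boundaries, and leaves constants unchanged in LLL).
coif1_filters <- function() {
  lo <- c(-0.015655728135465137, -0.07273261951252645, 0.3848648565381134,
          0.8525720202116004, 0.33789766245748187, -0.07273261951252645)
  lo <- lo / sum(lo)  # exact unit DC gain
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  hi <- hi - mean(hi)  # exact zero DC gain
  list(L = lo, H = hi)
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) Coiflet-1 transform: every subband
#' shares the input grid, labelled by one low/high-pass letter per axis in
#' x, y, z order (e.g. `HLL` = high-pass along x).
#'
#' @param image 3D numeric array.
#' @param boundary `"reflect"` (default), `"wrap"`, or `"replicate"`.
#' @return Named list of 8 subband arrays
#'   (`LLL`, `LLH`, `LHL`, `LHH`, `HLL`, `HLH`, `HHL`, `HHH`).
#' @export
wavelet_decompose <- function(image, boundary = "reflect") {
  d <- dim(image)
  f <- coif1_filters()
  mode <- match(boundary, c("replicate", "wrap", "reflect")) - 1L
  sub <- list()
  for (a in c("L", "H")) {
    xa <- conv_axis_cpp(image, d, f[[a]], 0L, mode)
    for (b in c("L", "H")) {
      xb <- conv_axis_cpp(xa, d, f[[b]], 1L, mode)
      for (cc in c("L", "H"))
        sub[[paste0(a, b, cc)]] <- conv_axis_cpp(xb, d, f[[cc]], 2L, mode)
    }
  }
  sub[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
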