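wavelet_subband_names <- c("LLL", "LLH", "LHL", "LHH",
                           "HLL", "HLH", "HHL", "HHH")

# Image-type labels for a configuration, in stable extraction order
image_type_labels <- function(cfg) {
  lab <- character(0)
  if ("original" %in% cfg$image_types) lab <- c(lab, "original")
  if ("log" %in% cfg$image_types)
    lab <- c(lab, sprintf("log-sigma-%g-mm-3D", cfg$log_sigmas_mm))
  if ("wavelet" %in% cfg$image_types)
    lab <- c(lab, paste0("wavelet-", wavelet_subband_names))
  lab
}

#' Expected feature names for a configuration
#'
#' Stable ordering: 14 shape features first (when enabled), then the 93
#' first-order/texture features per image type, image types in the order
#' original, LoG sigmas ascending, wavelet subbands. Intensity/texture
#' names carry the bin-count suffix used in the databank convention, e.g.
#' `log-sigma-2-mm-3D_glszm_LowGrayLevelZoneEmphasis_30_binCount`.
#'
#' @param cfg an [extraction_config()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(cfg = extraction_config()) {
  cls <- list(firstorder = firstorder_names, glcm = glcm_names,
              glrlm = glrlm_names, glszm = glszm_names,
              gldm = gldm_names, ngtdm = ngtdm_names)
  cls <- cls[intersect(names(cls), cfg$enabled_classes)]
  per_type <- unlist(lapply(names(cls), function(cl)
    paste0(cl, "_", cls[[cl]])), use.names = FALSE)
  nm <- character(0)
  if ("shape" %in% cfg$enabled_classes)
    nm <- paste0("original_shape_", shape_feature_names)
  for (lab in image_type_labels(cfg))
    nm <- c(nm, sprintf("%s_%s_%d_binCount", lab, per_type, cfg$bin_count))
  nm
}

#' Extract the full feature vector from one volume
#'
#' Runs [preprocess()] (isotropic resampling + HU resegmentation), crops to
#' the mask bounding box, computes the 14 shape features on the
#' morphological mask, derives the configured image types (original, LoG
#' at each sigma, 8 wavelet subbands) and extracts the 93 first-order and
#' texture features from each within the intensity mask. With the default
#' configuration this yields 14 + 93 x 15 = 1409 values.
#'
#' @param vm a [volume_with_mask()].
#' @param cfg an [extraction_config()].
#' @return Named numeric vector, ordered as [feature_names()].
#' @export
extract_all <- function(vm, cfg = extraction_config()) {
  pp <- preprocess(vm, cfg, crop = TRUE)
  out <- numeric(0)
  if ("shape" %in% cfg$enabled_classes) {
    sbox <- mask_bbox(pp$mask, pad = 1L)
    sf <- shape_features(crop_box(pp$mask, sbox), pp$spacing_mm)
    out <- stats::setNames(sf, paste0("original_shape_", names(sf)))
  }
  tex_classes <- setdiff(cfg$enabled_classes, "shape")
  if (!length(tex_classes)) return(out)
  box <- mask_bbox(pp$mask, pad = cfg$pad_vox)
  img <- crop_box(pp$image, box)
  imask <- crop_box(pp$intensity_mask, box)
  images <- list()
  if ("original" %in% cfg$image_types) images[["original"]] <- img
  if ("log" %in% cfg$image_types)
    for (s in cfg$log_sigmas_mm)
      images[[sprintf("log-sigma-%g-mm-3D", s)]] <-
        log_filter(img, pp$spacing_mm, s)
  if ("wavelet" %in% cfg$image_types) {
    wl <- wavelet_decompose(img)
    for (sb in wavelet_subband_names)
      images[[paste0("wavelet-", sb)]] <- wl[[sb]]
  }
  for (lab in names(images)) {
    fv <- intensity_texture_features(images[[lab]], imask, pp$spacing_mm,
                                     cfg$bin_count, tex_classes)
    out <- c(out, stats::setNames(
      fv, sprintf("%s_%s_%d_binCount", lab, names(fv), cfg$bin_count)))
  }
  out
}

#' Extract features for a cohort under perturbation
#'
#' For every patient: extracts the unperturbed feature vector, estimates
#' the native noise level, applies each perturbation realization (rigid
#' transform, scaled noise, randomized contour) and re-extracts. Output is
#' the long feature table consumed by [build_databank()].
#'
#' @param cohort list of [volume_with_mask()] (e.g. [generate_cohort()]).
#' @param grid a [perturbation_grid()].
#' @param cfg an [extraction_config()].
#' @param seed master seed; per-patient realization seeds are derived
#'   hierarchically.
#' @param sigma_hu native noise level; `NULL` (default) estimates it per
#'   patient with [estimate_noise()].
#' @return Data frame with columns `patient`, `realization`
#'   (`"unperturbed"` or the realization number) and one column per
#'   feature.
#' @export
extract_cohort_features <- function(cohort, grid = perturbation_grid(),
                                    cfg = extraction_config(), seed = 1L,
                                    sigma_hu = NULL) {
  ids <- names(cohort) %||% sprintf("p%03d", seq_along(cohort))
  seeds <- derive_seeds(seed, length(cohort))
  rows <- vector("list", length(cohort) * (grid$n_realizations + 1))
  meta <- vector("list", length(rows))
  ri <- 0L
  for (i in seq_along(cohort)) {
    vm <- cohort[[i]]
    s_hu <- sigma_hu %||% estimate_noise(vm)
    rl <- sample_realizations(grid, seeds[i])
    ri <- ri + 1L
    rows[[ri]] <- extract_all(vm, cfg)
    meta[[ri]] <- c(ids[i], "unperturbed")
    for (r in seq_len(nrow(rl))) {
      pvm <- apply_realization(vm, rl[r, ], s_hu,
                               grid$contour_smooth_sigma_vox,
                               grid$contour_amplitude_vox)
      ri <- ri + 1L
      rows[[ri]] <- extract_all(pvm, cfg)
      meta[[ri]] <- c(ids[i], as.character(r))
    }
  }
  feats <- do.call(rbind, rows)
  out <- data.frame(patient = vapply(meta, `[`, "", 1),
                    realization = vapply(meta, `[`, "", 2),
                    check.names = FALSE)
  cbind(out, as.data.frame(feats, check.names = FALSE))
}
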