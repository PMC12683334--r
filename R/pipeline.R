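# Cohort and table I/O plus the end-to-end orchestration. Volumes are
# stored as paired NIfTI files (`<id>_image.nii.gz`, `<id>_mask.nii.gz`),
# outcomes and all tabular results as CSV.

#' Write a cohort to paired NIfTI files
#'
#' @param cohort list of [volume_with_mask()] (named by patient id).
#' @param dir output directory (created if needed).
#' @param outcomes optional data frame with `time` and `event` per patient,
#'   written as `outcomes.csv` with an `id` column.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, outcomes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort) %||% sprintf("p%03d", seq_along(cohort))
  for (i in seq_along(cohort)) {
    vm <- cohort[[i]]
    img <- RNifti::asNifti(vm$image)
    RNifti::pixdim(img) <- vm$spacing_mm
    msk <- RNifti::asNifti(array(as.numeric(vm$mask), dim(vm$mask)))
    RNifti::pixdim(msk) <- vm$spacing_mm
    RNifti::writeNifti(img, file.path(dir, paste0(ids[i], "_image.nii.gz")))
    RNifti::writeNifti(msk, file.path(dir, paste0(ids[i], "_mask.nii.gz")))
  }
  if (!is.null(outcomes))
    write.csv(cbind(id = ids, outcomes), file.path(dir, "outcomes.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Read a cohort of paired NIfTI files
#'
#' Discovers patients by the `<id>_image.nii.gz` naming convention and
#' checks that every image has a mask on an identical grid with identical
#' spacing.
#'
#' @param dir directory written by [write_cohort()].
#' @return Named list of [volume_with_mask()] objects; if `outcomes.csv`
#'   is present it is attached as attribute `"outcomes"`.
#' @export
read_cohort <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "_image\\.nii(\\.gz)?$"))
  if (!length(imgs)) stopf("no *_image.nii[.gz] files in %s", dir)
  ids <- sub("_image\\.nii(\\.gz)?$", "", imgs)
  cohort <- vector("list", length(ids))
  names(cohort) <- ids
  for (i in seq_along(ids)) {
    ipath <- file.path(dir, imgs[i])
    mpath <- file.path(dir, sub("_image", "_mask", imgs[i]))
    if (!file.exists(mpath)) stopf("missing mask file for patient %s", ids[i])
    img <- RNifti::readNifti(ipath)
    msk <- RNifti::readNifti(mpath)
    if (!identical(dim(img), dim(msk)))
      stopf("image/mask grid mismatch for patient %s", ids[i])
    sp_i <- RNifti::pixdim(img); sp_m <- RNifti::pixdim(msk)
    if (!isTRUE(all.equal(sp_i, sp_m, tolerance = 1e-6)))
      stopf("image/mask spacing mismatch for patient %s", ids[i])
    cohort[[i]] <- volume_with_mask(array(as.numeric(img), dim(img)),
                                    array(as.numeric(msk), dim(msk)) >= 0.5,
                                    sp_i[1:3])
  }
  opath <- file.path(dir, "outcomes.csv")
  if (file.exists(opath)) attr(cohort, "outcomes") <- read.csv(opath)
  cohort
}

#' Write / read a feature table as CSV
#'
#' Values round-trip losslessly (full double precision).
#'
#' @param table data frame from [extract_cohort_features()].
#' @param path CSV path.
#' @return `write_features`: the path, invisibly; `read_features`: the
#'   data frame.
#' @export
write_features <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  num <- vapply(table, is.numeric, TRUE)
  table[num] <- lapply(table[num], function(x) format(x, digits = 17))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  for (nm in setdiff(names(out), c("patient", "realization")))
    out[[nm]] <- as.numeric(out[[nm]])
  out
}

#' Write / read a robustness databank as CSV
#'
#' @param databank a [build_databank()] result.
#' @param path CSV path.
#' @return `write_databank`: the path, invisibly; `read_databank`: the
#'   databank data frame.
#' @export
write_databank <- function(databank, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(databank, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_databank
#' @export
read_databank <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  class(out) <- c("robustness_databank", "data.frame")
  out
}

default_run_config <- function() {
  list(n_patients = 20L,
       n_realizations = 12L,
       master_seed = 1L,
       grid_shape = c(96, 96, 64),
       spacing_mm = c(1, 1, 3),
       ranges = cohort_ranges(),
       perturbation = list(),           # overrides for perturbation_grid()
       extraction = list(image_types = "original"),
       icc = list(n_rounds = 10L),
       sample_size = FALSE,
       modelling = FALSE,
       beta = c(original_firstorder_Mean_30_binCount = 0.8),
       out_dir = "radrobust_run")
}

#' Run the full pipeline end to end
#'
#' Phantom cohort generation, perturbation, feature extraction, databank
#' construction and (optionally) the sample-size curve and the
#' ICC-threshold modelling experiment, with every output written as CSV
#' plus a JSON manifest recording the configuration, its hash, the seeds
#' and per-stage durations. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config named list overriding the defaults (see the source of
#'   `default_run_config`): cohort size and ranges, perturbation grid
#'   overrides, extraction settings, ICC parameters, optional stages and
#'   `out_dir`. Unknown keys are rejected.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_end_to_end <- function(config = list()) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c(); tick <- function() Sys.time()
  stage <- function(name, expr) {
    t0 <- tick()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    timings[[name]] <<- round(as.numeric(difftime(tick(), t0, units = "secs")), 2)
    out
  }
  cohort <- stage("phantom", generate_cohort(
    cfg$n_patients, cfg$ranges, seed = cfg$master_seed,
    grid_shape = cfg$grid_shape, spacing_mm = cfg$spacing_mm))
  grid <- stage("perturb_grid", do.call(perturbation_grid, utils::modifyList(
    list(n_realizations = cfg$n_realizations), cfg$perturbation)))
  excfg <- do.call(extraction_config, cfg$extraction)
  feats <- stage("extract", extract_cohort_features(
    cohort, grid, excfg, seed = cfg$master_seed + 1L))
  write_features(feats, file.path(cfg$out_dir, "features.csv"))
  databank <- stage("databank", do.call(build_databank, c(
    list(feature_table = feats, seed = cfg$master_seed + 2L), cfg$icc)))
  write_databank(databank, file.path(cfg$out_dir, "databank.csv"))
  curve <- NULL
  if (isTRUE(cfg$sample_size)) {
    curve <- stage("samplesize", sample_size_curve(
      feats, n_rounds = cfg$icc$n_rounds %||% 10L,
      seed = cfg$master_seed + 3L))
    write.csv(curve, file.path(cfg$out_dir, "sample_size_curve.csv"),
              row.names = FALSE)
  }
  report <- NULL
  if (isTRUE(cfg$modelling)) {
    report <- stage("model", {
      unp <- feats[feats$realization == "unperturbed", ]
      fx <- unp[setdiff(names(unp), c("patient", "realization"))]
      outc <- simulate_survival(fx, cfg$beta, seed = cfg$master_seed + 4L)
      ds <- survival_dataset(fx, outc$time, outc$event, "train")
      ev <- survival_dataset(fx, outc$time, outc$event, "ev1")
      run_threshold_experiment(databank, ds, list(ev1 = ev),
                               seed = cfg$master_seed + 5L)
    })
    write.csv(as.data.frame(report), file.path(cfg$out_dir, "report.csv"),
              row.names = FALSE)
  }
  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- list.files(cfg$out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("radrobust")),
    master_seed = cfg$master_seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    output_md5 = as.list(tools::md5sum(outputs)),
    stage_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, features = feats, databank = databank,
                 curve = curve, report = report, manifest = manifest))
}
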