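test_that("preprocessing keeps isotropic grids and conserves volume", {
  vm <- generate_phantom(sphere_phantom(8))
  pp <- preprocess(vm, extraction_config())
  expect_identical(dim(pp$image), dim(vm$image))  # already at 1 mm
  # anisotropic (3,1,1) -> isotropic: physical mask volume conserved to 5%
  vma <- small_phantom(noise = 0)
  ppa <- preprocess(vma, extraction_config())
  v_nat <- sum(vma$mask) * prod(vma$spacing_mm)
  v_iso <- sum(ppa$mask) * prod(ppa$spacing_mm)
  expect_lt(abs(v_iso / v_nat - 1), 0.05)
})

test_that("resegmentation removes out-of-window voxels from intensity mask", {
  vm <- generate_phantom(sphere_phantom(8))
  hot <- which(vm$mask > 0)[1]
  vm$image[hot] <- 500
  pp <- preprocess(vm, extraction_config())
  expect_equal(pp$intensity_mask[hot], 0L)
  expect_equal(sum(pp$mask) - sum(pp$intensity_mask), 1)
})

test_that("discretization follows fixed-bin-count arithmetic", {
  img <- array(0:29, c(30, 1, 1))
  msk <- array(1L, c(30, 1, 1))
  lab <- discretize(img, msk, 30)
  expect_equal(sort(unique(as.integer(lab))), 1:30)
  # window [-150, 180], width 11: value 0 lands in bin 14
  img2 <- array(c(-150, 0, 180), c(3, 1, 1))
  lab2 <- discretize(img2, array(1L, c(3, 1, 1)), 30)
  expect_equal(as.integer(lab2), c(1L, 14L, 30L))
  # constant ROI: single bin, degenerate flag, zero entropy downstream
  lab3 <- discretize(array(5, c(4, 4, 4)), array(1L, c(4, 4, 4)), 30)
  expect_true(attr(lab3, "degenerate"))
  expect_true(all(lab3 == 1L))
})

test_that("LoG filter behaves like a band-pass at the blob scale", {
  cst <- array(7, c(16, 16, 16))
  expect_lt(max(abs(log_filter(cst, c(1, 1, 1), 2))), 1e-6 * 7)
  # scale-space extremum at the centre of a matched Gaussian blob
  xs <- (1:41) - 21
  blob <- exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * 16))
  resp <- log_filter(blob, c(1, 1, 1), 4)
  expect_equal(which.max(abs(resp)), which.max(blob))
  # linearity
  expect_equal(log_filter(3 * blob, c(1, 1, 1), 2),
               3 * log_filter(blob, c(1, 1, 1), 2), tolerance = 1e-12)
})

test_that("wavelet decomposition yields 8 aligned subbands", {
  set.seed(11)
  img <- array(rnorm(20^3), c(20, 20, 20))
  wl <- wavelet_decompose(img)
  expect_length(wl, 8)
  expect_named(wl, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (sb in wl) expect_identical(dim(sb), dim(img))
  cst <- wavelet_decompose(array(4, c(12, 12, 12)))
  for (nm in setdiff(names(cst), "LLL"))
    expect_lt(max(abs(cst[[nm]])), 1e-6 * 4)
  expect_equal(cst$LLL, array(4, c(12, 12, 12)), tolerance = 1e-10)
  # orthogonal filter pair conserves energy under periodic boundaries
  wlp <- wavelet_decompose(img, boundary = "wrap")
  energy <- sum(vapply(wlp, function(s) sum(s^2), 0))
  expect_equal(energy / sum(img^2), 1, tolerance = 0.01)
})

test_that("shape features match analytic solids and scaling laws", {
  ball <- digital_ball(10)
  sf <- shape_features(ball, c(1, 1, 1))
  expect_length(sf, 14)
  expect_named(sf, radrobust:::shape_feature_names)
  expect_gt(sf["Sphericity"], 0.97); expect_lte(sf["Sphericity"], 1.0)
  expect_lt(abs(sf["MeshVolume"] / 4188.79 - 1), 0.03)
  expect_equal(unname(sf["Elongation"]), 1, tolerance = 0.02)
  # doubling the spacing doubles lengths: volume x8, surface x4
  sf2 <- shape_features(ball, c(2, 2, 2))
  expect_equal(unname(sf2["MeshVolume"] / sf["MeshVolume"]), 8,
               tolerance = 0.03)
  expect_equal(unname(sf2["SurfaceArea"] / sf["SurfaceArea"]), 4,
               tolerance = 0.03)
  expect_equal(unname(sf2["Maximum3DDiameter"] / sf["Maximum3DDiameter"]), 2)
})

test_that("hand-computed co-occurrence statistics check out on a 2x2 ROI", {
  # bins [[1,2],[1,2]]: along y both columns pair 1-2; along x pairs 1-1, 2-2
  lab <- array(0L, c(2, 2, 1))
  lab[, , 1] <- rbind(c(1L, 2L), c(1L, 2L))
  counts <- radrobust:::glcm13_cpp(lab, c(2L, 2L, 1L), 2L)
  for (d in 1:13)
    expect_identical(counts[, , d], t(counts[, , d]))
  img <- array(0, c(2, 2, 1)); img[, , 1] <- rbind(c(1, 2), c(1, 2))
  msk <- array(1L, c(2, 2, 1))
  fv <- intensity_texture_features(img, msk, c(1, 1, 1), 2,
                                   classes = c("firstorder", "glcm"))
  expect_equal(unname(fv["firstorder_Mean"]), 1.5)
  # direction x (same-level pairs only): p = diag(0.5, 0.5)
  dx <- counts[, , 9]
  expect_equal(dx / sum(dx), diag(c(0.5, 0.5)))
})

test_that("constant ROI collapses to the documented degenerate values", {
  img <- array(50, c(10, 10, 10))
  msk <- array(0L, c(10, 10, 10)); msk[3:8, 3:8, 3:8] <- 1L
  fv <- intensity_texture_features(img, msk, c(1, 1, 1), 30)
  expect_length(fv, 93)
  expect_equal(unname(fv["firstorder_Variance"]), 0)
  expect_equal(unname(fv["firstorder_Entropy"]), 0)
  expect_equal(unname(fv["glcm_JointEntropy"]), 0)
  expect_equal(unname(fv["glcm_Correlation"]), 1)
  expect_equal(unname(fv["ngtdm_Contrast"]), 0)
})

test_that("full extraction has the configured arity and stable names", {
  cfg <- extraction_config()
  nm <- feature_names(cfg)
  expect_length(nm, 1409)
  expect_equal(sum(grepl("_shape_", nm)), 14)
  per_type <- (length(nm) - 14) / (1 + 6 + 8)
  expect_equal(per_type, 93)
  vm <- small_phantom(seed = 21)
  fv <- extract_all(vm, cfg)
  expect_identical(names(fv), nm)
  expect_true(all(is.finite(fv)))
  # first-order entropy bounded by log2(bin count)
  ent <- fv[grepl("firstorder_Entropy", names(fv))]
  expect_true(all(ent <= log2(30) + 1e-12))
})

test_that("shape features ignore intensities; rigid shifts spare features", {
  vm <- small_phantom(seed = 22)
  cfg <- extraction_config(image_types = "original")
  fv <- extract_all(vm, cfg)
  vm2 <- vm
  vm2$image <- vm2$image + rnorm(length(vm2$image), 0, 30)
  fv2 <- extract_all(vm2, cfg)
  shp <- grepl("_shape_", names(fv))
  expect_identical(fv[shp], fv2[shp])
  expect_false(identical(fv[!shp], fv2[!shp]))
  # integer-voxel translation leaves every feature bit-identical
  sh <- rigid_transform(vm, 3, 2, 0)
  expect_identical(extract_all(sh, cfg), fv)
})
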