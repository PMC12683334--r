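test_that("realization sampling honours the grid and the seed", {
  grid <- perturbation_grid()
  rl <- sample_realizations(grid, seed = 7)
  expect_equal(nrow(rl), 60)
  expect_true(all(rl$tx_px %in% c(0, 0.4, 0.8)))
  expect_true(all(rl$angle_deg %in% c(-20, 0, 20)))
  expect_true(all(rl$noise_multiplier %in% c(0, 1, 2, 5)))
  expect_identical(rl, sample_realizations(grid, seed = 7))
  g1 <- perturbation_grid(translations_px = 0, rotations_deg = 0,
                          noise_multipliers = 0, n_realizations = 5)
  r1 <- sample_realizations(g1, seed = 1)
  expect_true(all(r1$tx_px == 0 & r1$angle_deg == 0 & r1$noise_multiplier == 0))
  expect_error(perturbation_grid(translations_px = numeric(0)), "non-empty")
})

test_that("identity rigid transform is a bit-exact no-op", {
  vm <- small_phantom()
  expect_identical(rigid_transform(vm, 0, 0, 0), vm)
})

test_that("integer-voxel shifts preserve the tumour interior histogram", {
  vm <- small_phantom(noise = 0)
  sh <- rigid_transform(vm, 2, 3, 0)
  # compare intensities inside the (shifted) mask, away from the boundary
  inner <- function(v) sort(v$image[v$mask > 0])
  expect_equal(inner(sh), inner(vm), tolerance = 1e-12)
})

test_that("opposite rotations nearly invert each other", {
  vm <- generate_phantom(sphere_phantom(10, noise = 0))
  v2 <- rigid_transform(rigid_transform(vm, 0, 0, 20), 0, 0, -20)
  expect_gt(dice(v2$mask, vm$mask), 0.98)
})

test_that("noise estimator recovers the injected level and ignores DC", {
  vm0 <- generate_phantom(sphere_phantom(8, noise = 0, texture = 0))
  expect_lt(estimate_noise(vm0), 0.5)
  vm20 <- generate_phantom(sphere_phantom(8, noise = 20, texture = 0,
                                          seed = 3))
  est <- estimate_noise(vm20)
  expect_gt(est, 17); expect_lt(est, 23)
  shifted <- vm20; shifted$image <- shifted$image + 100
  expect_equal(estimate_noise(shifted), est, tolerance = 0.1)
  # anisotropic textured default phantom stays within +-15% for sigma >= 5
  for (s in c(5, 10, 20)) {
    vs <- generate_phantom(phantom_spec(noise_sigma_hu = s, seed = 4))
    expect_lt(abs(estimate_noise(vs) - s) / s, 0.15)
  }
})

test_that("noise injection matches the requested std and spares the mask", {
  vm <- small_phantom()
  expect_identical(add_noise(vm, 0, 15, seed = 1), vm)
  nz <- add_noise(vm, 2, 10, seed = 1)
  expect_identical(nz$mask, vm$mask)
  delta <- nz$image - vm$image
  expect_gt(length(delta), 1e5)
  expect_equal(sd(delta), 20, tolerance = 0.01)
  expect_lt(abs(mean(delta)), 3 * 20 / sqrt(length(delta)))
  nz2 <- add_noise(vm, 2, 10, seed = 2)
  expect_false(identical(nz$image, nz2$image))
  expect_identical(nz$mask, nz2$mask)
})

test_that("contour randomization deforms without destroying the mask", {
  vm <- generate_phantom(sphere_phantom(20, noise = 0))
  expect_identical(randomize_contour(vm, 10, 0, seed = 1), vm)
  rc <- randomize_contour(vm, 10, 1, seed = 1)
  d <- dice(rc$mask, vm$mask)
  expect_gt(d, 0.85); expect_lt(d, 1)
  expect_identical(rc$image, vm$image)
  expect_true(all(rc$mask %in% c(0L, 1L)))
  expect_lt(abs(sum(rc$mask) / sum(vm$mask) - 1), 0.2)
  expect_identical(rc$mask, randomize_contour(vm, 10, 1, seed = 1)$mask)
})

test_that("displacement-field z-component is constant within each slice", {
  fld <- radrobust:::contour_field(c(24, 24, 12), 5, 1, seed = 9)
  rng <- apply(fld$dz, 3, function(s) diff(range(s)))
  expect_lt(max(rng), 1e-12)
  # each smoothed component is RMS-normalized to the amplitude
  for (cmp in fld) expect_equal(sqrt(mean(cmp^2)), 1, tolerance = 1e-10)
  # literal order (normalize before smoothing) shrinks displacements
  lit <- radrobust:::contour_field(c(24, 24, 12), 5, 1, seed = 9,
                                   literal_order = TRUE)
  expect_lt(sqrt(mean(lit$dx^2)), 0.5)
})

test_that("identity realization composes to a bit-exact no-op", {
  vm <- small_phantom()
  out <- apply_realization(vm, identity_realization(), sigma_hu = 15,
                           contour_amplitude_vox = 0)
  expect_identical(out, vm)
})

test_that("sampled realizations give distinct, reproducible masks", {
  vm <- small_phantom(noise = 10)
  grid <- perturbation_grid(n_realizations = 12)
  rl <- sample_realizations(grid, seed = 5)
  vols <- vapply(seq_len(nrow(rl)), function(r)
    sum(apply_realization(vm, rl[r, ], 10)$mask), 0)
  expect_gt(length(unique(vols)), 1)
  again <- sum(apply_realization(vm, rl[3, ], 10)$mask)
  expect_equal(vols[3], as.numeric(again))
})
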