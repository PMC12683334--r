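test_that("noise-free, texture-free phantom is exactly the nominal tumour", {
  vm <- generate_phantom(sphere_phantom(8))
  expect_true(all(vm$image[vm$mask > 0] == 60))
  expect_gt(sum(vm$mask), 0)
})

test_that("phantom generation is deterministic given the seed", {
  sp <- sphere_phantom(8, noise = 12, texture = 20)
  expect_identical(generate_phantom(sp)$image, generate_phantom(sp)$image)
  sp2 <- sphere_phantom(8, noise = 12, texture = 20, seed = 2)
  expect_false(identical(generate_phantom(sp)$image,
                         generate_phantom(sp2)$image))
})

test_that("voxelized ellipsoid volume matches the analytic volume", {
  vm <- generate_phantom(sphere_phantom(10))
  expect_equal(sum(vm$mask), 4 / 3 * pi * 10^3, tolerance = 0.02)
  # convergence as spacing shrinks: finer grid is closer
  sp_fine <- phantom_spec(grid_shape = c(60, 60, 60),
                          spacing_mm = c(0.5, 0.5, 0.5),
                          tumor_axes_mm = c(10, 10, 10),
                          noise_sigma_hu = 0, texture_amplitude_hu = 0)
  v_fine <- sum(generate_phantom(sp_fine)$mask) * 0.5^3
  expect_lt(abs(v_fine - 4188.79) / 4188.79,
            abs(sum(vm$mask) - 4188.79) / 4188.79 + 1e-9)
})

test_that("tumour exceeding the grid is a configuration error", {
  expect_error(phantom_spec(grid_shape = c(30, 30, 30),
                            spacing_mm = c(1, 1, 1),
                            tumor_axes_mm = c(14, 14, 14)),
               "margin")
})

test_that("cohort generation varies patients and seeds hierarchically", {
  ch <- generate_cohort(6, seed = 3, grid_shape = c(64, 64, 40),
                        spacing_mm = c(1, 1, 3))
  expect_length(ch, 6)
  vols <- vapply(ch, function(v) sum(v$mask), 0)
  expect_gt(length(unique(vols)), 1)  # non-degenerate size range
  d <- dice(ch[[1]]$mask, ch[[2]]$mask)
  expect_lt(d, 1)
  # extending the cohort leaves earlier patients untouched
  ch2 <- generate_cohort(8, seed = 3, grid_shape = c(64, 64, 40),
                         spacing_mm = c(1, 1, 3))
  expect_identical(ch[[3]]$image, ch2[[3]]$image)
  expect_error(generate_cohort(0), "n must be")
  expect_error(generate_cohort(2, ranges = list(tumor_axes_mm = c(5))),
               "invalid range")
})

test_that("null survival simulation has concordance near 0.5", {
  x <- data.frame(f1 = rnorm(4000))
  out <- simulate_survival(x, c(f1 = 0), baseline_hazard = 0.1,
                           censor_rate = 0, seed = 4)
  expect_equal(harrell_c(out$time, out$event, x$f1), 0.5, tolerance = 0.02)
})

test_that("Cox regression recovers the simulated hazard coefficient", {
  set.seed(10)
  x <- data.frame(f1 = rnorm(2000))
  out <- simulate_survival(x, c(f1 = 1), baseline_hazard = 0.1,
                           censor_rate = 0, seed = 5)
  fit <- survival::coxph(survival::Surv(out$time, out$event) ~ scale(x$f1))
  expect_gt(coef(fit), 0.9)
  expect_lt(coef(fit), 1.1)
})

test_that("extreme censoring censors everything; unknown features error", {
  x <- data.frame(f1 = rnorm(50))
  out <- simulate_survival(x, c(f1 = 0.5), censor_rate = 1e9, seed = 6)
  expect_true(all(out$event == 0))
  expect_error(simulate_survival(x, c(nope = 1)), "unknown feature")
})
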