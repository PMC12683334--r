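# simulated modelling cohort: two hazard-driving features among noise
make_sim_cohort <- function(n = 300, n_noise = 10, beta = c(1, 1),
                            censor = 0.05, seed = 1, name = "sim") {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * (2 + n_noise)), n))
  names(x) <- c("f_true1", "f_true2",
                sprintf("f_noise%02d", seq_len(n_noise)))
  out <- simulate_survival(x, c(f_true1 = beta[1], f_true2 = beta[2]),
                           baseline_hazard = 0.1, censor_rate = censor,
                           seed = seed + 1)
  survival_dataset(x, out$time, out$event, name)
}

test_that("concordance matches exhaustive pair enumeration", {
  set.seed(51)
  tm <- rexp(30); ev <- rbinom(30, 1, 0.6); rk <- rnorm(30)
  expect_equal(harrell_c(tm, ev, rk), cindex_bruteforce(tm, ev, rk),
               tolerance = 1e-12)
  # and the survival package agrees on tie-free continuous data
  cc <- survival::concordance(survival::Surv(tm, ev) ~ rk,
                              reverse = TRUE)$concordance
  expect_equal(harrell_c(tm, ev, rk), unname(cc), tolerance = 1e-12)
  expect_equal(harrell_c(tm, ev, rep(1, 30)), 0.5)
  expect_equal(harrell_c(tm, rep(1, 30), -tm), 1)
  expect_error(harrell_c(c(1, 1), c(0, 0), c(1, 2)), "no usable pairs")
})

test_that("generalizability index reproduces hand arithmetic", {
  expect_equal(g_index(0.7, c(0.7, 0.7)), 0)
  expect_equal(g_index(0.8, c(0.7, 0.6)), 0.15)
  expect_equal(g_index(0.8, c(0.6, 0.7)), 0.15)  # permutation invariant
  expect_gte(g_index(0.5, c(0.9)), 0)
  expect_error(g_index(0.7, numeric(0)), "at least one")
})

test_that("univariate screening keeps signal and drops empty input", {
  ds <- make_sim_cohort(n = 500, seed = 52)
  kept <- univariate_screen(ds, c("f_true1", "f_true2", "f_noise01"))
  expect_true(all(c("f_true1", "f_true2") %in% kept))
  expect_identical(univariate_screen(ds, character(0)), character(0))
  tiny <- survival_dataset(data.frame(a = rnorm(8)), rexp(8),
                           rep(c(1, 0), 4), "tiny")
  expect_error(univariate_screen(tiny, "a"), ">= 10 events")
})

test_that("type-I error of the univariate screen is near alpha", {
  set.seed(53)
  rates <- vapply(1:3, function(rep) {
    x <- as.data.frame(matrix(rnorm(500 * 100), 500))
    names(x) <- sprintf("n%03d", 1:100)
    out <- simulate_survival(x[1], c(n001 = 0), censor_rate = 0.05,
                             seed = rep)
    ds <- survival_dataset(x, out$time, out$event, "null")
    length(univariate_screen(ds, names(x))) / 100
  }, 0)
  expect_lt(abs(mean(rates) - 0.05), 0.025)
})

test_that("bootstrap LASSO selection recovers the true features", {
  ds <- make_sim_cohort(n = 400, n_noise = 20, seed = 54)
  top <- lasso_frequency_select(ds, names(ds$features), n_bootstraps = 10,
                                k = 5, seed = 1)
  expect_length(top, 5)
  expect_true(all(c("f_true1", "f_true2") %in% top))
  trace <- attr(top, "selection_trace")
  expect_length(trace$per_bootstrap, 10)
  expect_identical(top[1:5],
                   lasso_frequency_select(ds, names(ds$features),
                                          n_bootstraps = 10, k = 5,
                                          seed = 1)[1:5])
  expect_error(lasso_frequency_select(ds, character(0)), "empty candidate")
})

test_that("final model recovers coefficients and scores new cohorts", {
  ds <- make_sim_cohort(n = 2000, n_noise = 2, censor = 0, seed = 55)
  model <- fit_final_model(ds, c("f_true1", "f_true2"))
  expect_equal(unname(model$beta), c(1, 1), tolerance = 0.15)
  model2 <- fit_final_model(ds, c("f_true1", "f_true2"))
  expect_identical(model$beta, model2$beta)
  # a feature equal to the true risk score approaches the attainable C
  lp <- as.numeric(scale(ds$features$f_true1) + scale(ds$features$f_true2))
  ds2 <- survival_dataset(data.frame(risk = lp), ds$time, ds$event, "o")
  m2 <- fit_final_model(ds2, "risk")
  c_obs <- c_index(m2, ds2)
  # the attainable maximum is the concordance of the true linear predictor
  expect_equal(c_obs, harrell_c(ds$time, ds$event, lp), tolerance = 1e-10)
  expect_gt(c_obs, 0.7)
  # collinear features fall back to a ridge fit with a warning
  ds3 <- survival_dataset(cbind(ds$features, dup = ds$features$f_true1),
                          ds$time, ds$event, "dup")
  expect_warning(fit_final_model(ds3, c("f_true1", "dup")), "ridge|collinear")
})

test_that("bootstrap C summarizes replicates reproducibly", {
  ds <- make_sim_cohort(n = 150, seed = 56)
  model <- fit_final_model(ds, c("f_true1", "f_true2"))
  b <- bootstrap_c(model, ds, n_boot = 100, seed = 2)
  expect_length(attr(b, "replicates"), 100)
  expect_lte(b[["ci_low"]], b[["mean"]]); expect_lte(b[["mean"]], b[["ci_high"]])
  expect_equal(b, bootstrap_c(model, ds, n_boot = 100, seed = 2))
  one <- survival_dataset(ds$features[1, , drop = FALSE], ds$time[1],
                          ds$event[1], "one")
  expect_error(bootstrap_c(model, one, 10, 1), "too small")
})

test_that("ICC preselection is strict, nested, and excludes shape", {
  db <- data.frame(
    feature_name = c("original_shape_MeshVolume",
                     sprintf("original_firstorder_F%02d_30_binCount", 1:5)),
    image_type = "original",
    family = c("shape", rep("firstorder", 5)),
    mean_icc = c(0.99, 0.95, 0.88, 0.80, 0.60, NaN),
    class = c("excellent", "excellent", "good", "good", "moderate",
              "degenerate"))
  sel_none <- preselect_by_icc(db, NA)
  expect_false(any(grepl("shape", sel_none)))
  expect_length(sel_none, 4)  # degenerate dropped
  thresholds <- c(0.9, 0.85, 0.8, 0.75, 0.5, NA)
  sels <- lapply(thresholds, function(t) preselect_by_icc(db, t))
  expect_length(sels, 6)
  for (i in 2:6) expect_true(all(sels[[i - 1]] %in% sels[[i]]))
  expect_length(preselect_by_icc(db, 1.0), 0)  # graceful empty set
  # strict inequality at the boundary
  expect_false("original_firstorder_F03_30_binCount" %in%
                 preselect_by_icc(db, 0.80))
})

test_that("feature-number sweep shows the nested-model pattern", {
  ds <- make_sim_cohort(n = 300, n_noise = 8, seed = 57)
  sp <- radrobust:::split_train_test(ds, 0.7, seed = 1)
  sweep_tab <- feature_number_sweep(sp$train, sp$test,
                                    names(ds$features), k_range = 1:6,
                                    seed = 3)
  expect_equal(nrow(sweep_tab), 6)
  # training C is non-decreasing in k up to optimizer tolerance
  expect_true(all(diff(sweep_tab$c_train) > -0.02))
  expect_error(feature_number_sweep(sp$train, sp$test, c("f_true1"),
                                    k_range = 1:5), "exceeds")
})
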