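test_that("one-way ICC matches hand-worked ANOVA cases", {
  expect_equal(icc_oneway(rbind(c(1, 1), c(2, 2), c(3, 3))), 1)
  # MSn = 0, MSW = 0.5: (0 - 0.5) / (0 + 1 * 0.5) = -1
  expect_equal(icc_oneway(rbind(c(1, 2), c(1, 2), c(1, 2))), -1)
  expect_true(is.nan(icc_oneway(matrix(2, 3, 4))))
  expect_error(icc_oneway(matrix(1:4, 1, 4)), "at least 2")
})

test_that("ICC agrees with the brute-force sum-of-squares oracle", {
  set.seed(31)
  for (rep in 1:200) {
    m <- matrix(rnorm(50, sd = runif(1, 0.5, 3)), 10, 5)
    expect_equal(icc_oneway(m), icc_bruteforce(m), tolerance = 1e-10)
    expect_equal(icc_oneway(m, "paper_literal"),
                 icc_bruteforce(m, literal = TRUE), tolerance = 1e-10)
  }
})

test_that("ICC is invariant under location and scale changes", {
  set.seed(32)
  m <- matrix(rnorm(60), 12, 5)
  base <- icc_oneway(m)
  expect_equal(icc_oneway(m + 100), base, tolerance = 1e-10)
  expect_equal(icc_oneway(m * -3.7), base, tolerance = 1e-10)
})

test_that("paper-literal denominator is systematically smaller", {
  set.seed(33)
  m <- matrix(rnorm(40) + rep(rnorm(8, sd = 2), 5), 8, 5)
  expect_lt(icc_oneway(m, "paper_literal"), icc_oneway(m))
})

test_that("resampled ICC summarizes rounds and is reproducible", {
  perfect <- matrix(rep(1:20, 5), 20, 5)
  r <- resampled_icc(perfect, 10, 10, seed = 1)
  expect_equal(unname(r), c(1, 1, 1))
  set.seed(34)
  m <- matrix(rnorm(200 * 6) + rep(rnorm(200, sd = 1), 6), 200, 6)
  r1 <- resampled_icc(m, 50, 20, seed = 2)
  expect_identical(r1, resampled_icc(m, 50, 20, seed = 2))
  expect_lte(r1[["ci_low"]], r1[["mean_icc"]])
  expect_lte(r1[["mean_icc"]], r1[["ci_high"]])
  # CI width shrinks on average when the subsample doubles
  widths <- vapply(1:10, function(s) {
    w1 <- resampled_icc(m, 40, 25, seed = s)
    w2 <- resampled_icc(m, 80, 25, seed = s)
    c(w1[["ci_high"]] - w1[["ci_low"]], w2[["ci_high"]] - w2[["ci_low"]])
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
  expect_error(resampled_icc(m, 500, 10), "exceeds")
})

test_that("repeatability classes follow the stated boundaries", {
  expect_equal(classify_icc(c(0.49, 0.5, 0.74, 0.75, 0.90, 0.901, 0.91)),
               c("poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent"))
  expect_equal(classify_icc(NaN), "degenerate")
  expect_equal(classify_icc(-0.3), "poor")
})

test_that("databank covers every feature once with parsed annotation", {
  ft <- make_feature_table(n_pat = 12, n_real = 4, seed = 41)
  db <- build_databank(ft, n_rounds = 5, seed = 1)
  feats <- setdiff(names(ft), c("patient", "realization"))
  expect_equal(nrow(db), length(feats))
  expect_false(any(duplicated(db$feature_name)))
  expect_true(all(db$class %in% c("poor", "moderate", "good", "excellent",
                                  "degenerate")))
  expect_identical(db, build_databank(ft, n_rounds = 5, seed = 1))
  # gap detection
  expect_error(build_databank(ft[-3, ]), "missing")
  s <- summary(db)
  expect_true(all(c("by_family", "by_image_type") %in% names(s)))
})

test_that("sample-size grid steps by 10 then by 100", {
  ft <- make_feature_table(n_pat = 25, n_real = 3, seed = 42)
  cv <- sample_size_curve(ft, sizes = c(10, 20), n_rounds = 10, seed = 1)
  expect_equal(sort(unique(cv$n)), c(10, 20))
  expect_equal(sum(cv$n == 10 & cv$feature == cv$feature[1]), 10)
  # default grid construction mirrors 10..100 by 10 then 100 steps
  ft2 <- make_feature_table(n_pat = 210, n_real = 2, seed = 43, n_feat = 1)
  cv2 <- sample_size_curve(ft2, n_rounds = 2, seed = 1)
  expect_equal(sort(unique(cv2$n)), c(seq(10, 100, 10), 200))
})

test_that("ICC estimates stabilize as the subsample grows", {
  ft <- make_feature_table(n_pat = 200, n_real = 4, seed = 44, n_feat = 3)
  cv <- sample_size_curve(ft, sizes = c(10, 150), n_rounds = 10, seed = 2)
  sds <- tapply(cv$icc, list(cv$feature, cv$n), sd)
  expect_lt(mean(sds[, "150"]), mean(sds[, "10"]))
})

test_that("top-variance ranking is order-invariant with lexical ties", {
  ft <- make_feature_table(n_pat = 30, n_real = 3, seed = 45, n_feat = 8)
  cv <- sample_size_curve(ft, sizes = c(10, 20, 30), n_rounds = 5, seed = 3)
  top <- top_variance_features(cv, 6)
  expect_length(top, 6)
  cv_shuf <- cv[sample.int(nrow(cv)), ]
  expect_identical(top_variance_features(cv_shuf, 6), top)
  # a constant-ICC feature ranks last
  const <- cv[cv$feature == cv$feature[1], ]
  const$feature <- "zzz_constant"; const$icc <- 0.8
  allf <- rbind(cv, const)
  ranked <- top_variance_features(allf, length(unique(allf$feature)))
  expect_equal(ranked[length(ranked)], "zzz_constant")
  expect_error(top_variance_features(cv, 99), "exceeds")
})
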