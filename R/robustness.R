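#' One-way random-effects intraclass correlation ICC(1,1)
#'
#' Repeatability of a single feature measured k times (unperturbed plus
#' perturbations) on each of n patients, from the one-way ANOVA
#' decomposition: `MSn` the between-patient mean square and `MSW` the
#' within-patient (residual) mean square. The default
#' `"shrout_fleiss"` variant returns `(MSn - MSW) / (MSn + (k-1) MSW)`;
#' the `"paper_literal"` variant uses `(k+1) MSW` in the denominator.
#'
#' @param m numeric matrix, patients in rows, measurements in columns
#'   (n >= 2, k >= 2).
#' @param formula_variant `"shrout_fleiss"` (default) or `"paper_literal"`.
#' @return ICC estimate; `NaN` when between- and within-patient variance
#'   are both zero (or any entry is non-finite, the degenerate-feature
#'   case).
#' @export
icc_oneway <- function(m, formula_variant = c("shrout_fleiss",
                                              "paper_literal")) {
  formula_variant <- match.arg(formula_variant)
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stopf("need at least 2 patients and 2 measurements")
  if (any(!is.finite(m))) return(NaN)
  rm_ <- rowMeans(m)
  msn <- k * var(rm_)
  msw <- sum((m - rm_)^2) / (n * (k - 1))
  if (msn == 0 && msw == 0) return(NaN)
  mult <- if (formula_variant == "shrout_fleiss") k - 1 else k + 1
  (msn - msw) / (msn + mult * msw)
}

#' Resampled mean ICC with percentile confidence interval
#'
#' Draws `n_rounds` subsamples of `n_patients` rows without replacement,
#' computes the ICC per round, and summarizes with the mean and the 2.5
#' and 97.5 percentiles.
#'
#' @param m feature measurement matrix (patients x measurements).
#' @param n_patients patients per resample (<= available rows).
#' @param n_rounds number of resampling rounds (>= 2).
#' @param seed RNG seed.
#' @param formula_variant passed to [icc_oneway()].
#' @return Named vector `c(mean_icc, ci_low, ci_high)`.
#' @export
resampled_icc <- function(m, n_patients = nrow(m), n_rounds = 10L, seed = 1L,
                          formula_variant = "shrout_fleiss") {
  m <- as.matrix(m)
  if (n_patients > nrow(m))
    stopf("n_patients (%d) exceeds available patients (%d)",
          n_patients, nrow(m))
  if (n_rounds < 2) stopf("n_rounds must be >= 2")
  iccs <- with_seed(seed, vapply(seq_len(n_rounds), function(r) {
    icc_oneway(m[sample.int(nrow(m), n_patients), , drop = FALSE],
               formula_variant)
  }, 0))
  iccs <- iccs[is.finite(iccs)]
  if (!length(iccs))
    return(c(mean_icc = NaN, ci_low = NaN, ci_high = NaN))
  c(mean_icc = mean(iccs),
    ci_low = quantile(iccs, 0.025, names = FALSE),
    ci_high = quantile(iccs, 0.975, names = FALSE))
}

#' Repeatability class of an ICC value
#'
#' Classes: poor (< 0.5), moderate (0.5 to < 0.75), good (0.75 to 0.90),
#' excellent (> 0.9); non-finite values are `"degenerate"`.
#'
#' @param icc numeric vector of ICC values.
#' @return Character vector of class labels.
#' @export
classify_icc <- function(icc) {
  ifelse(!is.finite(icc), "degenerate",
         ifelse(icc < 0.5, "poor",
                ifelse(icc < 0.75, "moderate",
                       ifelse(icc <= 0.90, "good", "excellent"))))
}

# Split a databank feature name into image type and class family
parse_feature_name <- function(nm) {
  parts <- strsplit(nm, "_", fixed = TRUE)
  data.frame(
    image_type = vapply(parts, `[`, "", 1),
    family = vapply(parts, `[`, "", 2))
}

#' Build the feature-robustness databank
#'
#' One record per feature: resampled mean ICC with 95% CI, repeatability
#' class, and the image-type/family annotation parsed from the feature
#' name. Degenerate features (non-finite ICC) are retained with class
#' `"degenerate"`.
#'
#' @param feature_table long table from [extract_cohort_features()]:
#'   columns `patient`, `realization`, then one column per feature; every
#'   patient must carry the identical realization set.
#' @param n_patients patients per resampling round (default: all).
#' @param n_rounds resampling rounds for the CI.
#' @param seed RNG seed.
#' @param formula_variant passed to [icc_oneway()].
#' @return Data frame of class `robustness_databank` with columns
#'   `feature_name`, `image_type`, `family`, `mean_icc`, `ci_low`,
#'   `ci_high`, `class`, `n`, `rounds`, `seed`.
#' @export
build_databank <- function(feature_table, n_patients = NULL, n_rounds = 10L,
                           seed = 1L, formula_variant = "shrout_fleiss") {
  fm <- feature_matrices(feature_table)
  n_patients <- n_patients %||% dim(fm)[1]
  feats <- dimnames(fm)[[3]]
  res <- vapply(feats, function(f)
    resampled_icc(fm[, , f], n_patients, n_rounds, seed, formula_variant),
    numeric(3))
  out <- data.frame(feature_name = feats, parse_feature_name(feats),
                    mean_icc = res[1, ], ci_low = res[2, ],
                    ci_high = res[3, ],
                    class = classify_icc(res[1, ]),
                    n = n_patients, rounds = n_rounds, seed = seed,
                    row.names = NULL)
  class(out) <- c("robustness_databank", "data.frame")
  out
}

# Reshape the long feature table into an n x k x n_features array
# (column 1 = unperturbed); errors listing any patient with missing
# realizations.
feature_matrices <- function(feature_table) {
  stopifnot(all(c("patient", "realization") %in% names(feature_table)))
  pats <- unique(feature_table$patient)
  reals <- unique(feature_table$realization)
  reals <- c("unperturbed", setdiff(reals, "unperturbed"))
  tab <- table(feature_table$patient, feature_table$realization)
  bad <- rownames(tab)[apply(tab != 1, 1, any)]
  if (length(bad))
    stopf("missing or duplicated realizations for patient(s): %s",
          paste(bad, collapse = ", "))
  feats <- setdiff(names(feature_table), c("patient", "realization"))
  key_p <- match(feature_table$patient, pats)
  key_r <- match(feature_table$realization, reals)
  arr <- array(NA_real_, c(length(pats), length(reals), length(feats)),
               dimnames = list(pats, reals, feats))
  for (f in feats)
    arr[cbind(key_p, key_r, match(f, feats))] <- feature_table[[f]]
  arr
}

#' Summarize a databank by repeatability class
#'
#' Counts of features per class within each feature family and each image
#' type group (original / LoG / wavelet).
#'
#' @param object a `robustness_databank`.
#' @param ... unused.
#' @return List with `by_family` and `by_image_type` contingency tables.
#' @export
summary.robustness_databank <- function(object, ...) {
  grp <- ifelse(grepl("^log-sigma", object$image_type), "log",
                ifelse(grepl("^wavelet", object$image_type), "wavelet",
                       "original"))
  list(by_family = table(object$family, object$class),
       by_image_type = table(grp, object$class))
}

#' Sample-size dependence of ICC estimates
#'
#' For each sample size, draws `n_rounds` random patient subsets and
#' recomputes each feature's ICC, tracing how the estimate stabilizes as
#' the cohort grows. Default sizes step by 10 up to 100 and by 100 beyond.
#'
#' @param feature_table long table from [extract_cohort_features()].
#' @param sizes patient counts; default `10, 20, ..., 100, 200, 300, ...`
#'   capped at the cohort size.
#' @param n_rounds resampling rounds per size.
#' @param seed RNG seed.
#' @param formula_variant passed to [icc_oneway()].
#' @return Long data frame `(feature, n, round, icc)`.
#' @export
sample_size_curve <- function(feature_table, sizes = NULL, n_rounds = 10L,
                              seed = 1L, formula_variant = "shrout_fleiss") {
  fm <- feature_matrices(feature_table)
  n_avail <- dim(fm)[1]
  if (is.null(sizes)) {
    sizes <- c(seq(10, 100, 10), seq(200, max(200, n_avail), 100))
    sizes <- sizes[sizes <= n_avail]
  }
  if (!length(sizes) || max(sizes) > n_avail)
    stopf("requested sizes exceed the cohort (%d patients)", n_avail)
  feats <- dimnames(fm)[[3]]
  out <- list()
  for (s in sizes) {
    draws <- with_seed(seed + s, lapply(seq_len(n_rounds), function(r)
      sample.int(n_avail, s)))
    for (r in seq_len(n_rounds)) {
      icc <- vapply(feats, function(f)
        icc_oneway(fm[draws[[r]], , f], formula_variant), 0)
      out[[length(out) + 1]] <- data.frame(feature = feats, n = s, round = r,
                                           icc = icc, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Features with the greatest ICC variation across sample sizes
#'
#' Ranks features by the variance of their mean ICC across the sample
#' sizes of a [sample_size_curve()] table and returns the top `top_n`
#' (ties broken lexicographically).
#'
#' @param curve_table output of [sample_size_curve()].
#' @param top_n how many features to return (default 6).
#' @return Character vector of feature names.
#' @export
top_variance_features <- function(curve_table, top_n = 6L) {
  mean_icc <- tapply(curve_table$icc, list(curve_table$feature,
                                           curve_table$n), mean)
  v <- apply(mean_icc, 1, var)
  if (top_n > length(v))
    stopf("top_n (%d) exceeds available features (%d)", top_n, length(v))
  names(v)[order(-v, names(v), na.last = TRUE)][seq_len(top_n)]
}
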