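#' Survival dataset for one cohort
#'
#' @param features data frame (patients x named features).
#' @param time follow-up durations (> 0).
#' @param event binary event indicators (1 = progression/death,
#'   0 = censored).
#' @param cohort_name label used in reports.
#' @return A `survival_dataset` object.
#' @export
survival_dataset <- function(features, time, event, cohort_name = "cohort") {
  features <- as.data.frame(features, check.names = FALSE)
  if (nrow(features) != length(time) || length(time) != length(event))
    stopf("features, time and event must have matching lengths")
  if (any(!is.finite(time)) || any(time <= 0)) stopf("all times must be > 0")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  structure(list(features = features, time = as.numeric(time),
                 event = as.integer(event), cohort_name = cohort_name),
            class = "survival_dataset")
}

#' Preselect features by databank repeatability
#'
#' Returns features whose mean ICC strictly exceeds `threshold`. Shape
#' features and degenerate records are excluded from the modelling pool;
#' `threshold = NA` (or `"none"` / 0) disables preselection and returns
#' every non-degenerate first-/high-order feature.
#'
#' @param databank a [build_databank()] result.
#' @param threshold ICC threshold, or `NA`/`"none"`/0 for no preselection.
#' @return Character vector of feature names.
#' @export
preselect_by_icc <- function(databank, threshold) {
  pool <- databank[databank$family != "shape" &
                     databank$class != "degenerate", ]
  none <- is.na(threshold) || identical(threshold, "none") ||
    (is.numeric(threshold) && threshold == 0)
  if (none) return(pool$feature_name)
  pool$feature_name[pool$mean_icc > threshold]
}

#' Univariate proportional-hazards screening
#'
#' Fits one single-covariate Cox model per candidate feature (z-scored
#' within the dataset) and keeps features with a Wald p-value below
#' `alpha`. Features that are constant or fail to converge are dropped
#' with a warning.
#'
#' @param ds a [survival_dataset()] with >= 10 events.
#' @param candidates candidate feature names.
#' @param alpha significance level (default 0.05).
#' @return Character vector of retained feature names.
#' @export
univariate_screen <- function(ds, candidates, alpha = 0.05) {
  p <- univariate_pvalues(ds, candidates)
  names(p)[!is.na(p) & p < alpha]
}

# Wald p-value of a single-covariate Cox fit per candidate (z-scored);
# constant or non-converging features get NA with a warning
univariate_pvalues <- function(ds, candidates) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (sum(ds$event) < 10) stopf("need >= 10 events for screening")
  if (!length(candidates)) return(stats::setNames(numeric(0), character(0)))
  missing <- setdiff(candidates, names(ds$features))
  if (length(missing)) stopf("unknown candidate feature(s): %s",
                             paste(missing, collapse = ", "))
  y <- survival::Surv(ds$time, ds$event)
  vapply(stats::setNames(candidates, candidates), function(f) {
    z <- ds$features[[f]]
    if (sd(z) == 0) { warning(sprintf("dropping constant feature %s", f))
      return(NA_real_) }
    z <- as.numeric(scale(z))
    p <- tryCatch({
      fit <- suppressWarnings(survival::coxph(y ~ z))
      summary(fit)$coefficients[1, "Pr(>|z|)"]
    }, error = function(e) NA_real_)
    if (is.na(p)) warning(sprintf("dropping non-converged feature %s", f))
    p
  }, 0)
}

#' Bootstrap LASSO-Cox frequency selection
#'
#' Repeatedly bootstraps the patients, fits an L1-penalized Cox model with
#' the penalty chosen by internal cross-validation, and records which
#' features keep non-zero coefficients. Features are ranked by selection
#' frequency (ties broken lexicographically) and the top `k` returned.
#'
#' @param ds a [survival_dataset()].
#' @param candidates candidate feature names (non-empty).
#' @param n_bootstraps bootstrap repetitions (default 10).
#' @param k how many features to return (default 5).
#' @param seed RNG seed.
#' @param allow_fewer return fewer than `k` when fewer features were ever
#'   selected instead of erroring.
#' @return Character vector of the top-k names, with the full
#'   `selection_trace` (per-bootstrap sets and frequency table) attached
#'   as an attribute.
#' @export
lasso_frequency_select <- function(ds, candidates, n_bootstraps = 10L,
                                   k = 5L, seed = 1L, allow_fewer = FALSE) {
  stopifnot(inherits(ds, "survival_dataset"))
  if (!length(candidates)) stopf("empty candidate set")
  if (n_bootstraps < 1) stopf("n_bootstraps must be >= 1")
  x <- scale(as.matrix(ds$features[candidates]))
  keepcol <- apply(is.finite(x), 2, all)
  x <- x[, keepcol, drop = FALSE]
  n <- nrow(x)
  sel_sets <- with_seed(seed, lapply(seq_len(n_bootstraps), function(b) {
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sum(ds$event[idx]) >= 5 && length(unique(idx)) >= 10) break
    }
    y <- survival::Surv(ds$time[idx], ds$event[idx])
    fold <- sample(rep_len(1:5, n))
    fit <- tryCatch(
      glmnet::cv.glmnet(x[idx, , drop = FALSE], y, family = "cox",
                        foldid = fold, standardize = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) return(character(0))
    cf <- as.matrix(coef(fit, s = "lambda.min"))
    rownames(cf)[cf[, 1] != 0]
  }))
  freq <- table(factor(unlist(sel_sets), levels = sort(colnames(x))))
  freq <- freq[freq > 0]
  if (!length(freq)) stopf("no feature was ever selected across bootstraps")
  ranked <- names(freq)[order(-as.numeric(freq), names(freq))]
  if (length(ranked) < k && !allow_fewer)
    stopf("only %d feature(s) ever selected, fewer than k = %d",
          length(ranked), k)
  top <- ranked[seq_len(min(k, length(ranked)))]
  attr(top, "selection_trace") <- list(
    candidates = candidates, per_bootstrap = sel_sets,
    frequency = freq, top = top)
  top
}

#' Fit the final multivariate proportional-hazards model
#'
#' Cox regression on features z-scored with *training* statistics; the
#' standardization parameters are stored and reused when scoring any other
#' cohort. Collinear fits fall back to a ridge-stabilized model with a
#' warning.
#'
#' @param ds_train training [survival_dataset()].
#' @param names features to include (non-empty).
#' @return A `pfs_model` (coefficients, centring/scaling, fitted coxph).
#' @export
fit_final_model <- function(ds_train, names) {
  stopifnot(inherits(ds_train, "survival_dataset"))
  if (!length(names)) stopf("empty feature set at modelling time")
  missing <- setdiff(names, colnames(ds_train$features))
  if (length(missing)) stopf("unknown feature(s): %s",
                             paste(missing, collapse = ", "))
  xm <- as.matrix(ds_train$features[names])
  ctr <- colMeans(xm)
  scl <- apply(xm, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(xm, 2, ctr), 2, scl, `/`)
  y <- survival::Surv(ds_train$time, ds_train$event)
  fit <- tryCatch(survival::coxph(y ~ z), warning = function(w)
    suppressWarnings(survival::coxph(y ~ z)))
  beta <- coef(fit)
  if (any(is.na(beta))) {
    warning("collinear features: ridge-stabilized fit used")
    rfit <- glmnet::glmnet(z, y, family = "cox", alpha = 0,
                           lambda = 1e-3, standardize = FALSE)
    beta <- as.numeric(coef(rfit))
  }
  structure(list(feature_names = names, center = ctr, scale = scl,
                 beta = stats::setNames(as.numeric(beta), names),
                 fit = fit),
            class = "pfs_model")
}

#' Linear risk score of a fitted model on a cohort
#'
#' @param model a `pfs_model`.
#' @param ds a [survival_dataset()] containing the model's features.
#' @return Numeric risk scores (higher = higher hazard).
#' @export
predict_risk <- function(model, ds) {
  stopifnot(inherits(model, "pfs_model"), inherits(ds, "survival_dataset"))
  xm <- as.matrix(ds$features[model$feature_names])
  z <- sweep(sweep(xm, 2, model$center), 2, model$scale, `/`)
  as.numeric(z %*% model$beta)
}

#' Harrell's concordance index
#'
#' Probability that, of a usable patient pair, the one with the higher
#' risk score experiences the event first. A pair is usable when the
#' earlier time is an observed event and the times differ; tied risk
#' scores count 0.5.
#'
#' @param time follow-up times.
#' @param event binary event indicators.
#' @param risk predicted risk scores.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  earlier <- outer(time, time, `<`) & (event == 1)
  usable <- sum(earlier)
  if (usable == 0) stopf("no usable pairs for concordance")
  conc <- sum(earlier & outer(risk, risk, `>`))
  ties <- sum(earlier & outer(risk, risk, `==`))
  (conc + 0.5 * ties) / usable
}

#' Concordance of a fitted model on a cohort
#'
#' @param model a `pfs_model`.
#' @param ds a [survival_dataset()].
#' @return Harrell's C in `[0, 1]`.
#' @export
c_index <- function(model, ds) {
  harrell_c(ds$time, ds$event, predict_risk(model, ds))
}

#' Bootstrap mean concordance with percentile CI
#'
#' Patient-level bootstrap of the evaluation cohort; the fitted model is
#' held fixed and re-scored on each replicate.
#'
#' @param model a `pfs_model`.
#' @param ds evaluation [survival_dataset()] (>= 2 patients).
#' @param n_boot bootstrap replicates (default 100).
#' @param seed RNG seed.
#' @return Named vector `c(mean, ci_low, ci_high)`; the replicate values
#'   are attached as attribute `"replicates"`.
#' @export
bootstrap_c <- function(model, ds, n_boot = 100L, seed = 1L) {
  stopifnot(inherits(ds, "survival_dataset"))
  n <- length(ds$time)
  if (n < 2) stopf("cohort too small to bootstrap")
  if (n_boot < 2) stopf("n_boot must be >= 2")
  risk <- predict_risk(model, ds)
  cs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(harrell_c(ds$time[idx], ds$event[idx], risk[idx]),
             error = function(e) NA_real_)
  }, 0))
  cs <- cs[is.finite(cs)]
  if (!length(cs)) stopf("no bootstrap replicate had usable pairs")
  out <- c(mean = mean(cs), ci_low = quantile(cs, 0.025, names = FALSE),
           ci_high = quantile(cs, 0.975, names = FALSE))
  attr(out, "replicates") <- cs
  out
}

#' Generalizability index
#'
#' Mean absolute gap between the training concordance and each external
#' validation cohort's concordance; lower values indicate a model whose
#' performance transports better.
#'
#' @param c_train training C index.
#' @param c_evs numeric vector of external-validation C indices (>= 1).
#' @return G index (>= 0).
#' @export
g_index <- function(c_train, c_evs) {
  if (!length(c_evs)) stopf("need at least one external validation cohort")
  mean(abs(c_train - c_evs))
}

# 70/30 split stratified by event status
split_train_test <- function(ds, prop = 0.7, seed = 1L) {
  idx <- with_seed(seed, {
    take <- logical(length(ds$time))
    for (e in unique(ds$event)) {
      grp <- which(ds$event == e)
      take[sample(grp, round(prop * length(grp)))] <- TRUE
    }
    take
  })
  subset_ds <- function(ds, sel, suffix) {
    survival_dataset(ds$features[sel, , drop = FALSE], ds$time[sel],
                     ds$event[sel], paste0(ds$cohort_name, suffix))
  }
  list(train = subset_ds(ds, idx, "_train"), test = subset_ds(ds, !idx, "_test"))
}

#' Run the ICC-threshold preselection experiment
#'
#' For each ICC threshold: preselect features from the databank, screen
#' them univariately on the training cohort, select the top-k by bootstrap
#' LASSO frequency, fit the multivariate Cox model, and evaluate
#' concordance (with bootstrap CIs) on train, internal test and every
#' external-validation cohort; summarize transportability with the G
#' index.
#'
#' @param databank a [build_databank()] result.
#' @param train training [survival_dataset()].
#' @param evs list of external-validation [survival_dataset()] objects.
#' @param test optional internal test set; by default a 70/30
#'   event-stratified split of `train` is used.
#' @param thresholds ICC thresholds; `NA` means no preselection.
#' @param n_bootstraps LASSO bootstraps per threshold.
#' @param k features per model.
#' @param n_boot_c bootstrap replicates for C-index CIs.
#' @param seed RNG seed.
#' @return Data frame with one row per threshold: selection counts, C
#'   indices (mean and CI), and G index (mean and CI over paired
#'   bootstrap replicates); selected features attached as attribute
#'   `"selections"`.
#' @export
run_threshold_experiment <- function(databank, train, evs, test = NULL,
                                     thresholds = c(0.9, 0.85, 0.8, 0.75,
                                                    0.5, NA),
                                     n_bootstraps = 10L, k = 5L,
                                     n_boot_c = 100L, seed = 1L) {
  if (!length(evs)) stopf("need at least one EV cohort")
  if (is.null(names(evs)))
    names(evs) <- vapply(evs, function(d) d$cohort_name, "")
  if (is.null(test)) {
    sp <- split_train_test(train, 0.7, seed)
    train <- sp$train; test <- sp$test
  }
  rows <- list(); selections <- list()
  for (ti in seq_along(thresholds)) {
    th <- thresholds[ti]
    lab <- if (is.na(th)) "none" else format(th)
    pool <- preselect_by_icc(databank, th)
    pool <- intersect(pool, colnames(train$features))
    if (!length(pool))
      stopf("threshold %s leaves an empty candidate pool", lab)
    screened <- univariate_screen(train, pool)
    if (!length(screened))
      stopf("univariate screening at threshold %s retained no feature", lab)
    top <- tryCatch(
      lasso_frequency_select(train, screened, n_bootstraps, k,
                             seed = seed + ti, allow_fewer = TRUE),
      error = function(e) {
        # sparse-selection washout (every bootstrap shrank all coefficients
        # to zero): fall back to the univariate ranking of the screened set
        warning(sprintf(
          "threshold %s: LASSO selected nothing; using univariate ranking",
          lab))
        p <- univariate_pvalues(train, screened)
        names(sort(p))[seq_len(min(k, length(screened)))]
      })
    model <- fit_final_model(train, top)
    ctr <- bootstrap_c(model, train, n_boot_c, seed = seed + 100 + ti)
    cte <- bootstrap_c(model, test, n_boot_c, seed = seed + 200 + ti)
    cev <- lapply(seq_along(evs), function(m)
      bootstrap_c(model, evs[[m]], n_boot_c, seed = seed + 300 + 10 * ti + m))
    names(cev) <- names(evs)
    c_train_pt <- c_index(model, train)
    c_ev_pt <- vapply(evs, function(d) c_index(model, d), 0)
    g_pt <- g_index(c_train_pt, c_ev_pt)
    # paired bootstrap replicates for the G CI
    nrep <- min(vapply(cev, function(x) length(attr(x, "replicates")), 0L),
                length(attr(ctr, "replicates")))
    g_rep <- vapply(seq_len(nrep), function(b)
      g_index(attr(ctr, "replicates")[b],
              vapply(cev, function(x) attr(x, "replicates")[b], 0)), 0)
    row <- data.frame(threshold = lab, n_preselected = length(pool),
                      n_screened = length(screened),
                      n_model = length(top),
                      c_train = c_train_pt,
                      c_train_lo = ctr[["ci_low"]],
                      c_train_hi = ctr[["ci_high"]],
                      c_test = c_index(model, test),
                      c_test_lo = cte[["ci_low"]],
                      c_test_hi = cte[["ci_high"]],
                      g = g_pt, g_mean = mean(g_rep),
                      g_lo = quantile(g_rep, 0.025, names = FALSE),
                      g_hi = quantile(g_rep, 0.975, names = FALSE))
    for (m in names(evs)) {
      row[[paste0("c_ev_", m)]] <- c_ev_pt[[m]]
      row[[paste0("c_ev_", m, "_lo")]] <- cev[[m]][["ci_low"]]
      row[[paste0("c_ev_", m, "_hi")]] <- cev[[m]][["ci_high"]]
    }
    rows[[ti]] <- row
    selections[[lab]] <- as.character(top)
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- selections
  class(out) <- c("generalizability_report", "data.frame")
  out
}

#' Model performance as a function of feature count
#'
#' Ranks candidates once by LASSO selection frequency on the training
#' cohort, then fits the top-k model for each k and records train/test
#' concordance and their gap.
#'
#' @param ds_train,ds_test training and test [survival_dataset()] objects.
#' @param candidates candidate feature names.
#' @param k_range feature counts to evaluate.
#' @param n_bootstraps LASSO bootstraps for the ranking.
#' @param seed RNG seed.
#' @return Data frame `(k, c_train, c_test, gap)`.
#' @export
feature_number_sweep <- function(ds_train, ds_test, candidates,
                                 k_range = 1:10, n_bootstraps = 10L,
                                 seed = 1L) {
  if (max(k_range) > length(candidates))
    stopf("k_range exceeds the candidate count")
  ranked <- lasso_frequency_select(ds_train, candidates, n_bootstraps,
                                   k = length(candidates), seed = seed,
                                   allow_fewer = TRUE)
  # features never selected: append alphabetically so every k is defined
  ranked <- c(ranked, sort(setdiff(candidates, ranked)))
  out <- lapply(k_range, function(kk) {
    model <- fit_final_model(ds_train, ranked[seq_len(kk)])
    ctr <- c_index(model, ds_train)
    cte <- c_index(model, ds_test)
    data.frame(k = kk, c_train = ctr, c_test = cte, gap = ctr - cte)
  })
  do.call(rbind, out)
}
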