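# First-order and texture feature formulas. Texture matrices come from the
# compiled kernels; GLCM/GLRLM features are computed per direction over the
# 13 unique 3D directions at Chebyshev distance 1 and averaged; zone,
# dependence and gray-tone-difference statistics use 26-connectivity.
# Degenerate (single-level) ROIs return the documented finite fallbacks
# (entropies 0, correlation-type features 1).

firstorder_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

glcm_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")

glrlm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

glszm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

gldm_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                 "Strength")

log2p <- function(p) ifelse(p > 0, log2(p), 0)

first_order_features <- function(values, labels_roi, bin_count, voxel_vol) {
  v <- values
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  qs <- quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inner <- v[v >= qs[1] & v <= qs[5]]
  p <- tabulate(labels_roi, nbins = bin_count) / n
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mu)^4) / m2^2 else 0
  out <- c(sum(v^2), voxel_vol * sum(v^2), -sum(p * log2p(p)),
           min(v), qs[1], qs[5], max(v), mu, qs[3], qs[4] - qs[2],
           max(v) - min(v), mean(abs(v - mu)),
           mean(abs(inner - mean(inner))), sqrt(mean(v^2)),
           skew, kurt, m2, sum(p^2))
  names(out) <- firstorder_names
  out
}

glcm_features_one <- function(P) {
  tot <- sum(P)
  p <- P / tot
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)  # symmetric: px == py
  mu <- sum(i * p)
  sigx <- sqrt(sum((i - mu)^2 * p))
  kd <- 0:(ng - 1)
  pdiff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), 0)
  ks <- 2:(2 * ng)
  psum <- vapply(ks, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(kd * pdiff)
  contrast <- sum((i - j)^2 * p)
  corr <- if (sigx > 0)
    (sum(i * j * p) - mu^2) / sigx^2 else 1
  hxy <- -sum(p * log2p(p))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2p(pxpy))
  hxy2 <- -sum(pxpy * log2p(pxpy))
  hx <- -sum(px * log2p(px))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  nz <- which(px > 0)
  mcc <- if (length(nz) > 1) {
    A <- p[nz, nz, drop = FALSE] / px[nz]
    B <- sweep(p[nz, nz, drop = FALSE], 2, px[nz], `/`)
    ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(min(ev[2], 1), 0))
  } else 1
  offd <- i != j
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * log2p(pdiff)),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offd] / (i[offd] - j[offd])^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(psum * log2p(psum)),
    SumSquares = sum((i - mu)^2 * p))
}

glcm_features <- function(counts) {
  vals <- vapply(seq_len(dim(counts)[3]), function(d) {
    P <- counts[, , d]
    if (sum(P) == 0) rep(NA_real_, 24) else glcm_features_one(P)
  }, numeric(24))
  out <- rowMeans(vals, na.rm = TRUE)
  names(out) <- glcm_names
  out
}

glrlm_features_one <- function(R, n_vox) {
  nr <- sum(R)
  p <- R / nr
  i <- row(p); l <- col(p)
  ri <- rowSums(R); cl <- colSums(R)
  pg <- rowSums(p); pl <- colSums(p)
  mu_g <- sum(row(p) * p); mu_l <- sum(col(p) * p)
  c(GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum((i - mu_g)^2 * p),
    HighGrayLevelRunEmphasis = sum(i^2 * p),
    LongRunEmphasis = sum(l^2 * p),
    LongRunHighGrayLevelEmphasis = sum(i^2 * l^2 * p),
    LongRunLowGrayLevelEmphasis = sum(l^2 * p / i^2),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    RunEntropy = -sum(p * log2p(p)),
    RunLengthNonUniformity = sum(cl^2) / nr,
    RunLengthNonUniformityNormalized = sum(cl^2) / nr^2,
    RunPercentage = nr / n_vox,
    RunVariance = sum((l - mu_l)^2 * p),
    ShortRunEmphasis = sum(p / l^2),
    ShortRunHighGrayLevelEmphasis = sum(i^2 * p / l^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * l^2)))
}

glrlm_features <- function(counts, n_vox) {
  vals <- vapply(seq_len(dim(counts)[3]), function(d) {
    R <- counts[, , d]
    if (sum(R) == 0) rep(NA_real_, 16) else glrlm_features_one(R, n_vox)
  }, numeric(16))
  out <- rowMeans(vals, na.rm = TRUE)
  names(out) <- glrlm_names
  out
}

glszm_features <- function(zones, n_vox) {
  # zones: matrix with columns (gray level, zone size)
  nz <- nrow(zones)
  if (nz == 0) stopf("no zones in ROI")
  g <- zones[, 1]; s <- zones[, 2]
  w <- rep(1 / nz, nz)
  # cell probabilities for the entropy (aggregate equal (g, s) cells)
  cell <- table(paste(g, s)) / nz
  mu_g <- sum(w * g); mu_s <- sum(w * s)
  by_g <- tapply(rep(1, nz), g, sum); by_s <- tapply(rep(1, nz), s, sum)
  out <- c(sum(by_g^2) / nz, sum(by_g^2) / nz^2,
           sum(w * (g - mu_g)^2), sum(w * g^2),
           sum(w * s^2), sum(w * g^2 * s^2), sum(w * s^2 / g^2),
           sum(w / g^2), sum(by_s^2) / nz, sum(by_s^2) / nz^2,
           sum(w / s^2), sum(w * g^2 / s^2), sum(w / (g^2 * s^2)),
           -sum(cell * log2(cell)), nz / n_vox, sum(w * (s - mu_s)^2))
  names(out) <- glszm_names
  out
}

gldm_features <- function(P) {
  nd <- sum(P)
  p <- P / nd
  i <- row(p); j <- col(p)
  ri <- rowSums(P); cj <- colSums(P)
  mu_g <- sum(i * p); mu_d <- sum(j * p)
  out <- c(-sum(p * log2p(p)), sum(cj^2) / nd, sum(cj^2) / nd^2,
           sum((j - mu_d)^2 * p), sum(ri^2) / nd, sum((i - mu_g)^2 * p),
           sum(i^2 * p), sum(j^2 * p), sum(i^2 * j^2 * p),
           sum(j^2 * p / i^2), sum(p / i^2), sum(p / j^2),
           sum(i^2 * p / j^2), sum(p / (i^2 * j^2)))
  names(out) <- gldm_names
  out
}

ngtdm_features <- function(ns) {
  n_i <- ns[, 1]; s_i <- ns[, 2]
  N <- sum(n_i)
  p <- n_i / N
  lev <- seq_along(p)
  act <- which(p > 0)
  ngp <- length(act)
  coarse_den <- sum(p * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  if (ngp > 1) {
    pi_ <- p[act]; li <- lev[act]; si <- s_i[act]
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * sum(s_i) / N
    busy_den <- sum(abs(outer(li * pi_, li * pi_, `-`)))
    busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    comp <- sum(abs(outer(li, li, `-`)) *
                  (outer(pi_ * si, pi_ * si, `+`)) /
                  outer(pi_, pi_, `+`)) / N
    strength_num <- sum(outer(pi_, pi_, `+`) * dif2)
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; comp <- 0; strength <- 0
  }
  out <- c(busyness, coarseness, comp, contrast, strength)
  names(out) <- ngtdm_names
  out
}

#' First-order and texture features of one image type
#'
#' Extracts the 93 first-order/high-order features from an image within an
#' intensity ROI: 18 first-order (continuous intensities, except the
#' discretization-based Entropy and Uniformity), 24 GLCM, 16 GLRLM,
#' 16 GLSZM, 14 GLDM and 5 NGTDM, using fixed-bin-count discretization
#' over the ROI range of *this* image.
#'
#' @param image 3D numeric array.
#' @param roi_mask binary intensity-ROI array.
#' @param spacing_mm voxel spacing (for total energy).
#' @param bin_count gray-level bins.
#' @param classes which classes to compute.
#' @return Named numeric vector (93 values for the full class set).
#' @export
intensity_texture_features <- function(image, roi_mask, spacing_mm,
                                       bin_count = 30L,
                                       classes = c("firstorder", "glcm",
                                                   "glrlm", "glszm", "gldm",
                                                   "ngtdm")) {
  box <- mask_bbox(roi_mask, pad = 1L)
  img <- crop_box(image, box)
  roi <- crop_box(roi_mask, box)
  d <- dim(img)
  labels <- discretize(img, roi, bin_count)
  lab_int <- array(as.integer(labels), d)
  inroi <- roi > 0
  n_vox <- sum(inroi)
  out <- numeric(0)
  if ("firstorder" %in% classes)
    out <- c(out, stats::setNames(
      first_order_features(img[inroi], labels[inroi], bin_count,
                           prod(spacing_mm)),
      paste0("firstorder_", firstorder_names)))
  ng <- as.integer(bin_count)
  if ("glcm" %in% classes)
    out <- c(out, stats::setNames(glcm_features(glcm13_cpp(lab_int, d, ng)),
                                  paste0("glcm_", glcm_names)))
  if ("glrlm" %in% classes)
    out <- c(out, stats::setNames(
      glrlm_features(glrlm13_cpp(lab_int, d, ng), n_vox),
      paste0("glrlm_", glrlm_names)))
  if ("glszm" %in% classes)
    out <- c(out, stats::setNames(
      glszm_features(glszm_cpp(lab_int, d, ng), n_vox),
      paste0("glszm_", glszm_names)))
  if ("gldm" %in% classes)
    out <- c(out, stats::setNames(gldm_features(gldm_cpp(lab_int, d, ng, 0)),
                                  paste0("gldm_", gldm_names)))
  if ("ngtdm" %in% classes)
    out <- c(out, stats::setNames(ngtdm_features(ngtdm_cpp(lab_int, d, ng)),
                                  paste0("ngtdm_", ngtdm_names)))
  out
}
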