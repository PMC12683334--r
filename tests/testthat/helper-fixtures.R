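# Shared fixtures: small, fast phantoms and digital solids built in code.

# isotropic noise-free sphere phantom (radius in mm == voxels)
sphere_phantom <- function(radius_mm = 10, spacing = c(1, 1, 1),
                           noise = 0, texture = 0, grid = NULL, seed = 1) {
  if (is.null(grid)) grid <- rep(2 * radius_mm + 14, 3) / spacing
  phantom_spec(grid_shape = grid, spacing_mm = spacing,
               tumor_axes_mm = rep(radius_mm, 3),
               noise_sigma_hu = noise, texture_amplitude_hu = texture,
               seed = seed)
}

# digital ball mask (array), radius in voxels
digital_ball <- function(r, spacing = c(1, 1, 1)) {
  n <- 2 * r + 7
  ctr <- (n + 1) / 2
  idx <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  inside <- with(idx, (i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r^2)
  array(as.integer(inside), c(n, n, n))
}

# small default-geometry phantom (anisotropic, textured, noisy)
small_phantom <- function(seed = 1, noise = 15) {
  generate_phantom(phantom_spec(grid_shape = c(64, 64, 40),
                                spacing_mm = c(1, 1, 3),
                                tumor_axes_mm = c(10, 10, 10),
                                noise_sigma_hu = noise, seed = seed))
}

# identity perturbation realization
identity_realization <- function() {
  list(tx_px = 0, ty_px = 0, angle_deg = 0, noise_multiplier = 0,
       noise_seed = 1L, contour_seed = 1L)
}

# synthetic long feature table: patient random effect + measurement noise,
# one column per fake feature (names follow the databank convention)
make_feature_table <- function(n_pat, n_real, seed = 1, n_feat = 5,
                               between_sd = 2, within_sd = 1) {
  set.seed(seed)
  pats <- sprintf("p%03d", seq_len(n_pat))
  reals <- c("unperturbed", as.character(seq_len(n_real)))
  out <- expand.grid(realization = reals, patient = pats,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  fams <- rep(c("firstorder", "glcm", "glszm"), length.out = n_feat)
  for (f in seq_len(n_feat)) {
    eff <- rnorm(n_pat, sd = between_sd * f / n_feat)
    out[[sprintf("original_%s_Fake%02d_30_binCount", fams[f], f)]] <-
      eff[match(out$patient, pats)] + rnorm(nrow(out), sd = within_sd)
  }
  out
}

# one-way ANOVA ICC by explicit sum-of-squares loops (independent oracle)
icc_bruteforce <- function(m, literal = FALSE) {
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ssb <- 0; ssw <- 0
  for (i in seq_len(n)) {
    mi <- mean(m[i, ])
    ssb <- ssb + k * (mi - gm)^2
    for (j in seq_len(k)) ssw <- ssw + (m[i, j] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  mult <- if (literal) k + 1 else k - 1
  (msb - msw) / (msb + mult * msw)
}

# O(n^2) Harrell concordance by explicit pair enumeration
cindex_bruteforce <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}
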