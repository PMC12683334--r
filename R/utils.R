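# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Hierarchical seed derivation: the first i draws are identical whatever n
# is, so extending a cohort never changes earlier patients' streams.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1D Gaussian kernel sampled at integer offsets, truncated at 4 sigma,
# normalized to unit sum.
gaussian_kernel <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Sampled second derivative of a Gaussian, zero-summed so that the response
# to a constant image is exactly zero.
gaussian_d2_kernel <- function(sigma_vox, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma_vox)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  k <- (x^2 - sigma_vox^2) / sigma_vox^4 * g
  k - mean(k)
}

# Separable Gaussian smoothing of a 3D array. FIR for small sigma; the
# recursive Young-van Vliet filter for large sigma where FIR kernels get
# long (the two agree to well under 1% of the signal range).
gaussian_smooth <- function(arr, sigma_vox, boundary = "replicate",
                            fir_limit = 4) {
  d <- dim(arr)
  stopifnot(length(d) == 3, length(sigma_vox) %in% c(1, 3))
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  mode <- match(boundary, c("replicate", "wrap", "reflect")) - 1L
  out <- arr
  for (axis in 0:2) {
    s <- sigma_vox[axis + 1]
    if (s <= 0) next
    if (s <= fir_limit) {
      out <- conv_axis_cpp(out, d, gaussian_kernel(s), axis, mode)
    } else {
      out <- yvv_axis_cpp(out, d, s, axis)
    }
  }
  out
}

# Crop box helpers -----------------------------------------------------

mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stopf("mask is empty")
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_box <- function(arr, box) {
  arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
      drop = FALSE]
}
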