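# Separable Gaussian smoothing on 3D arrays with zero extension.
# The discrete kernel is sampled at integer offsets, truncated at 4 sigma,
# and normalized to unit sum, so smoothing conserves total mass whenever the
# support stays at least a truncation radius away from the array boundary.

gaussian_kernel_1d <- function(sigma_vox, trunc = 4) {
  if (sigma_vox < 1e-8) return(1)
  r <- ceiling(trunc * sigma_vox)
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Shift a 3D array by s voxels along `axis`, filling with zeros.
shift_array <- function(a, s, axis) {
  if (s == 0) return(a)
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  if (abs(s) >= n) return(out)
  src <- dst <- lapply(d, seq_len)
  if (s > 0) {
    src[[axis]] <- seq_len(n - s)
    dst[[axis]] <- (s + 1):n
  } else {
    src[[axis]] <- (1 - s):n
    dst[[axis]] <- seq_len(n + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1) / 2
  if (r == 0) return(a * kernel)
  out <- array(0, dim(a))
  for (i in seq_along(kernel)) {
    s <- i - 1 - r
    if (kernel[i] > 0) out <- out + kernel[i] * shift_array(a, s, axis)
  }
  out
}

# sigma_vox: length-3 SDs in voxel units (may be 0 along an axis).
gaussian_smooth3 <- function(a, sigma_vox, trunc = 4) {
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis], trunc)
    if (length(k) > 1) a <- convolve_axis(a, k, axis)
  }
  a
}
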