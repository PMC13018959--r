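# Independent brute-force oracles and small fixture generators.
# Everything here is deliberately written as plain loops over voxels/pairs,
# separate from the vectorized implementations they check.

# exhaustive ordered-pair enumeration over all offsets (plus transposes)
oracle_glcm <- function(levels, weights, support, offsets, L) {
  M <- matrix(0, L, L)
  d <- dim(levels)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!support[i, j, k]) next
    for (r in seq_len(nrow(offsets))) {
      p2 <- c(i, j, k) + offsets[r, ]
      if (any(p2 < 1) || any(p2 > d)) next
      if (!support[p2[1], p2[2], p2[3]]) next
      w <- weights[i, j, k] * weights[p2[1], p2[2], p2[3]]
      a <- levels[i, j, k]; b <- levels[p2[1], p2[2], p2[3]]
      M[a, b] <- M[a, b] + w
      M[b, a] <- M[b, a] + w
    }
  }
  M
}

# per-voxel 26-neighbor dependence counting
oracle_ngldm <- function(levels, weights, support, alpha = 0) {
  d <- dim(levels)
  L <- max(levels)
  S <- matrix(0, L, 27)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!support[i, j, k]) next
    cnt <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      p2 <- c(i + di, j + dj, k + dk)
      if (any(p2 < 1) || any(p2 > d)) next
      if (!support[p2[1], p2[2], p2[3]]) next
      if (abs(levels[p2[1], p2[2], p2[3]] - levels[i, j, k]) <= alpha) cnt <- cnt + 1
    }
    S[levels[i, j, k], cnt + 1] <- S[levels[i, j, k], cnt + 1] + weights[i, j, k]
  }
  S
}

# classical two-way ANOVA ICC(C,1) with explicit sums-of-squares loops
oracle_icc_c1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0
  for (i in 1:n) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in 1:k) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (m[i, j] - grand)^2
  msr <- ss_rows / (n - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# Harrell's C by explicit double loop
oracle_cindex <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# dense direct 3D Gaussian convolution (non-separable triple loop)
oracle_gauss3 <- function(a, sigma_vox, trunc = 4) {
  d <- dim(a)
  k1 <- function(s) {
    if (s < 1e-8) return(1)
    r <- ceiling(trunc * s)
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k / sum(k)
  }
  kx <- k1(sigma_vox[1]); ky <- k1(sigma_vox[2]); kz <- k1(sigma_vox[3])
  rx <- (length(kx) - 1) / 2; ry <- (length(ky) - 1) / 2; rz <- (length(kz) - 1) / 2
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    acc <- 0
    for (a1 in -rx:rx) for (a2 in -ry:ry) for (a3 in -rz:rz) {
      p <- c(i - a1, j - a2, k - a3)
      if (any(p < 1) || any(p > d)) next
      acc <- acc + kx[a1 + rx + 1] * ky[a2 + ry + 1] * kz[a3 + rz + 1] *
        a[p[1], p[2], p[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

# small random discretized patch with random weights, for matrix oracles
random_level_patch <- function(seed, n = 4, L = 4) {
  set.seed(seed)
  d <- c(n, n, n)
  support <- array(runif(prod(d)) > 0.25, d)
  levels <- array(0L, d)
  levels[support] <- sample.int(L, sum(support), replace = TRUE)
  weights <- array(0, d)
  weights[support] <- runif(sum(support), 0.05, 1)
  list(levels = levels, L = as.integer(L), support = support, weights = weights,
       disc = list(levels = levels, L = as.integer(L), support = support,
                   weights = weights))
}

# small lumpy phantom for property sweeps
small_phantom <- function(seed, shape = 28, radius = 5, ...) {
  make_phantom(phantom_config(shape = rep(shape, 3),
                              radii_mm = rep(radius, 3),
                              lumpiness = 0.15, noise_sd = 8,
                              margin_vox = 6, seed = seed, ...))
}

dice <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))
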