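#' Membership-weighted first-order (intensity) features
#'
#' Classical first-order statistics generalized to continuous voxel
#' memberships: every sum over mask voxels becomes a membership-weighted sum
#' with normalized weights, so the statistics reduce exactly to their
#' unweighted forms when all memberships are 0/1, and are invariant to
#' rescaling all memberships by a common factor. Quantiles come from the
#' weighted empirical CDF (smallest intensity whose cumulative weight reaches
#' the probability). Energy keeps its classical extensive scale via the
#' support voxel count. Histogram entropy and uniformity use the
#' membership-weighted discretized histogram.
#'
#' @param image An `image_volume`.
#' @param mask A `membership_mask` on the same grid.
#' @param cfg A [discretization_config()] for the histogram features.
#' @return Named numeric vector of `stat_*` and `ih_*` features, with a
#'   `notes` attribute listing degenerate-value reasons (e.g. zero variance).
#' @export
weighted_first_order <- function(image, mask, cfg = discretization_config()) {
  disc <- discretize(image, mask, cfg)
  x <- image$data[disc$support]
  w <- mask$data[disc$support]
  W <- sum(w)
  if (W <= 0) abort("zero total membership weight over the support.")
  notes <- character()

  m <- sum(w * x) / W
  v <- sum(w * (x - m)^2) / W
  if (v > 0) {
    skew <- sum(w * (x - m)^3) / W / v^1.5
    kurt <- sum(w * (x - m)^4) / W / v^2 - 3  # excess kurtosis
  } else {
    skew <- NaN; kurt <- NaN
    notes <- c(notes, "zero variance: skewness/kurtosis undefined")
  }
  q <- weighted_quantile(x, w, c(0.1, 0.25, 0.5, 0.75, 0.9))
  msq <- sum(w * x^2) / W
  nvox <- sum(disc$support)

  # histogram features on the weighted discretized histogram
  lv <- disc$levels[disc$support]
  p <- as.vector(rowsum(w, lv)) / W
  p <- p[p > 0]
  out <- c(
    stat_Mean3D = m,
    stat_Variance3D = v,
    stat_Skewness3D = skew,
    stat_Kurtosis3D = kurt,
    stat_Median3D = unname(q[3]),
    stat_Minimum3D = min(x),
    stat_Maximum3D = max(x),
    stat_P10_3D = unname(q[1]),
    stat_P90_3D = unname(q[5]),
    stat_Range3D = max(x) - min(x),
    stat_IQR3D = unname(q[4] - q[2]),
    stat_MeanAbsoluteDeviation3D = sum(w * abs(x - m)) / W,
    stat_Energy3D = nvox * msq,
    stat_RootMeanSquare3D = sqrt(msq),
    ih_Entropy3D = -sum(p * log2(p)),
    ih_Uniformity3D = sum(p^2)
  )
  attr(out, "notes") <- notes
  out
}

# Smallest x with weighted CDF >= p; equals the type-1 sample quantile at
# equal weights.
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p - 1e-12)[1]], numeric(1))
}
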