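# The 13 unique 3D direction vectors at Chebyshev distance 1 (one from each
# antipodal pair of the 26-neighborhood).
glcm_offsets_3d <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dz > 0 | (d$dz == 0 & (d$dy > 0 | (d$dy == 0 & d$dx > 0)))
  as.matrix(d[keep, , drop = FALSE])
}

shift_vec <- function(a, d) {
  for (axis in 1:3) if (d[axis] != 0) a <- shift_array(a, d[axis], axis)
  a
}

#' Build a membership-weighted grey-level co-occurrence matrix
#'
#' For each ordered voxel pair `(p, p + d)` with both voxels in the mask
#' support, the pair weight `w(p) * w(p + d)` (product rule; `min` and
#' `mean` are available alternatives) is added to entry
#' `(level(p), level(p + d))`; the transpose is added too, so the matrix is
#' symmetric. All offsets are accumulated into a single merged matrix
#' (merged full-volume aggregation). With binary weights the raw entries are
#' the classical integer co-occurrence counts.
#'
#' @param disc Output of [discretize()].
#' @param offsets Integer matrix of displacement vectors (rows); defaults to
#'   the 13 unique distance-1 directions.
#' @param pair_weight `"product"` (default), `"min"` or `"mean"`.
#' @return List of class `weighted_glcm` with `raw` and `normalized` L-by-L
#'   matrices and the offsets used.
#' @export
build_weighted_glcm <- function(disc, offsets = glcm_offsets_3d(),
                                pair_weight = c("product", "min", "mean")) {
  pair_weight <- match.arg(pair_weight)
  if (is.null(dim(offsets))) offsets <- matrix(offsets, nrow = 1)
  if (nrow(offsets) == 0) abort("`offsets` must be nonempty.")
  L <- disc$L
  lv <- disc$levels
  w <- disc$weights
  s <- disc$support
  M <- matrix(0, L, L)
  for (r in seq_len(nrow(offsets))) {
    d <- offsets[r, ]
    # nb[p] = value at p + d  (shift by -d brings p+d onto p)
    lv_nb <- shift_vec(lv, -d)
    w_nb <- shift_vec(w, -d)
    s_nb <- shift_vec(s * 1, -d) > 0
    sel <- s & s_nb
    if (!any(sel)) next
    wp <- switch(pair_weight,
                 product = w[sel] * w_nb[sel],
                 min = pmin(w[sel], w_nb[sel]),
                 mean = (w[sel] + w_nb[sel]) / 2)
    idx <- lv[sel] + (lv_nb[sel] - 1L) * L
    acc <- rowsum(wp, idx)
    ii <- as.integer(rownames(acc))
    M[ii] <- M[ii] + acc[, 1]
  }
  raw <- M + t(M)
  tot <- sum(raw)
  if (tot <= 0) abort("no co-occurrences: support has no voxel pairs at the given offsets.")
  structure(list(raw = raw, normalized = raw / tot, offsets = offsets,
                 pair_weight = pair_weight),
            class = "weighted_glcm")
}

#' GLCM texture features
#'
#' Computes the co-occurrence feature set from the normalized symmetric
#' matrix: joint maximum/average/variance/entropy, contrast, dissimilarity,
#' inverse difference (plus normalized), inverse difference moment (plus
#' normalized), correlation, autocorrelation, cluster tendency/shade/
#' prominence, angular second moment, sum and difference average/variance/
#' entropy, and the two information measures of correlation. Entropies are
#' in bits. A single-level matrix has zero marginal variance and yields NaN
#' correlation (noted).
#'
#' @param glcm A `weighted_glcm` from [build_weighted_glcm()].
#' @return Named numeric vector of `glcm_*` features with a `notes` attribute.
#' @export
glcm_features <- function(glcm) {
  P <- glcm$normalized
  L <- nrow(P)
  i <- row(P); j <- col(P)
  pi_ <- rowSums(P)
  mu <- sum(seq_len(L) * pi_)
  sig2 <- sum((seq_len(L) - mu)^2 * pi_)
  notes <- character()

  joint_avg <- sum(i * P)
  nz <- P > 0
  hxy <- -sum(P[nz] * log2(P[nz]))
  pij <- outer(pi_, pi_)
  nz2 <- pij > 0
  hxy1 <- -sum((P * log2(pij))[nz2])
  hxy2 <- -sum((pij * log2(pij))[nz2])
  hx <- -sum(pi_[pi_ > 0] * log2(pi_[pi_ > 0]))

  if (sig2 > 0) {
    corr <- (sum(i * j * P) - mu^2) / sig2
  } else {
    corr <- NaN
    notes <- c(notes, "single grey level: correlation undefined")
  }
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else NaN
  # second information measure with natural-log entropies
  ic2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - hxy))))

  k_diff <- abs(i - j)
  pd <- vapply(0:(L - 1), function(k) sum(P[k_diff == k]), numeric(1))
  k_sum <- i + j
  ps <- vapply(2:(2 * L), function(k) sum(P[k_sum == k]), numeric(1))
  da <- sum((0:(L - 1)) * pd)
  sa <- sum((2:(2 * L)) * ps)
  ent_of <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  out <- c(
    glcm_JointMaximum3D = max(P),
    glcm_JointAverage3D = joint_avg,
    glcm_JointVariance3D = sum((i - joint_avg)^2 * P),
    glcm_JointEntropy3D = hxy,
    glcm_Contrast3D = sum((i - j)^2 * P),
    glcm_Dissimilarity3D = sum(abs(i - j) * P),
    glcm_InverseDifference3D = sum(P / (1 + abs(i - j))),
    glcm_InverseDifferenceNorm3D = sum(P / (1 + abs(i - j) / L)),
    glcm_InverseDifferenceMoment3D = sum(P / (1 + (i - j)^2)),
    glcm_InverseDifferenceMomentNorm3D = sum(P / (1 + (i - j)^2 / L^2)),
    glcm_Correlation3D = corr,
    glcm_Autocorrelation3D = sum(i * j * P),
    glcm_ClusterTendency3D = sum((i + j - 2 * mu)^2 * P),
    glcm_ClusterShade3D = sum((i + j - 2 * mu)^3 * P),
    glcm_ClusterProminence3D = sum((i + j - 2 * mu)^4 * P),
    glcm_AngularSecondMoment3D = sum(P^2),
    glcm_SumAverage3D = sa,
    glcm_SumVariance3D = sum(((2:(2 * L)) - sa)^2 * ps),
    glcm_SumEntropy3D = ent_of(ps),
    glcm_DifferenceAverage3D = da,
    glcm_DifferenceVariance3D = sum(((0:(L - 1)) - da)^2 * pd),
    glcm_DifferenceEntropy3D = ent_of(pd),
    glcm_InfoCorrelation1_3D = ic1,
    glcm_InfoCorrelation2_3D = ic2
  )
  attr(out, "notes") <- notes
  out
}
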