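# The full 26-connected neighborhood at Chebyshev distance 1.
ngldm_neighborhood_3d <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), , drop = FALSE])
}

#' Build a membership-weighted neighbouring grey-level dependence matrix
#'
#' For each support voxel `c`, the dependence count `k` is the number of
#' 26-neighbors inside the support whose grey level differs from `level(c)`
#' by at most `alpha`; neighbors outside the support never count. The
#' center membership `w(c)` is then accumulated into `s(level(c), k)`
#' (neighbors gate the count, only the center contributes mass). With binary
#' weights the entries are the classical integer dependence counts.
#'
#' @param disc Output of [discretize()].
#' @param alpha Integer level-difference tolerance (default 0).
#' @return List of class `weighted_ngldm` with `matrix` (L rows, columns for
#'   dependence counts 0..26), `alpha`, `total_weight`.
#' @export
build_weighted_ngldm <- function(disc, alpha = 0) {
  L <- disc$L
  lv <- disc$levels
  w <- disc$weights
  s <- disc$support
  if (!any(s)) abort("empty support.")
  nb <- ngldm_neighborhood_3d()
  dep <- array(0L, dim(lv))
  for (r in seq_len(nrow(nb))) {
    d <- nb[r, ]
    lv_nb <- shift_vec(lv, -d)
    s_nb <- shift_vec(s * 1, -d) > 0
    dep <- dep + (s_nb & abs(lv_nb - lv) <= alpha)
  }
  S <- matrix(0, L, 27)
  idx <- lv[s] + (dep[s]) * L  # column = k + 1
  acc <- rowsum(w[s], idx)
  ii <- as.integer(rownames(acc))
  S[ii] <- S[ii] + acc[, 1]
  structure(list(matrix = S, alpha = alpha, total_weight = sum(w[s]),
                 n_support = sum(s)),
            class = "weighted_ngldm")
}

#' NGLDM features
#'
#' The dependence-count percentage is the fraction of membership mass whose
#' voxel has at least one dependent neighbor. The remaining features come
#' from the matrix normalized by its total mass, with nonuniformities
#' rescaled by the support voxel count so that all features reduce to their
#' classical forms at binary weights and are invariant to rescaling the
#' memberships. Dependence counts `k` enter emphasis features as `k + 1` so
#' isolated voxels (`k = 0`) are well-defined.
#'
#' @param ngldm A `weighted_ngldm` from [build_weighted_ngldm()].
#' @return Named numeric vector of `ngldm_*` features.
#' @export
ngldm_features <- function(ngldm) {
  S <- ngldm$matrix
  N <- sum(S)
  p <- S / N
  kk <- matrix(0:(ncol(S) - 1), nrow(S), ncol(S), byrow = TRUE)
  pk <- colSums(p)   # dependence-count marginal
  pg <- rowSums(p)   # grey-level marginal
  nz <- p > 0
  nvox <- ngldm$n_support
  c(
    ngldm_DependenceCountPercentage3D = sum(S[, -1]) / ngldm$total_weight,
    ngldm_LowDependenceEmphasis3D = sum(p / (kk + 1)^2),
    ngldm_HighDependenceEmphasis3D = sum(p * (kk + 1)^2),
    ngldm_GrayLevelNonUniformity3D = nvox * sum(pg^2),
    ngldm_DependenceCountNonUniformity3D = nvox * sum(pk^2),
    ngldm_DependenceCountEntropy3D = -sum(p[nz] * log2(p[nz])),
    ngldm_DependenceCountEnergy3D = sum(p^2)
  )
}
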