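#' Correlation distance between features
#'
#' `d(f, g) = 1 - Pearson r` between the two features' patient vectors, in
#' \[0, 2\]. Zero-variance features cannot enter (filter with
#' [drop_zero_variance()] first).
#'
#' @param table Feature tibble (`patient_id` + numeric feature columns),
#'   at least 2 features and 3 patients.
#' @return A symmetric feature-by-feature distance matrix with zero diagonal.
#' @export
correlation_distance <- function(table) {
  x <- as.matrix(table[, setdiff(names(table), "patient_id"), drop = FALSE])
  if (ncol(x) < 2 || nrow(x) < 3) abort("need >= 2 features and >= 3 patients.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance features present: %s; drop them first.",
                  paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  d <- 1 - cor(x)
  diag(d) <- 0
  d
}

#' Drop zero-variance feature columns
#'
#' @param table Feature tibble.
#' @return The table without constant columns; dropped names in attribute
#'   `dropped`.
#' @export
drop_zero_variance <- function(table) {
  feats <- setdiff(names(table), "patient_id")
  bad <- feats[vapply(feats, function(f) {
    v <- table[[f]]
    any(!is.finite(v)) || sd(v) == 0
  }, logical(1))]
  out <- table[, setdiff(names(table), bad), drop = FALSE]
  attr(out, "dropped") <- bad
  out
}

#' Cluster features by correlation distance
#'
#' Agglomerative hierarchical clustering on the correlation-distance matrix,
#' cut so that features whose merge height is strictly below the threshold
#' share a cluster. A higher cluster count signifies lower redundancy
#' (higher relevance diversity) of the feature set.
#'
#' @param distances Distance matrix from [correlation_distance()].
#' @param threshold Dendrogram cut height (default 0.25).
#' @param linkage Linkage method: `"average"` (default), `"single"` or
#'   `"complete"`. Reported alongside the counts since the count depends
#'   on it.
#' @return A `cluster_solution` list: `labels` (named integer vector with
#'   contiguous ids from 1), `n_clusters`, `threshold`, `linkage`.
#' @export
cluster_features <- function(distances, threshold = 0.25,
                             linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  hc <- hclust(as.dist(distances), method = linkage)
  raw <- cutree(hc, h = threshold * (1 - 1e-9))
  # relabel to contiguous ids in first-appearance order
  labels <- setNames(match(raw, unique(raw)), names(raw))
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 threshold = threshold, linkage = linkage),
            class = "cluster_solution")
}

#' Cluster-count sweep over thresholds
#'
#' @param table Feature tibble.
#' @param thresholds Numeric vector of cut heights.
#' @param linkage Linkage method, see [cluster_features()].
#' @return A tibble `threshold`, `n_clusters`, `linkage`.
#' @export
cluster_count_sweep <- function(table, thresholds = seq(0.05, 0.95, by = 0.05),
                                linkage = "average") {
  d <- correlation_distance(drop_zero_variance(table))
  purrr::map_dfr(thresholds, function(h) {
    tibble(threshold = h,
           n_clusters = cluster_features(d, h, linkage)$n_clusters,
           linkage = linkage)
  })
}

#' Pick one representative feature per cluster
#'
#' The highest-ICC member of each cluster, ties broken lexicographically by
#' feature name.
#'
#' @param solution A `cluster_solution`.
#' @param icc_map Named numeric vector or a [feature_reliability()] tibble
#'   giving an ICC for every clustered feature.
#' @return Character vector of representative feature names (one per
#'   cluster, in cluster-id order).
#' @export
pick_representatives <- function(solution, icc_map) {
  if (is.data.frame(icc_map)) icc_map <- setNames(icc_map$icc, icc_map$feature)
  feats <- names(solution$labels)
  missing <- setdiff(feats, names(icc_map))
  if (length(missing)) abort(sprintf("no ICC for clustered features: %s",
                                     paste(missing, collapse = ", ")))
  vapply(seq_len(solution$n_clusters), function(cl) {
    members <- sort(feats[solution$labels == cl])  # lexicographic tie-break
    members[which.max(icc_map[members])]
  }, character(1))
}
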