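#' Max-relevance min-redundancy feature ranking for survival outcomes
#'
#' Greedy mRMR adapted to censored outcomes: relevance of a feature is the
#' distance of its univariate concordance from 0.5
#' (`|C(feature, survival) - 0.5|`), redundancy against the already-selected
#' set is the mean absolute Pearson correlation. At each step the candidate
#' maximizing relevance minus redundancy is added; ties break
#' lexicographically by feature name, making the ranking deterministic.
#'
#' @param table Feature tibble (`patient_id` + candidate features, already
#'   reliability-filtered and cluster-deduplicated).
#' @param survival Survival tibble (`patient_id`, `time`, `event`).
#' @return Character vector: all candidate features in selection order.
#' @export
mrmr_rank <- function(table, survival) {
  feats <- setdiff(names(table), "patient_id")
  if (length(feats) == 0) abort("empty candidate feature set.")
  sv <- survival[match(table$patient_id, survival$patient_id), ]
  rel <- vapply(feats, function(f) {
    abs(c_index(table[[f]], sv$time, sv$event) - 0.5)
  }, numeric(1))
  x <- as.matrix(table[, feats, drop = FALSE])
  cm <- abs(suppressWarnings(cor(x)))
  cm[!is.finite(cm)] <- 1  # constant features are maximally redundant
  selected <- character(0)
  remaining <- feats[order(-rel, feats)]  # seeds the first pick
  while (length(remaining) > 0) {
    red <- if (length(selected) == 0) rep(0, length(remaining)) else
      colMeans(cm[selected, remaining, drop = FALSE])
    score <- rel[remaining] - red
    best <- remaining[order(-score, remaining)][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}
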