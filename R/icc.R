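#' Intraclass correlation ICC(C,1)
#'
#' Single-measurement consistency ICC from the two-way random-effects
#' (subjects x raters) ANOVA decomposition:
#' `ICC = (MS_rows - MS_err) / (MS_rows + (k - 1) * MS_err)`, where
#' `MS_err` is the subject-by-rater interaction/residual mean square.
#' Consistency ICC ignores additive per-rater offsets, so a matrix whose
#' columns differ only by constants scores exactly 1.
#'
#' @param m Numeric matrix, rows = subjects (n >= 2), columns = raters or
#'   perturbation realizations (k >= 2). Rows containing NaN/NA are dropped
#'   with a note.
#' @return A tibble of class `icc_result` with columns `icc`, `category`,
#'   `ms_rows`, `ms_error`, `n`, `k`, `n_dropped`.
#' @export
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' icc_c1(x + rep(c(0, 5, 10), each = 10))$icc  # additive rater bias
icc_c1 <- function(m) {
  m <- as.matrix(m)
  dropped <- !stats::complete.cases(m) | apply(m, 1, function(r) any(!is.finite(r)))
  n_dropped <- sum(dropped)
  m <- m[!dropped, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort(sprintf("need n >= 2 and k >= 2 after NaN drops (got %d x %d).", n, k))
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm_ - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_rows + (k - 1) * ms_err
  icc <- if (denom <= 0) NaN else (ms_rows - ms_err) / denom
  tibble::new_tibble(
    tibble(icc = icc, category = icc_category(icc), ms_rows = ms_rows,
           ms_error = ms_err, n = n, k = k, n_dropped = n_dropped),
    class = "icc_result")
}

#' Reliability category of an ICC value
#'
#' Poor below 0.5, moderate in \[0.5, 0.75), good in \[0.75, 0.9),
#' excellent at and above 0.9; boundary values go to the higher category.
#' Non-finite values map to `"undefined"`.
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector of categories.
#' @export
icc_category <- function(icc) {
  out <- rep("undefined", length(icc))
  ok <- is.finite(icc)
  out[ok & icc < 0.5] <- "poor"
  out[ok & icc >= 0.5 & icc < 0.75] <- "moderate"
  out[ok & icc >= 0.75 & icc < 0.9] <- "good"
  out[ok & icc >= 0.9] <- "excellent"
  out
}

#' Feature reliability across perturbation realizations
#'
#' Builds, for every feature, the subjects-by-realizations measurement
#' matrix from a list of feature tables (one table per perturbation, all
#' sharing patients and feature columns) and computes ICC(C,1). Features
#' with ICC at or above `reliable_at` (default 0.75) are flagged reliable.
#'
#' @param tables List of feature tibbles (each `patient_id` + features).
#' @param reliable_at Reliability cut point (default 0.75).
#' @return A tibble with one row per feature: `feature`, `family`, `icc`,
#'   `category`, `reliable`, `n_used`, `n_dropped`.
#' @export
feature_reliability <- function(tables, reliable_at = 0.75) {
  stopifnot(length(tables) >= 2)
  ref_ids <- tables[[1]]$patient_id
  ref_feats <- setdiff(names(tables[[1]]), "patient_id")
  for (tb in tables[-1]) {
    if (!setequal(tb$patient_id, ref_ids) ||
        !setequal(setdiff(names(tb), "patient_id"), ref_feats)) {
      abort("perturbation tables disagree on patients or feature names.")
    }
  }
  aligned <- lapply(tables, function(tb) tb[match(ref_ids, tb$patient_id), ])
  purrr::map_dfr(ref_feats, function(f) {
    m <- vapply(aligned, function(tb) tb[[f]], numeric(length(ref_ids)))
    res <- tryCatch(icc_c1(m), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble(feature = f, family = feature_family(f), icc = NaN,
                    category = "undefined", reliable = FALSE,
                    n_used = 0L, n_dropped = length(ref_ids)))
    }
    tibble(feature = f, family = feature_family(f), icc = res$icc,
           category = res$category,
           reliable = is.finite(res$icc) && res$icc >= reliable_at,
           n_used = res$n, n_dropped = res$n_dropped)
  })
}

#' Count reliable features by family
#'
#' The stacked-bar report: total reliable features and the per-family
#' contributions.
#'
#' @param rel Output of [feature_reliability()].
#' @return A tibble `family`, `n_reliable`, `n_total`.
#' @export
reliable_by_family <- function(rel) {
  rel |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_reliable = sum(.data$reliable),
                     n_total = dplyr::n(), .groups = "drop")
}

#' Stratify patients by tumor voxel volume
#'
#' Half-open bins of 5,000 voxels: `[0, 5000)`, `[5000, 10000)`, ...; every
#' patient falls in exactly one stratum.
#'
#' @param patient_id Character vector of patient IDs.
#' @param volume_vox Positive numeric tumor volumes in voxels.
#' @param width Stratum width in voxels (default 5000).
#' @return A tibble `patient_id`, `volume_vox`, `stratum`, `lower`, `upper`.
#' @export
stratify_by_volume <- function(patient_id, volume_vox, width = 5000) {
  stopifnot(all(volume_vox > 0))
  lower <- floor(volume_vox / width) * width
  tibble(patient_id = patient_id, volume_vox = volume_vox,
         stratum = sprintf("[%gk, %gk)", lower / 1000, (lower + width) / 1000),
         lower = lower, upper = lower + width)
}
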