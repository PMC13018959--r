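#' Model-output reliability across perturbed validation sets
#'
#' Applies a fitted model to each perturbed realization of the validation
#' feature table, forming a patients-by-realizations matrix of risk scores,
#' and computes ICC(C,1) on it. A model that only uses
#' perturbation-invariant features scores exactly 1 regardless of how the
#' other features vary.
#'
#' @param fit A `fuzzrad_cox` model.
#' @param perturbed_tables List of feature tibbles (one per perturbation)
#'   aligned on the same validation patients.
#' @return An `icc_result` tibble, see [icc_c1()].
#' @export
model_output_icc <- function(fit, perturbed_tables) {
  ids <- perturbed_tables[[1]]$patient_id
  scores <- vapply(perturbed_tables, function(tb) {
    predict(fit, tb[match(ids, tb$patient_id), ])
  }, numeric(length(ids)))
  icc_c1(scores)
}

#' Repeated train/validation survival-modeling evaluation
#'
#' The full modeling loop, once per mask kind: candidate features are
#' selected cohort-level (reliability filter at ICC >= 0.75, then one
#' representative per correlation-distance cluster); each repeat draws an
#' event-stratified 7:3 train/validation split, ranks candidates by mRMR on
#' the training set, fits the penalized Cox model with internal 5-fold CV,
#' and records the validation C-index, the mean 1/3/5-year time-dependent
#' AUC, and (when perturbed tables are supplied) the ICC(C,1) of risk
#' scores across the perturbed validation sets. Mask kinds are compared
#' pairwise by two-sided Wilcoxon rank-sum tests on their C-index
#' distributions.
#'
#' @param features Named list (per mask kind) of feature tibbles.
#' @param survival Survival tibble (`patient_id`, `time`, `event`).
#' @param perturbed_features Optional named list (per mask kind) of lists of
#'   perturbed feature tibbles; enables the reliability filter and the
#'   output-ICC measurement. When absent, all non-constant features are
#'   candidates.
#' @param n_repeats Number of repeated splits (default 50).
#' @param seed Integer master seed; repeat r uses `seed + r`.
#' @param train_frac Training fraction (default 0.7).
#' @param sizes Model sizes swept in CV, see [fit_penalized_cox()].
#' @param cluster_threshold Correlation-distance cut (default 0.25).
#' @param reliable_at Reliability cut point (default 0.75).
#' @param alpha glmnet penalty mixing (default 0, ridge).
#' @return A `fuzzrad_experiment` object: `runs` (per-repeat tibble),
#'   `comparisons` (pairwise Wilcoxon), `candidates` (per mask), `seed`.
#' @export
run_experiment <- function(features, survival, perturbed_features = NULL,
                           n_repeats = 50, seed = 0L, train_frac = 0.7,
                           sizes = 2:15, cluster_threshold = 0.25,
                           reliable_at = 0.75, alpha = 0) {
  stopifnot(is.list(features), length(features) >= 1)
  masks <- names(features)
  survival <- validate_survival(survival)

  candidates <- lapply(masks, function(mk) {
    select_candidates(features[[mk]], perturbed_features[[mk]],
                      cluster_threshold, reliable_at)
  })
  names(candidates) <- masks

  runs <- list()
  for (r in seq_len(n_repeats)) {
    split <- make_split(survival, train_frac, seed + r)
    for (mk in masks) {
      tb <- features[[mk]]
      cand <- candidates[[mk]]
      run <- tryCatch({
        tr_tb <- tb[tb$patient_id %in% split$train, c("patient_id", cand)]
        va_tb <- tb[tb$patient_id %in% split$validation, c("patient_id", cand)]
        sv_tr <- survival[survival$patient_id %in% split$train, ]
        sv_va <- survival[match(va_tb$patient_id, survival$patient_id), ]
        ranked <- mrmr_rank(tr_tb, sv_tr)
        fit <- fit_penalized_cox(tr_tb, sv_tr, ranked = ranked, sizes = sizes,
                                 alpha = alpha, seed = seed + r)
        scores <- predict(fit, va_tb)
        ci <- c_index(scores, sv_va$time, sv_va$event)
        ta <- td_auc(scores, sv_va$time, sv_va$event)
        oicc <- NA_real_
        if (!is.null(perturbed_features[[mk]])) {
          pv <- lapply(perturbed_features[[mk]], function(pt) {
            pt[pt$patient_id %in% split$validation, ]
          })
          oicc <- model_output_icc(fit, pv)$icc
        }
        tibble(mask = mk, rep = r, ok = TRUE, c_index = ci,
               mean_auc = attr(ta, "mean_auc"), output_icc = oicc,
               n_features = length(fit$features),
               selected = list(fit$features), error = NA_character_)
      }, error = function(e) {
        tibble(mask = mk, rep = r, ok = FALSE, c_index = NA_real_,
               mean_auc = NA_real_, output_icc = NA_real_,
               n_features = NA_integer_, selected = list(character(0)),
               error = conditionMessage(e))
      })
      runs[[length(runs) + 1]] <- run
    }
  }
  runs <- dplyr::bind_rows(runs)

  comparisons <- NULL
  if (length(masks) >= 2) {
    prs <- utils::combn(masks, 2, simplify = FALSE)
    comparisons <- purrr::map_dfr(prs, function(p) {
      a <- runs$c_index[runs$mask == p[1] & runs$ok]
      b <- runs$c_index[runs$mask == p[2] & runs$ok]
      pv <- if (length(a) && length(b)) {
        suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
      } else NA_real_
      tibble(mask_a = p[1], mask_b = p[2],
             mean_c_a = mean(a), mean_c_b = mean(b), p_value = pv)
    })
  }
  structure(list(runs = runs, comparisons = comparisons,
                 candidates = candidates, seed = seed),
            class = "fuzzrad_experiment")
}

select_candidates <- function(table, perturbed, cluster_threshold, reliable_at) {
  tb <- drop_zero_variance(table)
  feats <- setdiff(names(tb), "patient_id")
  icc_map <- setNames(rep(1, length(feats)), feats)
  if (!is.null(perturbed)) {
    rel <- feature_reliability(perturbed, reliable_at = reliable_at)
    keep <- rel$feature[rel$reliable]
    keep <- intersect(keep, feats)
    if (length(keep) >= 2) {
      feats <- keep
      tb <- tb[, c("patient_id", feats)]
    }
    icc_map <- setNames(rel$icc, rel$feature)
  }
  if (length(feats) < 2) return(feats)
  sol <- cluster_features(correlation_distance(tb), threshold = cluster_threshold)
  pick_representatives(sol, icc_map[feats])
}

make_split <- function(survival, train_frac, seed) {
  with_seed(seed, {
    tr <- unlist(lapply(split(survival$patient_id, survival$event), function(ids) {
      sample(ids, round(train_frac * length(ids)))
    }))
    list(train = tr, validation = setdiff(survival$patient_id, tr))
  })
}

#' @export
print.fuzzrad_experiment <- function(x, ...) {
  cat(sprintf("<fuzzrad_experiment> %d repeats x %d masks (seed %d)\n",
              max(x$runs$rep), length(unique(x$runs$mask)), x$seed))
  print(glance(x))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `fuzzrad_experiment`.
#' @param ... Unused.
#' @method tidy fuzzrad_experiment
#' @export
tidy.fuzzrad_experiment <- function(x, ...) x$runs

#' @rdname run_experiment
#' @method glance fuzzrad_experiment
#' @export
glance.fuzzrad_experiment <- function(x, ...) {
  x$runs |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(mask = .data$mask) |>
    dplyr::summarise(n_ok = dplyr::n(),
                     mean_c_index = mean(.data$c_index),
                     sd_c_index = sd(.data$c_index),
                     mean_auc = mean(.data$mean_auc, na.rm = TRUE),
                     mean_output_icc = mean(.data$output_icc, na.rm = TRUE),
                     .groups = "drop")
}

#' Serialize an experiment summary to JSON
#'
#' Writes per-run records and pairwise comparisons, sufficient to
#' regenerate the box-plot style summaries.
#'
#' @param x A `fuzzrad_experiment`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_experiment_summary <- function(x, path) {
  out <- list(seed = x$seed,
              runs = dplyr::select(x$runs, -"selected"),
              selected = lapply(x$runs$selected, identity),
              comparisons = x$comparisons,
              candidates = x$candidates,
              summary = glance(x))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
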