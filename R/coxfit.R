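#' Fit a penalized proportional-hazards model with internal CV
#'
#' Ridge-penalized Cox regression (via glmnet; lasso/elastic-net through
#' `alpha`) on the top-ranked features. The number of features kept and the
#' penalty strength are chosen jointly by k-fold cross-validated concordance
#' on the training set: for each candidate model size the glmnet lambda path
#' is scored on held-out folds with Harrell's C, and the (size, lambda) pair
#' with the best CV concordance wins (ties prefer the smaller model and the
#' stronger penalty). Folds are stratified on the event indicator and
#' re-drawn (with a note) if any fold carries fewer than 2 events.
#'
#' @param table Training feature tibble (`patient_id` + features).
#' @param survival Survival tibble (`patient_id`, `time`, `event`).
#' @param ranked Feature names in rank order (e.g. from [mrmr_rank()]);
#'   computed with [mrmr_rank()] when `NULL`.
#' @param sizes Candidate model sizes swept in CV (default `2:15`, clipped
#'   to the number of candidates).
#' @param cv_folds Number of CV folds (default 5).
#' @param alpha glmnet elastic-net mixing (0 = ridge, default).
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `fuzzrad_cox` with elements `features`,
#'   `coefficients`, `lambda`, `alpha`, `cv_cindex`, `cv_grid`.
#' @export
fit_penalized_cox <- function(table, survival, ranked = NULL, sizes = 2:15,
                              cv_folds = 5, alpha = 0, seed = 0L) {
  sv <- survival[match(table$patient_id, survival$patient_id), ]
  if (any(is.na(sv$time))) abort("survival data missing for some patients.")
  if (sum(sv$event) < 2) abort("degenerate training set: fewer than 2 events.")
  if (is.null(ranked)) ranked <- mrmr_rank(table, sv)
  sizes <- sort(unique(pmin(sizes, length(ranked))))
  sizes <- sizes[sizes >= 1]
  y <- survival::Surv(sv$time, sv$event)
  folds <- make_event_folds(sv$event, cv_folds, seed)

  grid <- list()
  for (m in sizes) {
    X <- as.matrix(table[, ranked[seq_len(m)], drop = FALSE])
    if (m == 1) {
      # glmnet needs >= 2 columns; single-feature model is an unpenalized fit
      cvc <- mean(vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f
        cf <- coxph_coef1(X[tr, 1], sv$time[tr], sv$event[tr])
        c_index(cf * X[!tr, 1], sv$time[!tr], sv$event[!tr])
      }, numeric(1)))
      grid[[length(grid) + 1]] <- tibble(size = 1, lambda = 0, cv_cindex = cvc)
      next
    }
    path <- glmnet::glmnet(X, y, family = "cox", alpha = alpha)
    lambdas <- path$lambda
    fold_c <- matrix(NA_real_, cv_folds, length(lambdas))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr, ], family = "cox",
                            alpha = alpha, lambda = lambdas)
      lp <- predict(fit, newx = X[!tr, , drop = FALSE], s = lambdas)
      fold_c[f, ] <- apply(lp, 2, function(s) {
        tryCatch(c_index(s, sv$time[!tr], sv$event[!tr]),
                 error = function(e) NA_real_)
      })
    }
    cvc <- colMeans(fold_c, na.rm = TRUE)
    grid[[length(grid) + 1]] <- tibble(size = m, lambda = lambdas, cv_cindex = cvc)
  }
  grid <- dplyr::bind_rows(grid)
  best <- grid[order(-grid$cv_cindex, grid$size, -grid$lambda), ][1, ]

  feats <- ranked[seq_len(best$size)]
  X <- as.matrix(table[, feats, drop = FALSE])
  if (best$size == 1) {
    coefs <- setNames(coxph_coef1(X[, 1], sv$time, sv$event), feats)
  } else {
    fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                          lambda = sort(c(best$lambda, best$lambda * c(2, 0.5)),
                                        decreasing = TRUE))
    coefs <- setNames(as.numeric(coef(fit, s = best$lambda)), feats)
  }
  structure(list(features = feats, coefficients = coefs,
                 lambda = best$lambda, alpha = alpha,
                 cv_cindex = best$cv_cindex, cv_grid = grid, seed = seed),
            class = "fuzzrad_cox")
}

# event-stratified fold ids; re-draw if a fold has < 2 events
make_event_folds <- function(event, k, seed, max_tries = 25) {
  n <- length(event)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      folds <- integer(n)
      for (g in unique(event)) {
        idx <- which(event == g)
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      ev_per_fold <- vapply(seq_len(k), function(f) sum(event[folds == f]), numeric(1))
      if (all(ev_per_fold >= 2)) return(folds)
    }
    inform("fold stratification could not place >= 2 events per fold; using last draw.")
    folds
  })
}

coxph_coef1 <- function(x, time, event) {
  if (sd(x) == 0) return(0)
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ x,
                    control = survival::coxph.control(iter.max = 50)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x))
  }
  unname(coef(fit))
}

#' Risk scores from a fitted penalized Cox model
#'
#' @param object A `fuzzrad_cox` fit.
#' @param newdata Feature tibble containing the model's features.
#' @param ... Unused.
#' @return Numeric linear-predictor risk scores (higher = higher risk).
#' @export
predict.fuzzrad_cox <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  drop(X %*% object$coefficients)
}

#' @export
print.fuzzrad_cox <- function(x, ...) {
  cat(sprintf("<fuzzrad_cox> %d features, lambda = %.4g, CV C-index = %.3f\n",
              length(x$features), x$lambda, x$cv_cindex))
  invisible(x)
}

#' @rdname fit_penalized_cox
#' @param x A `fuzzrad_cox` fit.
#' @param ... Unused.
#' @method tidy fuzzrad_cox
#' @export
tidy.fuzzrad_cox <- function(x, ...) {
  tibble(term = x$features, estimate = unname(x$coefficients))
}

#' @rdname fit_penalized_cox
#' @method glance fuzzrad_cox
#' @export
glance.fuzzrad_cox <- function(x, ...) {
  tibble(n_features = length(x$features), lambda = x$lambda,
         alpha = x$alpha, cv_cindex = x$cv_cindex)
}
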