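noise_table <- function(ids, p, seed) {
  set.seed(seed)
  tb <- tibble::tibble(patient_id = ids)
  for (f in 1:p) tb[[sprintf("n%02d", f)]] <- rnorm(length(ids))
  tb
}

test_that("concordance index honors its tie and comparability conventions", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 1, 1, 1)
  expect_equal(c_index(c(5, 4, 3, 2, 1), time, event), 1)   # perfect ordering
  expect_equal(c_index(rep(2, 5), time, event), 0.5)        # all tied
  expect_equal(c_index(c(1, 2, 3, 4, 5), time, event), 0)   # reversed
  expect_error(c_index(1, 3, 0), "no comparable")
})

test_that("concordance equals brute-force pair enumeration and the survival package", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    time <- round(rexp(n, 0.3), 2)
    event <- rbinom(n, 1, 0.7)
    scores <- sample(round(rnorm(n), 1))  # ties possible
    if (sum(event) == 0 || length(unique(time)) == 1) next
    ci <- tryCatch(c_index(scores, time, event), error = function(e) NULL)
    or <- tryCatch(oracle_cindex(scores, time, event), error = function(e) NULL)
    expect_identical(is.null(ci), is.null(or))
    if (!is.null(ci)) expect_equal(ci, or, tolerance = 1e-12)
  }
  # cross-check against survival::concordance on a larger draw
  set.seed(11)
  n <- 80
  time <- rexp(n); event <- rbinom(n, 1, 0.6); sc <- rnorm(n)
  cc <- survival::concordance(survival::Surv(time, event) ~ sc, reverse = TRUE)
  expect_equal(c_index(sc, time, event), unname(cc$concordance), tolerance = 1e-10)
})

test_that("time-dependent AUC reduces to the binary AUC without censoring", {
  set.seed(12)
  n <- 120
  time <- rexp(n, 0.4)
  event <- rep(1, n)
  sc <- -time + rnorm(n, 0, 0.5)  # higher score ~ earlier death
  ta <- td_auc(sc, time, event, horizons = 1)
  status <- time <= 1
  # plain rank-based AUC of status vs score
  r <- rank(sc)
  auc <- (sum(r[status]) - sum(status) * (sum(status) + 1) / 2) /
    (sum(status) * sum(!status))
  expect_equal(ta$auc[1], auc, tolerance = 1e-10)

  # perfect separation -> AUC 1 at every horizon
  sc2 <- -time
  ta2 <- td_auc(sc2, time, event, horizons = c(0.5, 1, 2))
  expect_equal(ta2$auc, rep(1, 3))

  # random scores sit near 0.5
  set.seed(13)
  ta3 <- td_auc(rnorm(2000), rexp(2000, 0.4), rbinom(2000, 1, 0.8), horizons = 1)
  expect_lt(abs(ta3$auc[1] - 0.5), 0.05)

  # horizon beyond follow-up -> NaN
  ta4 <- td_auc(rnorm(20), runif(20, 0, 2), rep(1, 20), horizons = 10)
  expect_true(is.nan(ta4$auc[1]))
})

test_that("mRMR ranks a planted hazard feature first and penalizes duplicates", {
  co <- make_cohort(cohort_config(n_patients = 200, seed = 101), rasterize = FALSE)
  tb <- noise_table(co$truth$patient_id, 4, 200)
  tb$f_signal <- co$truth$heterogeneity
  r <- mrmr_rank(tb, co$survival)
  expect_identical(r[1], "f_signal")

  # the planted feature wins across many cohorts
  hits <- vapply(1:20, function(s) {
    cs <- make_cohort(cohort_config(n_patients = 200, seed = 100 + s),
                      rasterize = FALSE)
    tbs <- noise_table(cs$truth$patient_id, 4, 300 + s)
    tbs$f_signal <- cs$truth$heterogeneity
    mrmr_rank(tbs, cs$survival)[1] == "f_signal"
  }, logical(1))
  expect_gte(sum(hits), 18)

  # an exact duplicate column is maximally redundant and ranks last
  tb2 <- tb[, c("patient_id", "f_signal")]
  tb2$f_signal_copy <- tb2$f_signal
  tb2$weak <- rnorm(200)
  r2 <- mrmr_rank(tb2, co$survival)
  expect_identical(r2[1], "f_signal")
  expect_identical(r2[3], "f_signal_copy")

  expect_error(mrmr_rank(tb["patient_id"], co$survival), "empty candidate")
})

test_that("penalized Cox recovers a planted signal and is deterministic", {
  co <- make_cohort(cohort_config(n_patients = 300,
                                  hazard_coef = c(heterogeneity = log(3)),
                                  seed = 1), rasterize = FALSE)
  tb <- tibble::tibble(patient_id = co$truth$patient_id,
                       f_lp = co$truth$true_lp)
  ex <- run_experiment(list(m = tb), co$survival, n_repeats = 5, seed = 2,
                       sizes = 1)
  expect_gt(glance(ex)$mean_c_index, 0.7)

  tb2 <- noise_table(co$truth$patient_id, 3, 7)
  tb2$f_lp <- co$truth$true_lp
  f1 <- fit_penalized_cox(tb2, co$survival, seed = 5)
  f2 <- fit_penalized_cox(tb2, co$survival, seed = 5)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_identical(f1$features, f2$features)
})

test_that("all-noise features give chance-level validation concordance", {
  co <- make_cohort(cohort_config(n_patients = 300, seed = 5), rasterize = FALSE)
  tb <- noise_table(co$truth$patient_id, 5, 99)
  ex <- run_experiment(list(m = tb), co$survival, n_repeats = 10, seed = 3,
                       sizes = 2:5)
  expect_gt(glance(ex)$mean_c_index, 0.4)
  expect_lt(glance(ex)$mean_c_index, 0.6)
})

test_that("model output ICC is exactly 1 for perturbation-invariant features", {
  co <- make_cohort(cohort_config(n_patients = 60, seed = 8), rasterize = FALSE)
  tb <- noise_table(co$truth$patient_id, 3, 21)
  tb$f_inv <- co$truth$heterogeneity
  fit <- fit_penalized_cox(tb[, c("patient_id", "f_inv", "n01")], co$survival,
                           ranked = c("f_inv", "n01"), sizes = 2, seed = 1)
  # perturbations leave the model's features untouched, others vary freely
  perturbed <- lapply(1:20, function(k) {
    p <- tb
    p$n02 <- rnorm(60)
    p$n03 <- rnorm(60)
    p
  })
  expect_equal(model_output_icc(fit, perturbed)$icc, 1, tolerance = 1e-12)
})

test_that("the experiment loop is reproducible and serializable end to end", {
  co <- make_cohort(cohort_config(n_patients = 60, seed = 9), rasterize = FALSE)
  tb <- noise_table(co$truth$patient_id, 4, 31)
  tb$f_signal <- co$truth$heterogeneity
  ex1 <- run_experiment(list(bin = tb, fuzzy = tb), co$survival,
                        n_repeats = 2, seed = 4, sizes = 2:3)
  ex2 <- run_experiment(list(bin = tb, fuzzy = tb), co$survival,
                        n_repeats = 2, seed = 4, sizes = 2:3)
  expect_equal(tidy(ex1)$c_index, tidy(ex2)$c_index)
  expect_true(all(tidy(ex1)$ok))
  # identical feature tables -> identical C-index distributions -> p ~ 1
  expect_gt(ex1$comparisons$p_value[1], 0.95)
  f <- withr::local_tempfile(fileext = ".json")
  write_experiment_summary(ex1, f)
  js <- jsonlite::read_json(f)
  expect_identical(length(js$runs), 4L)

  # train and validation never overlap
  sp <- fuzzrad:::make_split(co$survival, 0.7, 123)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), co$survival$patient_id)
})
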