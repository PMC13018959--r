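#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the higher risk score
#' belongs to the patient with the earlier event. A pair is comparable when
#' the earlier time is an observed event and the times differ; tied risk
#' scores count 0.5. Computed by direct pair enumeration.
#'
#' @param scores Numeric risk scores (higher = higher risk).
#' @param time Survival/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Concordance in \[0, 1\].
#' @export
c_index <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  ok <- is.finite(scores) & is.finite(time)
  scores <- scores[ok]; time <- time[ok]; event <- event[ok]
  # comparable pairs: i has the (strictly) earlier time and an event
  dt <- outer(time, time, "<")
  comp <- dt & matrix(event == 1, length(time), length(time))
  if (!any(comp)) abort("no comparable pairs.")
  ds <- outer(scores, scores, "-")
  conc <- sum(comp & ds > 0) + 0.5 * sum(comp & ds == 0)
  conc / sum(comp)
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' Discrimination of survival status at fixed horizons: cases are patients
#' with an observed event at or before the horizon, controls are patients
#' still at risk beyond it. Case/control contributions are weighted by the
#' inverse probability of censoring (Kaplan-Meier estimate of the censoring
#' distribution), so the estimate is consistent under independent
#' censoring. Without censoring it reduces to the plain binary AUC of
#' status-at-horizon against score.
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival data as in [c_index()].
#' @param horizons Evaluation times (default `c(1, 3, 5)` years).
#' @return A tibble `horizon`, `auc` (NaN, with a note, when a horizon has
#'   no cases or no controls), plus attribute `mean_auc` over the finite
#'   horizons.
#' @export
td_auc <- function(scores, time, event, horizons = c(1, 3, 5)) {
  n <- length(time)
  # censoring distribution G(t) = P(C > t)
  Gfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  Gfun <- stats::stepfun(Gfit$time, c(1, Gfit$surv), right = FALSE)
  # left limit G(t-)
  Gminus <- function(t) vapply(t, function(ti) {
    prev <- Gfit$time < ti - 1e-12
    if (!any(prev)) 1 else Gfit$surv[max(which(prev))]
  }, numeric(1))
  out <- purrr::map_dfr(horizons, function(h) {
    case <- time <= h & event == 1
    ctrl <- time > h
    if (!any(case) || !any(ctrl)) return(tibble(horizon = h, auc = NaN))
    wc <- 1 / pmax(Gminus(time[case]), 1e-12)
    gt <- pmax(Gfun(h), 1e-12)
    wk <- rep(1 / gt, sum(ctrl))
    sc <- scores[case]; sk <- scores[ctrl]
    num <- sum(outer(wc, wk) * (outer(sc, sk, ">") + 0.5 * outer(sc, sk, "==")))
    tibble(horizon = h, auc = num / (sum(wc) * sum(wk)))
  })
  attr(out, "mean_auc") <- mean(out$auc[is.finite(out$auc)])
  out
}
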