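# Survival read-outs: Kaplan-Meier product-limit curves, two-group log-rank
# tests, Pearson trait correlation and the IPCW cumulative/dynamic
# time-dependent AUC. KM and log-rank delegate to the survival package; the
# time-dependent AUC estimator is implemented here.

DAYS_PER_YEAR <- 365.25

#' Kaplan-Meier product-limit curve
#'
#' Standard convention: censorings at an event time are processed after the
#' events at that time.
#'
#' @param times follow-up times (>= 0).
#' @param events 0/1 event indicators.
#' @return a `survival_curve` data.frame: time (sorted unique event times),
#'   n_risk, n_event, survival.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) stop_sf("empty input")
  if (length(times) != length(events)) stop_sf("times/events length mismatch")
  if (any(times < 0)) stop_sf("negative times")
  events <- check_flag01(events, "events")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                       n_event = fit$n.event[keep],
                       survival = fit$surv[keep], row.names = NULL),
            class = c("survival_curve", "data.frame"))
}

#' Survival probability at given times
#' @param curve a `survival_curve`.
#' @param t times at which to evaluate S(t).
#' @return numeric vector.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    idx <- which(curve$time <= ti)
    if (!length(idx)) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard unstratified (O - E)^2 / V form with hypergeometric variance;
#' two-sided p from chi-square with 1 df. Zero events in total yields
#' chi2 = 0, p = 1 with a log note.
#'
#' @param times_1,events_1 first group.
#' @param times_2,events_2 second group.
#' @return list(chi2, p).
#' @export
logrank_test <- function(times_1, events_1, times_2, events_2) {
  if (!length(times_1) || !length(times_2)) stop_sf("both groups must be non-empty")
  ev1 <- check_flag01(events_1, "events_1")
  ev2 <- check_flag01(events_2, "events_2")
  if (sum(ev1) + sum(ev2) == 0) {
    sf_log("logrank", "no events in either group; p = 1")
    return(list(chi2 = 0, p = 1))
  }
  time <- c(times_1, times_2)
  event <- c(ev1, ev2)
  grp <- rep(1:2, c(length(times_1), length(times_2)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param values_x,values_y numeric vectors, n >= 3, no missing values.
#' @return list(r, p, n).
#' @export
trait_correlation <- function(values_x, values_y) {
  if (length(values_x) != length(values_y)) stop_sf("length mismatch")
  if (anyNA(values_x) || anyNA(values_y)) stop_sf("missing values; apply listwise deletion first")
  n <- length(values_x)
  if (n < 3) stop_sf("correlation needs n >= 3")
  if (stats::sd(values_x) == 0 || stats::sd(values_y) == 0) {
    stop_sf("zero variance in one of the vectors; correlation undefined")
  }
  ct <- stats::cor.test(values_x, values_y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' IPCW cumulative/dynamic time-dependent AUC
#'
#' For horizon t: cases are subjects with an event at or before t, controls
#' subjects still event-free strictly beyond t (`time > t`). Each case i is
#' weighted by 1/G(T_i-), each control j by 1/G(t), where G is the
#' Kaplan-Meier estimate of the censoring survival function; then
#' `AUC(t) = sum_ij w_i w_j [1(s_i > s_j) + 0.5 * 1(s_i = s_j)] /
#'  (sum_i w_i * sum_j w_j)`.
#'
#' @param scores marker values (higher = higher risk).
#' @param times,events follow-up data.
#' @param horizon evaluation time (same units as `times`).
#' @return a `time_roc` list: horizon, auc, n_cases, n_controls,
#'   weighting = "IPCW-KM".
#' @export
time_dependent_auc <- function(scores, times, events, horizon) {
  events <- check_flag01(events, "events")
  if (length(scores) != length(times)) stop_sf("scores/times length mismatch")
  if (horizon > max(times)) stop_sf("horizon %.1f beyond observed follow-up", horizon)
  is_case <- events == 1L & times <= horizon
  is_ctrl <- times > horizon
  if (!any(is_case)) stop_sf("no cases (events <= %.1f)", horizon)
  if (!any(is_ctrl)) stop_sf("no controls (time > %.1f)", horizon)
  # censoring survival G from the reversed-event KM
  gfit <- survival::survfit(survival::Surv(times, 1L - events) ~ 1)
  g_at <- function(t) {
    idx <- which(gfit$time <= t)
    if (!length(idx)) 1 else gfit$surv[max(idx)]
  }
  eps <- min(diff(sort(unique(c(0, times))))) / 2
  w_case <- 1 / vapply(times[is_case], function(ti) g_at(ti - eps), numeric(1))
  w_ctrl <- rep(1 / g_at(horizon), sum(is_ctrl))
  sc <- scores[is_case]; sq <- scores[is_ctrl]
  conc <- outer(sc, sq, ">") + 0.5 * outer(sc, sq, "==")
  auc <- sum(outer(w_case, w_ctrl) * conc) / (sum(w_case) * sum(w_ctrl))
  structure(list(horizon = horizon, auc = auc, n_cases = sum(is_case),
                 n_controls = sum(is_ctrl), weighting = "IPCW-KM"),
            class = "time_roc")
}

#' @export
print.time_roc <- function(x, ...) {
  cat(sprintf("time-dependent AUC at t = %.0f: %.3f (%d cases, %d controls, %s)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls, x$weighting))
  invisible(x)
}

#' Convert years to days
#' @param y years.
#' @export
years_to_days <- function(y) DAYS_PER_YEAR * y
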