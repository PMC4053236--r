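#' Kaplan-Meier product-limit survival estimate
#'
#' Nonparametric estimate of the survival function under right censoring,
#' with Greenwood's variance. Censorings tied with events at the same time
#' are handled after the events (the standard convention): a subject
#' censored at an event time is still at risk for that event.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return Object of class `ma_km`: list with `time` (distinct event
#'   times), `n_risk`, `n_event`, `surv`, `greenwood_var`, `std_err`,
#'   `n`, `n_events`, `n_censored`.
#' @export
#' @examples
#' km <- kaplan_meier(c(1, 2, 3, 3, 4), c(FALSE, TRUE, TRUE, TRUE, FALSE))
#' survival_at(km, 2)   # 0.75
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events))
  keep <- !is.na(times) & !is.na(events)
  times <- times[keep]
  events <- as.logical(events[keep])
  if (length(times) < 1) stop("need at least one subject", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)

  ev_times <- sort(unique(times[events]))
  n <- length(times)
  surv <- numeric(length(ev_times))
  n_risk <- integer(length(ev_times))
  n_event <- integer(length(ev_times))
  s <- 1
  gw <- 0
  greenwood <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk[i] <- sum(times >= t)              # censored at t still at risk
    n_event[i] <- sum(times == t & events)
    s <- s * (1 - n_event[i] / n_risk[i])
    gw <- gw + n_event[i] / (n_risk[i] * (n_risk[i] - n_event[i]))
    surv[i] <- s
    greenwood[i] <- if (is.finite(gw)) s^2 * gw else NA_real_
  }
  structure(
    list(time = ev_times, n_risk = n_risk, n_event = n_event, surv = surv,
         greenwood_var = greenwood, std_err = sqrt(greenwood),
         n = n, n_events = sum(events), n_censored = sum(!events)),
    class = "ma_km")
}

#' @export
print.ma_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, censored = %d\n",
              x$n, x$n_events, x$n_censored))
  if (length(x$time) > 0) {
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     survival = round(x$surv, 4),
                     std_err = round(x$std_err, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a survival curve at given times
#'
#' Right-continuous step-function evaluation: `S(t)` is the product-limit
#' value at the last event time at or before `t`; before the first event
#' `S(t) = 1`, beyond the last event time the last value carries forward.
#'
#' @param curve An `ma_km`.
#' @param t Non-negative times (vectorized).
#' @return Survival proportions in \[0, 1\].
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "ma_km"), all(t >= 0))
  if (length(curve$time) == 0) return(rep(1, length(t)))
  f <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  f(t)
}

#' Two-group log-rank test
#'
#' The standard one-degree-of-freedom log-rank statistic: at each distinct
#' event time the observed events in group A are compared with their
#' hypergeometric expectation given the risk sets, and the squared summed
#' difference is scaled by the summed hypergeometric variance. The p-value
#' is the chi-square upper tail with 1 df. If neither group has any event,
#' p = 1 by convention.
#'
#' @param times_a,events_a Follow-up and event indicators of group A.
#' @param times_b,events_b Same for group B.
#' @return List with `chi2`, `p`, and the observed/expected event counts.
#' @export
log_rank_test <- function(times_a, events_a, times_b, events_b) {
  ka <- !is.na(times_a) & !is.na(events_a)
  kb <- !is.na(times_b) & !is.na(events_b)
  ta <- times_a[ka]; ea <- as.logical(events_a[ka])
  tb <- times_b[kb]; eb <- as.logical(events_b[kb])
  if (length(ta) < 1 || length(tb) < 1) {
    stop("each group needs at least one subject", call. = FALSE)
  }
  ev_times <- sort(unique(c(ta[ea], tb[eb])))
  if (length(ev_times) == 0) {
    return(list(chi2 = 0, p = 1, observed = c(0, 0), expected = c(0, 0)))
  }
  O <- 0; E <- 0; V <- 0; Ob <- 0; Eb <- 0
  for (t in ev_times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t)
    d1 <- sum(ta == t & ea); d2 <- sum(tb == t & eb)
    n <- n1 + n2; d <- d1 + d2
    O <- O + d1
    Ob <- Ob + d2
    e1 <- d * n1 / n
    E <- E + e1
    Eb <- Eb + d - e1
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = c(O, Ob), expected = c(E, Eb))
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' The follow-up distribution estimated by treating censorings as events
#' and events as censorings; the median is the smallest time at which the
#' reverse curve drops to 0.5 or below.
#'
#' @param times,events As in [kaplan_meier()].
#' @return Median follow-up time (NA if the curve never reaches 0.5).
#' @export
median_followup <- function(times, events) {
  rk <- kaplan_meier(times, !as.logical(events))
  below <- which(rk$surv <= 0.5)
  if (length(below) == 0) NA_real_ else rk$time[below[1]]
}

#' Plot a Kaplan-Meier curve
#'
#' @param x An `ma_km`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ma_km <- function(x, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$surv, each = 2)[-(2 * length(x$surv))])
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = "time (months)",
                 ylab = "survival", ...)
  invisible(x)
}
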