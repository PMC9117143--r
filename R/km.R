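#' Kaplan-Meier product-limit estimate with Greenwood variance
#'
#' Fits the product-limit survival curve over the distinct event times.
#' Censorings at a time point are processed after the events at that time
#' (the standard convention: a patient censored at t is still at risk for
#' an event at t). The Greenwood variance of the survival probability,
#' \eqn{\widehat{Var}[S(t)] = S(t)^2 \sum_{t_j \le t} d_j / (n_j (n_j - d_j))},
#' is accumulated per event time on the plain survival scale. Optional
#' case weights (e.g. inverse-probability weights) replace the unit counts
#' in the risk and event sums.
#'
#' @param data Data frame with one row per patient.
#' @param time,event Columns (tidy-eval) holding the follow-up time in
#'   months and the event flag (1 = event, 0 = censored).
#' @param weights Optional column of positive case weights.
#' @return Object of class `btmb_km`: list with `steps` (tibble `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `var_survival`,
#'   `std_err`), `n`, `n_events`.
#' @export
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3), ev = 1)
#' tidy(km_fit(d, t, ev))$survival # 2/3, 1/3, 0
km_fit <- function(data, time, event, weights = NULL) {
  times <- dplyr::pull(data, {{ time }})
  events <- dplyr::pull(data, {{ event }})
  wq <- enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, length(times)) else dplyr::pull(data, !!wq)
  kaplan_meier(times, events, w)
}

kaplan_meier <- function(times, events, w = NULL) {
  if (length(times) == 0) stop_validation("no observations")
  if (any(times < 0)) stop_validation("survival times must be non-negative")
  if (!all(events %in% c(0, 1))) stop_validation("event flags must be 0/1")
  if (is.null(w)) w <- rep(1, length(times))
  if (any(w <= 0)) stop_validation("weights must be positive")

  ut <- sort(unique(times))
  # weighted risk set: everyone with follow-up >= t (censoring after events)
  n_risk <- vapply(ut, function(t) sum(w[times >= t]), numeric(1))
  n_event <- vapply(ut, function(t) sum(w[times == t & events == 1]), numeric(1))
  n_censor <- vapply(ut, function(t) sum(w[times == t & events == 0]), numeric(1))

  keep <- n_event > 0
  et <- ut[keep]
  nr <- n_risk[keep]
  de <- n_event[keep]
  surv <- cumprod(1 - de / nr)
  gw_term <- ifelse(nr > de, de / (nr * (nr - de)), NA_real_)
  var_s <- surv^2 * cumsum(gw_term)
  # S = 0 has zero estimated variance (the curve is exhausted)
  var_s[surv == 0] <- 0

  structure(
    list(
      steps = tibble(
        time = et, n_risk = nr, n_event = de,
        n_censor = vapply(et, function(t) sum(w[times == t & events == 0]), numeric(1)),
        survival = surv, var_survival = var_s, std_err = sqrt(var_s)
      ),
      censor_times = ut[n_censor > 0],
      n = length(times), n_events = sum(events == 1),
      max_time = max(times), weighted = !all(w == 1)
    ),
    class = "btmb_km"
  )
}

#' @export
print.btmb_km <- function(x, ...) {
  med <- km_median_ci(x)
  cat(sprintf(
    "<btmb_km> n = %d, events = %d, median = %s months (%s CI %s, %s)\n",
    x$n, x$n_events, fmt_na(med$median), paste0(100 * med$conf, "%"),
    fmt_na(med$conf_low), fmt_na(med$conf_high)
  ))
  invisible(x)
}

fmt_na <- function(x) ifelse(is.na(x), "NE", format(round_half_up(x, 2)))

# survival step-function lookup: S(t), Var[S(t)] at arbitrary t
km_at <- function(fit, t) {
  idx <- findInterval(t, fit$steps$time)
  s <- c(1, fit$steps$survival)[idx + 1]
  v <- c(0, fit$steps$var_survival)[idx + 1]
  list(survival = s, var_survival = v)
}

#' Brookmeyer-Crowley confidence interval for the median survival time
#'
#' The median is the first event time at which the survival curve drops to
#' 0.5 or below. Its interval inverts the chi-square test
#' \eqn{(S(t) - 0.5)^2 / \widehat{Var}[S(t)] \le \chi^2_1(conf)} over the
#' event-time grid and reports the hull of the acceptance set. A side the
#' data cannot bound (the curve never leaves the acceptance region before
#' follow-up ends) is reported as not estimable (`NA`).
#'
#' @param fit A `btmb_km` object.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `median`, `conf`, `conf_low`, `conf_high` (months;
#'   `NA` = not estimable).
#' @export
km_median_ci <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "btmb_km"))
  st <- fit$steps
  if (nrow(st) == 0) {
    return(tibble(median = NA_real_, conf = conf,
                  conf_low = NA_real_, conf_high = NA_real_))
  }
  med_idx <- which(st$survival <= 0.5)[1]
  median <- if (is.na(med_idx)) NA_real_ else st$time[med_idx]

  crit <- qchisq(conf, df = 1)
  stat <- ifelse(
    st$var_survival > 0,
    (st$survival - 0.5)^2 / st$var_survival,
    ifelse(st$survival == 0.5, 0, Inf)
  )
  in_set <- which(stat <= crit)
  if (length(in_set) == 0) {
    return(tibble(median = median, conf = conf,
                  conf_low = NA_real_, conf_high = NA_real_))
  }
  conf_low <- st$time[min(in_set)]
  # if the acceptance set runs to the last event time the right side is
  # open: follow-up ended while the curve was still consistent with 0.5
  conf_high <- if (max(in_set) == nrow(st) && st$survival[nrow(st)] > 0) {
    NA_real_
  } else {
    st$time[max(in_set)]
  }
  tibble(median = median, conf = conf, conf_low = conf_low, conf_high = conf_high)
}

#' Greenwood confidence interval for landmark survival
#'
#' Normal-approximation interval for S(landmark), with the Greenwood
#' variance. The default works on the plain survival scale,
#' \eqn{S \pm z\,\widehat{se}[S]} clipped to \[0, 1\]; the complementary
#' log-log transform is available by flag (it respects the \[0, 1\] range
#' without clipping and is preferable near the boundaries).
#'
#' @param fit A `btmb_km` object.
#' @param landmark Time in months (must not exceed the last follow-up).
#' @param conf Confidence level (default 0.95).
#' @param transform `"plain"` (default) or `"loglog"`.
#' @return Tibble with `landmark`, `survival`, `conf_low`, `conf_high`.
#' @export
greenwood_landmark_ci <- function(fit, landmark, conf = 0.95,
                                  transform = c("plain", "loglog")) {
  stopifnot(inherits(fit, "btmb_km"))
  transform <- match.arg(transform)
  if (landmark < 0) stop_validation("`landmark` must be non-negative")
  if (landmark > fit$max_time) {
    stop_validation("`landmark` lies beyond the last follow-up time")
  }
  at <- km_at(fit, landmark)
  s <- at$survival
  se <- sqrt(at$var_survival)
  z <- z_conf(conf)
  if (se == 0) {
    lo <- hi <- s
  } else if (transform == "plain") {
    lo <- max(0, s - z * se)
    hi <- min(1, s + z * se)
  } else {
    # se on the log(-log S) scale by the delta method
    se_ll <- se / abs(s * log(s))
    lo <- s^exp(z * se_ll)
    hi <- s^exp(-z * se_ll)
  }
  tibble(landmark = landmark, survival = s, conf = conf,
         conf_low = lo, conf_high = hi)
}
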