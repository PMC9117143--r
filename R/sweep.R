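#' Sweep efficacy statistics over bTMB cutoffs
#'
#' Recomputes the biomarker-stratified statistics at each score cutoff of a
#' grid (default 10 to 20 by 2): group sizes, objective response rates with
#' Blaker exact CIs, the CMH response p-value, the response-rate
#' difference with its 90% CI, and PFS/OS hazard ratios (high vs low,
#' HR < 1 favours high) with Wald CIs, log-rank p-values and
#' Brookmeyer-Crowley median CIs. Non-evaluable patients are excluded from
#' every row, so `n_high + n_low` is constant across cutoffs and `n_high`
#' is non-increasing in the cutoff.
#'
#' @param patients Tibble with columns `btmb_score`, `evaluable`,
#'   `confirmed_response`, `pfs_time`, `pfs_event`, `os_time`, `os_event`
#'   (e.g. a simulated cohort's clinical table joined to a
#'   [compute_btmb()] result).
#' @param cutoffs Integer cutoffs to sweep (default `seq(10, 20, by = 2)`).
#' @param conf_orr Confidence level for response-rate CIs (default 0.95).
#' @param conf_hr Confidence level for hazard-ratio CIs and rate
#'   differences (default 0.90, the trial convention).
#' @return A tibble of class `btmb_sweep`, one row per cutoff. Rows where a
#'   group is empty are flagged `estimable = FALSE` with `NA` ratios.
#' @export
btmb_cutoff_sweep <- function(patients, cutoffs = seq(10, 20, by = 2),
                              conf_orr = 0.95, conf_hr = 0.90) {
  req <- c("btmb_score", "evaluable", "confirmed_response",
           "pfs_time", "pfs_event", "os_time", "os_event")
  missing_cols <- setdiff(req, names(patients))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf(
      "`patients` is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  ev <- dplyr::filter(patients, .data$evaluable)
  if (nrow(ev) == 0) stop_validation("no evaluable patients")

  rows <- purrr::map_dfr(sort(cutoffs), function(cutoff) {
    high <- ev$btmb_score >= cutoff
    n_high <- sum(high)
    n_low <- sum(!high)
    x_high <- sum(ev$confirmed_response[high])
    x_low <- sum(ev$confirmed_response[!high])
    base <- tibble(
      cutoff = cutoff, n_high = n_high, n_low = n_low,
      x_high = x_high, x_low = x_low,
      estimable = n_high > 0 & n_low > 0
    )
    if (!base$estimable) {
      return(dplyr::bind_cols(base, empty_sweep_stats()))
    }
    orr_h <- orr_blaker(x_high, n_high, conf = conf_orr)
    orr_l <- orr_blaker(x_low, n_low, conf = conf_orr)
    cmh <- cmh_test(tibble(x1 = x_high, n1 = n_high, x2 = x_low, n2 = n_low))
    rd <- rate_difference_ci(x_high, n_high, x_low, n_low, conf = conf_hr)
    pfs <- sweep_survival(ev, high, "pfs_time", "pfs_event", conf_hr)
    os <- sweep_survival(ev, high, "os_time", "os_event", conf_hr)
    dplyr::bind_cols(
      base,
      tibble(
        orr_high_pct = orr_h$orr_pct, orr_high_low = orr_h$conf_low_pct,
        orr_high_high = orr_h$conf_high_pct,
        orr_low_pct = orr_l$orr_pct, orr_low_low = orr_l$conf_low_pct,
        orr_low_high = orr_l$conf_high_pct,
        orr_p = cmh$p_value,
        rate_diff_pct = rd$diff_pct, rate_diff_low = rd$conf_low_pct,
        rate_diff_high = rd$conf_high_pct
      ),
      stats::setNames(pfs, paste0("pfs_", names(pfs))),
      stats::setNames(os, paste0("os_", names(os)))
    )
  })
  class(rows) <- c("btmb_sweep", class(rows))
  attr(rows, "conf_orr") <- conf_orr
  attr(rows, "conf_hr") <- conf_hr
  rows
}

empty_sweep_stats <- function() {
  na <- NA_real_
  tibble(
    orr_high_pct = na, orr_high_low = na, orr_high_high = na,
    orr_low_pct = na, orr_low_low = na, orr_low_high = na,
    orr_p = na, rate_diff_pct = na, rate_diff_low = na, rate_diff_high = na,
    pfs_hr = na, pfs_hr_low = na, pfs_hr_high = na, pfs_logrank_p = na,
    pfs_median_high = na, pfs_median_high_low = na, pfs_median_high_high = na,
    pfs_median_low = na, pfs_median_low_low = na, pfs_median_low_high = na,
    os_hr = na, os_hr_low = na, os_hr_high = na, os_logrank_p = na,
    os_median_high = na, os_median_high_low = na, os_median_high_high = na,
    os_median_low = na, os_median_low_low = na, os_median_low_high = na
  )
}

sweep_survival <- function(ev, high, time_col, event_col, conf_hr) {
  d <- tibble(
    time = ev[[time_col]], event = ev[[event_col]],
    high = factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  )
  cox <- tryCatch(
    cox_hr(d, .data$time, .data$event, .data$high, conf = conf_hr),
    error = function(e) NULL, warning = function(w) NULL
  )
  lr <- suppressWarnings(logrank_test(d, .data$time, .data$event, .data$high))
  med_h <- km_median_ci(km_fit(d[d$high == "high", ], .data$time, .data$event))
  med_l <- km_median_ci(km_fit(d[d$high == "low", ], .data$time, .data$event))
  tibble(
    hr = if (is.null(cox)) NA_real_ else cox$hr,
    hr_low = if (is.null(cox)) NA_real_ else cox$conf_low,
    hr_high = if (is.null(cox)) NA_real_ else cox$conf_high,
    logrank_p = lr$p_value,
    median_high = med_h$median, median_high_low = med_h$conf_low,
    median_high_high = med_h$conf_high,
    median_low = med_l$median, median_low_low = med_l$conf_low,
    median_low_high = med_l$conf_high
  )
}
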