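#' Tidy a Kaplan-Meier fit
#'
#' @param x A `btmb_km` object.
#' @param ... Unused.
#' @return The per-event-time step tibble (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, `var_survival`, `std_err`).
#' @exportS3Method generics::tidy
tidy.btmb_km <- function(x, ...) x$steps

#' One-row summary of a Kaplan-Meier fit
#'
#' @param x A `btmb_km` object.
#' @param conf Confidence level for the median interval.
#' @param ... Unused.
#' @return Tibble with `n`, `n_events`, `median`, `conf_low`, `conf_high`.
#' @exportS3Method generics::glance
glance.btmb_km <- function(x, conf = 0.95, ...) {
  med <- km_median_ci(x, conf = conf)
  tibble(
    n = x$n, n_events = x$n_events, median = med$median,
    conf = conf, conf_low = med$conf_low, conf_high = med$conf_high
  )
}

#' Tidy a Cox fit
#'
#' @param x A `btmb_cox` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate` (log HR), `std.error`,
#'   `hr`, `conf_low`, `conf_high`, `p.value`.
#' @exportS3Method generics::tidy
tidy.btmb_cox <- function(x, ...) {
  tibble(
    term = "group", estimate = x$coef, std.error = x$se,
    hr = x$hr, conf = x$conf, conf_low = x$conf_low,
    conf_high = x$conf_high, p.value = x$p_value
  )
}

#' One-row summary of a Cox fit
#'
#' @param x A `btmb_cox` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_events`, `loglik`, `iter`, `converged`,
#'   `monotone`.
#' @exportS3Method generics::glance
glance.btmb_cox <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events, loglik = x$loglik,
    iter = x$iter, converged = x$converged, monotone = x$monotone
  )
}

#' Tidy an IPW comparison
#'
#' @param x A `btmb_ipw` object.
#' @param ... Unused.
#' @return The estimates tibble (unadjusted and adjusted rows).
#' @exportS3Method generics::tidy
tidy.btmb_ipw <- function(x, ...) x$estimates

#' One-row summary of an IPW comparison
#'
#' @param x A `btmb_ipw` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_truncated`, `stabilized`, `max_smd_before`,
#'   `max_smd_after`.
#' @exportS3Method generics::glance
glance.btmb_ipw <- function(x, ...) {
  tibble(
    n = x$n, n_truncated = x$n_truncated, stabilized = x$stabilized,
    max_smd_before = if (nrow(x$balance)) max(abs(x$balance$smd_before)) else NA_real_,
    max_smd_after = if (nrow(x$balance)) max(abs(x$balance$smd_after)) else NA_real_
  )
}
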