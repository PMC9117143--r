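#' Plot a Kaplan-Meier curve
#'
#' Step curve with a Greenwood pointwise confidence ribbon.
#'
#' @param object A `btmb_km` object.
#' @param conf Ribbon confidence level (default 0.95).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.btmb_km <- function(object, conf = 0.95, ...) {
  z <- z_conf(conf)
  d <- object$steps |>
    dplyr::mutate(
      lo = pmax(0, .data$survival - z * .data$std_err),
      hi = pmin(1, .data$survival + z * .data$std_err)
    )
  d0 <- dplyr::bind_rows(
    tibble(time = 0, survival = 1, lo = 1, hi = 1),
    d[c("time", "survival", "lo", "hi")]
  )
  # expand to a step function so the ribbon follows the curve:
  # value rows repeat (v0, v0, v1, v1, ...), times repeat (t0, t1, t1, ...)
  k <- nrow(d0)
  step <- d0[rep(seq_len(k), each = 2)[seq_len(2 * k - 1)], ]
  step$time <- rep(d0$time, each = 2)[-1]
  ggplot2::ggplot(step, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_line(linewidth = 0.7, colour = "steelblue4") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard ratios across bTMB cutoffs
#'
#' Mirrors the cutoff-sweep presentation: one hazard ratio (high vs low,
#' HR < 1 favours high) per cutoff with its confidence bar, for PFS and OS.
#'
#' @param object A `btmb_sweep` tibble from [btmb_cutoff_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.btmb_sweep <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble(
      endpoint = "PFS", cutoff = object$cutoff, hr = object$pfs_hr,
      lo = object$pfs_hr_low, hi = object$pfs_hr_high
    ),
    tibble(
      endpoint = "OS", cutoff = object$cutoff, hr = object$os_hr,
      lo = object$os_hr_low, hi = object$os_hr_high
    )
  )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$hr, y = factor(.data$cutoff))
  ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2
    ) +
    ggplot2::geom_point(shape = 18, size = 3, colour = "steelblue4") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::labs(
      x = "Hazard ratio (high vs low, log scale)", y = "bTMB cutoff"
    ) +
    ggplot2::theme_minimal()
}

#' Covariate balance (love) plot for an IPW comparison
#'
#' Standardised mean differences per screened factor before and after
#' weighting; adequate balance is conventionally |SMD| < 0.1.
#'
#' @param object A `btmb_ipw` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.btmb_ipw <- function(object, ...) {
  if (nrow(object$balance) == 0) {
    stop_validation("no balance table: supply `factors` to ipw_estimate()")
  }
  d <- object$balance |>
    dplyr::mutate(
      label = ifelse(is.na(.data$level), .data$factor,
                     paste0(.data$factor, ": ", .data$level))
    ) |>
    tidyr::pivot_longer(
      c("smd_before", "smd_after"),
      names_to = "stage", values_to = "smd"
    ) |>
    dplyr::mutate(
      stage = ifelse(.data$stage == "smd_before", "before", "after")
    )
  ggplot2::ggplot(
    d, ggplot2::aes(x = abs(.data$smd), y = .data$label, colour = .data$stage)
  ) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = "|standardised mean difference|", y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}
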