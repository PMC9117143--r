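#' Round half away from zero
#'
#' Journal-style rounding: exact halves move away from zero, so 14.55 prints
#' as 14.6 and -14.55 as -14.6, unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(16 / 1.1, 1) # 14.5
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# fraction -> percentage, journal rounding
as_pct <- function(x, digits = 1) round_half_up(100 * x, digits)

stop_validation <- function(msg, ...) {
  abort(msg, class = "btmb_validation_error", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "btmb_format_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "btmb_config_error", ...)
}

check_prob <- function(x, name) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    stop_validation(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

# two-sided normal quantile for a confidence level
z_conf <- function(conf) qnorm(1 - (1 - conf) / 2)
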