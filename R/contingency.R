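#' Cochran-Mantel-Haenszel test for response by group
#'
#' Tests association between response and binary group membership across one
#' or more strata. Each stratum is a 2x2 table given as responder counts and
#' totals per group. With a single stratum the statistic reduces to the
#' continuity-uncorrected Mantel-Haenszel chi-square, i.e. the Pearson
#' chi-square scaled by (N-1)/N. The two-sided p-value uses the chi-square
#' reference with 1 degree of freedom.
#'
#' @param strata Tibble (or data frame) with one row per stratum and columns
#'   `x1`, `n1` (responders and total, group 1) and `x2`, `n2` (group 2).
#' @return Tibble with `statistic`, `df`, `p_value`, `n_strata`.
#' @export
#' @examples
#' cmh_test(tibble::tibble(x1 = 10, n1 = 28, x2 = 5, n2 = 91)) # p < 0.0001
cmh_test <- function(strata) {
  req <- c("x1", "n1", "x2", "n2")
  if (!all(req %in% names(strata))) {
    stop_validation("`strata` needs columns x1, n1, x2, n2")
  }
  x1 <- as.numeric(strata$x1); n1 <- as.numeric(strata$n1)
  x2 <- as.numeric(strata$x2); n2 <- as.numeric(strata$n2)
  if (any(x1 < 0 | x2 < 0 | x1 > n1 | x2 > n2)) {
    stop_validation("counts must satisfy 0 <= x <= n in every stratum")
  }
  N <- n1 + n2
  m1 <- x1 + x2 # responder margin
  usable <- N > 1 & m1 > 0 & m1 < N & n1 > 0 & n2 > 0
  if (!any(usable)) stop_validation("no stratum with positive margins")
  a <- x1[usable]; n1u <- n1[usable]; n2u <- n2[usable]
  m1u <- m1[usable]; Nu <- N[usable]
  expected <- n1u * m1u / Nu
  variance <- n1u * n2u * m1u * (Nu - m1u) / (Nu^2 * (Nu - 1))
  stat <- sum(a - expected)^2 / sum(variance)
  tibble(
    statistic = stat, df = 1,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    n_strata = sum(usable)
  )
}

#' Response-rate difference with Wald confidence interval
#'
#' Difference in response proportions (group 1 minus group 2) in percentage
#' points, with an unpooled Wald normal-approximation interval. This is the
#' interval construction that reproduces trial-style rate-difference
#' figures at the 90% level.
#'
#' @param x1,n1 Responders and total in group 1.
#' @param x2,n2 Responders and total in group 2.
#' @param conf Confidence level (default 0.90, the trial convention for
#'   rate differences).
#' @return Tibble with `diff_pct`, `conf_low_pct`, `conf_high_pct` (and the
#'   same on the fraction scale without the `_pct` suffix).
#' @export
#' @examples
#' rate_difference_ci(10, 28, 5, 91) # 30.2 (14.8, 45.6) percentage points
rate_difference_ci <- function(x1, n1, x2, n2, conf = 0.90) {
  if (n1 <= 0 || n2 <= 0) stop_validation("n1 and n2 must be positive")
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- z_conf(conf)
  diff <- p1 - p2
  tibble(
    diff = diff, conf = conf,
    conf_low = diff - z * se, conf_high = diff + z * se,
    diff_pct = as_pct(diff),
    conf_low_pct = as_pct(diff - z * se),
    conf_high_pct = as_pct(diff + z * se)
  )
}

#' Odds ratio with Woolf logit confidence interval
#'
#' OR = (a d) / (b c) for the 2x2 table \[a b; c d\] (rows = groups,
#' columns = responder / non-responder), with the Woolf interval
#' \eqn{\exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. A zero cell
#' triggers the Haldane-Anscombe 0.5 continuity correction on all cells,
#' flagged in the output.
#'
#' @param a,b Responders and non-responders, group 1.
#' @param c,d Responders and non-responders, group 2.
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `or`, `conf_low`, `conf_high`, `corrected`.
#' @export
#' @examples
#' odds_ratio_ci(11, 18, 15, 104) # OR 4.2 (1.7, 10.7)
odds_ratio_ci <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_validation("cell counts must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- z_conf(conf)
  tibble(
    or = or, conf = conf,
    conf_low = exp(log(or) - z * se),
    conf_high = exp(log(or) + z * se),
    corrected = corrected
  )
}
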