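#' Two-group log-rank test
#'
#' Standard unweighted log-rank test over the pooled distinct event times.
#' At each event time t the group-1 event count is compared with its
#' hypergeometric expectation given the risk sets, and the chi-square
#' statistic is \eqn{(\sum (O_1 - E_1))^2 / \sum V}. The two-sided p-value
#' comes from the chi-square reference with 1 df, or — for small samples —
#' from the exact permutation distribution of the statistic over all
#' reassignments of group labels (`p_method = "permutation"`).
#'
#' @param data Data frame with one row per patient.
#' @param time,event,group Columns (tidy-eval): follow-up time, event flag
#'   (1 = event), and a two-level group label.
#' @param p_method `"asymptotic"` (default) or `"permutation"` (exact when
#'   the number of label reassignments is at most `max_permutations`,
#'   otherwise an error).
#' @param max_permutations Cap on exhaustive enumeration (default 200000).
#' @return Tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(data, time, event, group,
                         p_method = c("asymptotic", "permutation"),
                         max_permutations = 2e5) {
  p_method <- match.arg(p_method)
  times <- dplyr::pull(data, {{ time }})
  events <- dplyr::pull(data, {{ event }})
  grp <- dplyr::pull(data, {{ group }})
  g <- as.integer(factor(grp))
  if (length(unique(g[!is.na(g)])) != 2) {
    stop_validation("`group` must have exactly two levels")
  }
  is1 <- g == 1L

  res <- logrank_stat(times, events, is1)
  if (is.na(res$statistic)) {
    warn("no events in either group; log-rank statistic is 0")
    return(tibble(statistic = 0, df = 1, p_value = 1, method = p_method))
  }
  if (p_method == "asymptotic") {
    p <- pchisq(res$statistic, df = 1, lower.tail = FALSE)
  } else {
    n <- length(times)
    n1 <- sum(is1)
    n_comb <- choose(n, n1)
    if (n_comb > max_permutations) {
      stop_validation(sprintf(
        "exact permutation needs %.0f label assignments (cap %g)",
        n_comb, max_permutations
      ))
    }
    assignments <- combn(n, n1)
    perm_stats <- apply(assignments, 2, function(idx) {
      lab <- rep(FALSE, n)
      lab[idx] <- TRUE
      logrank_stat(times, events, lab)$statistic
    })
    p <- mean(perm_stats >= res$statistic - 1e-12)
  }
  tibble(statistic = res$statistic, df = 1, p_value = p, method = p_method)
}

# O-E / V accumulation over pooled event times; group1 = logical
logrank_stat <- function(times, events, group1) {
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0) {
    return(list(statistic = NA_real_, o_minus_e = 0, variance = 0))
  }
  o_minus_e <- 0
  v <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group1)
    e1 <- d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_minus_e <- o_minus_e + (d1 - e1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  list(statistic = stat, o_minus_e = o_minus_e, variance = v)
}

#' Schoenfeld power approximation for the log-rank test
#'
#' Power of the two-sided log-rank test for a two-group comparison with
#' hazard ratio `hr`, by Schoenfeld's formula: with d expected events and
#' biomarker-high prevalence p,
#' \eqn{power = \Phi(\sqrt{d\,p(1-p)}\,|\log hr| - z_{1-\alpha/2})}.
#'
#' @param n Number of patients.
#' @param prevalence_high Fraction in the biomarker-high group (0 < p < 1).
#' @param hr Hazard ratio to detect (> 0).
#' @param alpha_two_sided Two-sided significance level (default 0.10, the
#'   phase-2 convention).
#' @param event_fraction Expected fraction of patients with an event by the
#'   analysis time.
#' @return Power as a fraction in (0, 1).
#' @export
logrank_power <- function(n, prevalence_high, hr, alpha_two_sided = 0.10,
                          event_fraction = 0.9) {
  if (prevalence_high <= 0 || prevalence_high >= 1) {
    stop_validation("`prevalence_high` must lie strictly in (0, 1)")
  }
  if (hr <= 0) stop_validation("`hr` must be positive")
  check_prob(alpha_two_sided, "alpha_two_sided")
  check_prob(event_fraction, "event_fraction")
  d <- n * event_fraction
  z_a <- qnorm(1 - alpha_two_sided / 2)
  pnorm(sqrt(d * prevalence_high * (1 - prevalence_high)) * abs(log(hr)) - z_a)
}
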