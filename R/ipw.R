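#' Screen baseline factors for between-group imbalance
#'
#' Compares each baseline factor between two groups (e.g. MSAF < 1% vs
#' MSAF >= 1%) and flags those with p below `alpha` (default 0.15, a
#' deliberately permissive screen: the goal is to catch any factor that
#' could confound the group comparison, not to test hypotheses).
#' Continuous factors use the two-sample Wilcoxon rank-sum test;
#' categorical factors use the chi-square test, falling back to Fisher's
#' exact test when any expected cell count is below 5. Constant factors
#' are skipped with a warning.
#'
#' @param patients Tibble, one row per patient.
#' @param group Column (tidy-eval) with the two-level group indicator.
#' @param factors Character vector of factor columns to screen. Defaults to
#'   the standard baseline set present in the table among `age`, `sex`,
#'   `smoking`, `histology`, `pdl1_status`, `sld_mm`, `n_target_lesions`.
#' @param alpha Screening level (default 0.15).
#' @return Tibble with `factor`, `type`, `test`, `p_value`, `selected`.
#' @export
screen_factors <- function(patients, group, factors = NULL, alpha = 0.15) {
  check_prob(alpha, "alpha")
  g <- dplyr::pull(patients, {{ group }})
  g <- factor(g)
  if (nlevels(g) != 2 || min(table(g)) < 2) {
    stop_validation("`group` must have two levels with >= 2 patients each")
  }
  factors <- factors %||% intersect(
    c("age", "sex", "smoking", "histology", "pdl1_status", "sld_mm",
      "n_target_lesions"),
    names(patients)
  )
  rows <- purrr::map(factors, function(f) {
    v <- patients[[f]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(sprintf("factor `%s` is constant; skipped", f))
      return(NULL)
    }
    if (is.numeric(v)) {
      p <- suppressWarnings(wilcox.test(v ~ g)$p.value)
      tibble(factor = f, type = "continuous", test = "wilcoxon", p_value = p)
    } else {
      tab <- table(v, g)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- fisher.test(tab)$p.value
        tibble(factor = f, type = "categorical", test = "fisher", p_value = p)
      } else {
        p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
        tibble(factor = f, type = "categorical", test = "chi-square", p_value = p)
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  out$selected <- out$p_value < alpha
  out
}

#' Fit a propensity model for group membership
#'
#' Logistic regression (binomial GLM, fitted by iteratively reweighted
#' least squares) of group membership on the screened baseline factors.
#' Categorical factors keep their `"missing"` level as an ordinary
#' category, so patients without e.g. a PD-L1 result stay in the model.
#' With no factors the propensity is the group prevalence for everyone.
#'
#' @param patients Tibble, one row per patient.
#' @param group Column (tidy-eval): logical or two-level indicator of the
#'   modelled group (`TRUE` = the group whose probability is returned).
#' @param factors Character vector of covariate columns (typically
#'   `screen_factors()$factor[screen_factors()$selected]`).
#' @return `patients` with a `.propensity` column appended (probability of
#'   the `TRUE` group); the fitted `glm` is attached as attribute
#'   `"propensity_model"`.
#' @export
fit_propensity <- function(patients, group, factors = character()) {
  g <- dplyr::pull(patients, {{ group }})
  if (is.factor(g) || is.character(g)) g <- as.integer(factor(g)) - 1L
  g <- as.numeric(g)
  if (!all(g %in% c(0, 1))) stop_validation("`group` must be binary")

  if (length(factors) == 0) {
    patients$.propensity <- rep(mean(g), nrow(patients))
    return(patients)
  }
  mf <- patients[factors]
  mf <- dplyr::mutate(mf, dplyr::across(
    dplyr::where(~ is.character(.x) || is.factor(.x)),
    ~ factor(dplyr::coalesce(as.character(.x), "missing"))
  ))
  mf$.group <- g
  fml <- stats::as.formula(paste(
    ".group ~", paste(sprintf("`%s`", factors), collapse = " + ")
  ))
  fit <- suppressWarnings(glm(fml, data = mf, family = binomial()))
  p <- as.numeric(predict(fit, type = "response"))
  # separation matters when a patient's own-group probability vanishes:
  # that is the weight that diverges. A fitted 0 on the other side is a
  # sparse cell, not a weighting problem.
  diverging <- (g == 1 & p < 1e-8) | (g == 0 & p > 1 - 1e-8)
  if (!fit$converged || any(diverging)) {
    abort(
      "separation detected in the propensity model (a weight diverges); remove the offending factor",
      class = "btmb_separation_error"
    )
  }
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  patients$.propensity <- p
  attr(patients, "propensity_model") <- fit
  patients
}

#' Inverse-probability-weighted group comparison
#'
#' Builds inverse-probability weights from a propensity score (1/p for the
#' modelled group, 1/(1-p) otherwise; unstabilised by default, stabilised
#' by multiplying in the marginal group prevalences on request) and
#' recomputes the group comparison under weighting: weighted response
#' proportions, a weighted odds ratio with a robust (sandwich) interval,
#' weighted Kaplan-Meier PFS medians and a weighted Cox hazard ratio, and
#' the standardised mean difference of each screened factor before and
#' after weighting. Weights beyond the truncation percentiles are capped
#' and the cap count reported.
#'
#' @param patients Tibble with a `.propensity` column
#'   (see [fit_propensity()]), a response flag column, and optionally
#'   `pfs_time`/`pfs_event`.
#' @param group Column (tidy-eval): the modelled group indicator
#'   (`TRUE` = numerator group of the odds ratio).
#' @param response Column (tidy-eval) with the 0/1 response flag.
#' @param factors Character vector of factor columns for the balance table.
#' @param conf Confidence level for the adjusted odds ratio (default 0.95).
#' @param stabilized Use stabilised weights (default `FALSE`).
#' @param truncate Weight truncation percentiles (default `c(0.01, 0.99)`);
#'   `NULL` disables truncation.
#' @return Object of class `btmb_ipw`: list with `estimates` (unadjusted
#'   and adjusted response rates, OR, CI, p), `survival` (weighted medians
#'   and HR, when PFS columns are present), `balance` (per-factor SMDs
#'   before/after), `weights`, `n_truncated`.
#' @export
ipw_estimate <- function(patients, group, response, factors = character(),
                         conf = 0.95, stabilized = FALSE,
                         truncate = c(0.01, 0.99)) {
  if (!".propensity" %in% names(patients)) {
    stop_validation("`patients` must carry a `.propensity` column; run fit_propensity()")
  }
  p <- patients$.propensity
  check_prob(p, ".propensity")
  if (any(p <= 0 | p >= 1)) {
    stop_validation("propensity scores must lie strictly in (0, 1)")
  }
  g <- dplyr::pull(patients, {{ group }})
  if (is.factor(g) || is.character(g)) g <- as.integer(factor(g)) - 1L
  g <- as.logical(g)
  y <- dplyr::pull(patients, {{ response }})
  if (!all(y %in% c(0, 1))) stop_validation("`response` must be 0/1")

  w <- ifelse(g, 1 / p, 1 / (1 - p))
  if (stabilized) w <- w * ifelse(g, mean(g), 1 - mean(g))
  n_truncated <- 0L
  if (!is.null(truncate)) {
    bounds <- stats::quantile(w, truncate, names = FALSE)
    n_truncated <- sum(w < bounds[1] | w > bounds[2])
    w <- pmin(pmax(w, bounds[1]), bounds[2])
  }

  unadj_or <- odds_ratio_ci(
    sum(y[g]), sum(g) - sum(y[g]), sum(y[!g]), sum(!g) - sum(y[!g]),
    conf = conf
  )
  adj <- weighted_or(y, g, w, conf = conf)

  estimates <- tibble(
    adjusted = c(FALSE, TRUE),
    rate_group1 = c(mean(y[g]), weighted.mean(y[g], w[g])),
    rate_group2 = c(mean(y[!g]), weighted.mean(y[!g], w[!g])),
    or = c(unadj_or$or, adj$or),
    conf_low = c(unadj_or$conf_low, adj$conf_low),
    conf_high = c(unadj_or$conf_high, adj$conf_high),
    p_value = c(or_wald_p(unadj_or), adj$p_value)
  )

  survival_tab <- NULL
  if (all(c("pfs_time", "pfs_event") %in% names(patients))) {
    survival_tab <- ipw_survival(patients, g, w, conf = conf)
  }

  balance <- balance_table(patients, g, w, factors)

  structure(
    list(
      estimates = estimates, survival = survival_tab, balance = balance,
      weights = w, n_truncated = n_truncated, stabilized = stabilized,
      conf = conf, n = length(y)
    ),
    class = "btmb_ipw"
  )
}

or_wald_p <- function(or_row) {
  if (or_row$or <= 0 || !is.finite(or_row$or)) return(NA_real_)
  se <- (log(or_row$conf_high) - log(or_row$conf_low)) / (2 * z_conf(or_row$conf))
  2 * pnorm(-abs(log(or_row$or) / se))
}

# weighted logistic OR with sandwich (HC0) robust interval; quasibinomial
# family accepts the non-integer weighted counts without complaint
weighted_or <- function(y, g, w, conf) {
  d <- data.frame(y = y, g = as.numeric(g), w = w)
  fit <- suppressWarnings(
    glm(y ~ g, data = d, family = stats::quasibinomial(), weights = w)
  )
  vc <- sandwich::vcovHC(fit, type = "HC0")
  b <- coef(fit)[["g"]]
  se <- sqrt(vc["g", "g"])
  z <- z_conf(conf)
  tibble(
    or = exp(b), conf_low = exp(b - z * se), conf_high = exp(b + z * se),
    p_value = 2 * pnorm(-abs(b / se))
  )
}

ipw_survival <- function(patients, g, w, conf) {
  d <- tibble(
    time = patients$pfs_time, event = patients$pfs_event,
    grp = factor(ifelse(g, "group1", "group2"), levels = c("group2", "group1")),
    w = w
  )
  med_unadj <- purrr::map(c(TRUE, FALSE), function(in1) {
    km_median_ci(km_fit(d[(d$grp == "group1") == in1, ], .data$time, .data$event))
  })
  med_adj <- purrr::map(c(TRUE, FALSE), function(in1) {
    km_median_ci(km_fit(d[(d$grp == "group1") == in1, ], .data$time, .data$event,
                        weights = .data$w))
  })
  hr_unadj <- cox_hr(d, .data$time, .data$event, .data$grp, conf = conf)
  hr_adj <- cox_hr(d, .data$time, .data$event, .data$grp, conf = conf,
                   weights = .data$w)
  tibble(
    adjusted = c(FALSE, TRUE),
    median_group1 = c(med_unadj[[1]]$median, med_adj[[1]]$median),
    median_group2 = c(med_unadj[[2]]$median, med_adj[[2]]$median),
    hr = c(hr_unadj$hr, hr_adj$hr),
    conf_low = c(hr_unadj$conf_low, hr_adj$conf_low),
    conf_high = c(hr_unadj$conf_high, hr_adj$conf_high),
    p_value = c(hr_unadj$p_value, hr_adj$p_value)
  )
}

# standardised mean differences per factor (per level for categoricals),
# before and after weighting
balance_table <- function(patients, g, w, factors) {
  if (length(factors) == 0) return(tibble())
  purrr::map_dfr(factors, function(f) {
    v <- patients[[f]]
    if (is.numeric(v)) {
      tibble(
        factor = f, level = NA_character_,
        smd_before = smd_continuous(v, g, rep(1, length(v))),
        smd_after = smd_continuous(v, g, w)
      )
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "missing"
      purrr::map_dfr(sort(unique(v)), function(lv) {
        ind <- as.numeric(v == lv)
        tibble(
          factor = f, level = lv,
          smd_before = smd_binary(ind, g, rep(1, length(ind))),
          smd_after = smd_binary(ind, g, w)
        )
      })
    }
  })
}

smd_continuous <- function(v, g, w) {
  m1 <- weighted.mean(v[g], w[g]); m2 <- weighted.mean(v[!g], w[!g])
  v1 <- weighted.mean((v[g] - m1)^2, w[g])
  v2 <- weighted.mean((v[!g] - m2)^2, w[!g])
  (m1 - m2) / sqrt((v1 + v2) / 2)
}

smd_binary <- function(ind, g, w) {
  p1 <- weighted.mean(ind[g], w[g]); p2 <- weighted.mean(ind[!g], w[!g])
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (denom == 0) return(0)
  (p1 - p2) / denom
}

#' @export
print.btmb_ipw <- function(x, ...) {
  est <- x$estimates
  cat(sprintf(
    "<btmb_ipw> n = %d (%d weight(s) truncated)\n  unadjusted OR %.2f (%.2f, %.2f); adjusted OR %.2f (%.2f, %.2f)\n",
    x$n, x$n_truncated,
    est$or[1], est$conf_low[1], est$conf_high[1],
    est$or[2], est$conf_low[2], est$conf_high[2]
  ))
  invisible(x)
}
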