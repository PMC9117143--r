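test_that("factor screening keeps planted shifts and drops permuted noise", {
  set.seed(151)
  # planted shift of trial magnitude: SLD medians 42 vs 70 mm at n = 29/119
  d <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), c(29, 119)),
    sld_mm = c(rlnorm(29, log(42.4), 0.5), rlnorm(119, log(70), 0.5))
  )
  sc <- screen_factors(d, grp, factors = "sld_mm")
  expect_true(sc$selected)

  # a factor identically distributed in both groups should rarely pass
  hits <- replicate(60, {
    d$noise <- sample(d$sld_mm)
    screen_factors(d, grp, factors = "noise")$selected
  })
  expect_gte(mean(!hits), 0.75) # expect ~85% exclusion at alpha = 0.15

  expect_equal(sum(screen_factors(d, grp, factors = "sld_mm",
                                  alpha = 0)$selected), 0)
})

test_that("screening picks tests by factor type and skips constants", {
  set.seed(161)
  d <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), each = 40),
    age = rnorm(80, 67, 9),
    smoking = sample(c("never", "former", "current"), 80, replace = TRUE),
    const = 1
  )
  expect_warning(sc <- screen_factors(d, grp,
                                      factors = c("age", "smoking", "const")),
                 "constant")
  expect_equal(nrow(sc), 2)
  expect_equal(sc$test[sc$factor == "age"], "wilcoxon")
  expect_true(sc$test[sc$factor == "smoking"] %in% c("chi-square", "fisher"))
})

test_that("propensity model: intercept-only and saturated closed forms", {
  set.seed(171)
  d <- tibble::tibble(
    grp = rbinom(60, 1, 0.3),
    bin = sample(c("a", "b"), 60, replace = TRUE)
  )
  # no factors: propensity is the prevalence
  p0 <- fit_propensity(d, grp)
  expect_equal(unique(p0$.propensity), mean(d$grp))

  # single categorical factor: fitted probabilities are the cell rates
  p1 <- fit_propensity(d, grp, factors = "bin")
  for (lv in c("a", "b")) {
    expect_equal(unique(round(p1$.propensity[d$bin == lv], 10)),
                 round(mean(d$grp[d$bin == lv]), 10))
  }
})

test_that("propensity coefficients match a direct likelihood maximiser", {
  set.seed(181)
  d <- tibble::tibble(
    x1 = rnorm(120), x2 = rnorm(120),
    grp = rbinom(120, 1, plogis(-0.5 + 0.8 * x1 - 0.6 * x2))
  )
  fit <- fit_propensity(d, grp, factors = c("x1", "x2"))
  m <- attr(fit, "propensity_model")
  nll <- function(b) {
    eta <- b[1] + b[2] * d$x1 + b[3] * d$x2
    -sum(d$grp * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(coef(m)), opt$par, tolerance = 1e-4)
})

test_that("uniform propensity makes adjusted equal unadjusted exactly", {
  set.seed(191)
  d <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), c(30, 70)),
    confirmed_response = rbinom(100, 1, ifelse(rep(c(TRUE, FALSE), c(30, 70)),
                                               0.35, 0.12)),
    pfs_time = round(rexp(100, 0.2), 2), pfs_event = rbinom(100, 1, 0.8),
    .propensity = 0.5
  )
  ipw <- ipw_estimate(d, grp, confirmed_response, truncate = NULL)
  expect_equal(ipw$weights, rep(2, 100))
  est <- ipw$estimates
  expect_equal(est$rate_group1[1], est$rate_group1[2])
  expect_equal(est$or[1], est$or[2])
  expect_equal(ipw$survival$hr[1], ipw$survival$hr[2])
  expect_equal(ipw$survival$median_group1[1], ipw$survival$median_group1[2])
})

test_that("weighted group sizes recover each arm's total (Horvitz-Thompson)", {
  set.seed(201)
  d <- simulate_confounded_msaf(sim_config(seed = 3))
  sel <- c("age", "sld_mm", "n_target_lesions", "smoking", "pdl1_status")
  d2 <- fit_propensity(d, msaf_lt1, sel)
  ipw <- ipw_estimate(d2, msaf_lt1, confirmed_response, factors = sel,
                      truncate = NULL)
  w <- ipw$weights
  n <- nrow(d)
  expect_lt(abs(sum(w[d$msaf_lt1]) - n) / n, 0.35) # sampling tolerance
  expect_lt(abs(sum(w[!d$msaf_lt1]) - n) / n, 0.35)
})

test_that("weighting shrinks the planted covariate imbalance", {
  d <- simulate_confounded_msaf(sim_config(seed = 17))
  sc <- suppressWarnings(screen_factors(d, msaf_lt1))
  sel <- sc$factor[sc$selected]
  expect_gt(length(sel), 0) # the planted shifts should be caught
  d2 <- fit_propensity(d, msaf_lt1, sel)
  ipw <- ipw_estimate(d2, msaf_lt1, confirmed_response, factors = sel)
  bal <- ipw$balance
  expect_lt(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)))
})

test_that("confounded cohort: unadjusted OR biased up, adjusted near null", {
  set.seed(211)
  res <- t(replicate(40, {
    d <- simulate_confounded_msaf(sim_config(seed = sample.int(1e6, 1)))
    sc <- suppressWarnings(screen_factors(d, msaf_lt1))
    sel <- sc$factor[sc$selected]
    d2 <- fit_propensity(d, msaf_lt1, sel)
    ipw <- ipw_estimate(d2, msaf_lt1, confirmed_response, factors = sel)
    est <- ipw$estimates
    c(unadj = est$or[1],
      covers = est$conf_low[2] <= 1 && est$conf_high[2] >= 1)
  }))
  expect_gt(mean(res[, "unadj"] > 1), 0.8) # bias away from 1 by construction
  expect_gte(mean(res[, "covers"]), 0.85)
})

test_that("zero planted effects make both estimates null on average", {
  set.seed(221)
  # larger cohorts and medians: a rare zero-responder arm otherwise drags
  # the mean log OR far from its centre
  ors <- t(replicate(30, {
    d <- simulate_confounded_msaf(sim_config(n_patients = 400,
                                             seed = sample.int(1e6, 1),
                                             confound_strength = 0))
    d2 <- fit_propensity(d, msaf_lt1,
                         c("age", "sld_mm", "n_target_lesions"))
    est <- ipw_estimate(d2, msaf_lt1, confirmed_response)$estimates
    c(est$or[1], est$or[2])
  }))
  expect_lt(abs(median(log(ors[, 1]))), 0.25)
  expect_lt(abs(median(log(ors[, 2]))), 0.25)
})

test_that("propensity outside (0,1) and missing column are rejected", {
  d <- tibble::tibble(grp = c(TRUE, FALSE), confirmed_response = c(1, 0))
  expect_error(ipw_estimate(d, grp, confirmed_response),
               class = "btmb_validation_error")
  d$.propensity <- c(0, 0.5)
  expect_error(ipw_estimate(d, grp, confirmed_response),
               class = "btmb_validation_error")
})
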