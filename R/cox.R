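#' Two-group Cox proportional-hazards ratio
#'
#' Maximises the Cox partial likelihood for a single binary covariate by
#' Newton's method with step halving, using the Efron approximation for
#' tied event times by default (Breslow by flag). The reported hazard ratio
#' contrasts the `TRUE`/second level of `group` against the other, so with
#' `group = btmb_high` an HR below 1 favours the biomarker-high group. The
#' Wald interval is built on the log-hazard scale at a caller-chosen level
#' (trial convention for hazard ratios: 90%).
#'
#' Monotone likelihood (e.g. no events in one group) is detected when the
#' coefficient diverges; the fit is then flagged and the interval reported
#' unbounded.
#'
#' @param data Data frame, one row per patient.
#' @param time,event,group Columns (tidy-eval): follow-up time, event flag,
#'   binary group (logical, 0/1 or two-level factor).
#' @param conf Confidence level for the Wald interval (default 0.90).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param weights Optional column of positive case weights
#'   (inverse-probability weights for adjusted analyses).
#' @param max_iter,tol Newton iteration cap and convergence tolerance on
#'   the log-likelihood change.
#' @return Object of class `btmb_cox` with elements `coef` (log HR), `se`,
#'   `hr`, `conf_low`, `conf_high`, `p_value` (Wald), `n`, `n_events`,
#'   `iter`, `converged`, `monotone`.
#' @export
cox_hr <- function(data, time, event, group, conf = 0.90,
                   ties = c("efron", "breslow"), weights = NULL,
                   max_iter = 25, tol = 1e-9) {
  ties <- match.arg(ties)
  times <- dplyr::pull(data, {{ time }})
  events <- dplyr::pull(data, {{ event }})
  grp <- dplyr::pull(data, {{ group }})
  wq <- enquo(weights)
  w <- if (rlang::quo_is_null(wq)) rep(1, length(times)) else dplyr::pull(data, !!wq)

  x <- as.numeric(as.integer(factor(grp)) - 1L)
  if (length(unique(x)) != 2) stop_validation("`group` must have two levels")
  if (any(w <= 0)) stop_validation("weights must be positive")
  if (!all(events %in% c(0, 1))) stop_validation("event flags must be 0/1")

  fit <- cox_newton(times, events, x, w, ties, max_iter, tol)
  z <- z_conf(conf)
  hr <- exp(fit$beta)
  if (fit$monotone) {
    ci <- if (fit$beta < 0) c(0, Inf) else c(0, Inf)
    se <- Inf
    p <- NA_real_
    warn("monotone partial likelihood (no events in a group?); HR unbounded")
  } else {
    se <- sqrt(1 / fit$info)
    ci <- exp(fit$beta + c(-1, 1) * z * se)
    p <- 2 * pnorm(-abs(fit$beta / se))
  }
  structure(
    list(
      coef = fit$beta, se = se, hr = hr, conf = conf,
      conf_low = ci[1], conf_high = ci[2], p_value = p,
      n = length(times), n_events = sum(events == 1),
      n_events_group = c(sum(events == 1 & x == 0), sum(events == 1 & x == 1)),
      iter = fit$iter, converged = fit$converged, monotone = fit$monotone,
      ties = ties, loglik = fit$loglik
    ),
    class = "btmb_cox"
  )
}

#' @export
print.btmb_cox <- function(x, ...) {
  cat(sprintf(
    "<btmb_cox> HR = %.3f (%d%% CI %.3f, %.3f), Wald p = %s, %d events / %d patients\n",
    x$hr, round(100 * x$conf), x$conf_low, x$conf_high,
    format.pval(x$p_value, digits = 3), x$n_events, x$n
  ))
  invisible(x)
}

# Partial log-likelihood, score and information for one covariate.
# Efron with case weights: at a tied event time with event set D
# (d unweighted events, weighted sums wD, S0D, S1D, S2D over D),
#   ll += sum_{i in D} w_i x_i b - (wD/d) * sum_{j=0}^{d-1} log(S0 - (j/d) S0D)
# and score/information are the corresponding derivatives.
cox_loglik <- function(beta, times, events, x, w, ties) {
  r <- w * exp(beta * x)
  et <- sort(unique(times[events == 1]))
  ll <- 0; score <- 0; info <- 0
  for (t in et) {
    at_risk <- times >= t
    S0 <- sum(r[at_risk])
    S1 <- sum(r[at_risk] * x[at_risk])
    S2 <- sum(r[at_risk] * x[at_risk]^2)
    D <- times == t & events == 1
    d <- sum(D)
    wD <- sum(w[D])
    ll <- ll + beta * sum(w[D] * x[D])
    if (ties == "breslow" || d == 1) {
      ll <- ll - wD * log(S0)
      score <- score + sum(w[D] * x[D]) - wD * S1 / S0
      info <- info + wD * (S2 / S0 - (S1 / S0)^2)
    } else {
      S0D <- sum(r[D]); S1D <- sum(r[D] * x[D]); S2D <- sum(r[D] * x[D]^2)
      frac <- (seq_len(d) - 1) / d
      denom <- S0 - frac * S0D
      num1 <- S1 - frac * S1D
      num2 <- S2 - frac * S2D
      ll <- ll - (wD / d) * sum(log(denom))
      score <- score + sum(w[D] * x[D]) - (wD / d) * sum(num1 / denom)
      info <- info + (wD / d) * sum(num2 / denom - (num1 / denom)^2)
    }
  }
  list(loglik = ll, score = score, info = info)
}

cox_newton <- function(times, events, x, w, ties, max_iter, tol) {
  beta <- 0
  cur <- cox_loglik(beta, times, events, x, w, ties)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    if (cur$info <= 0) break
    step <- cur$score / cur$info
    new_beta <- beta + step
    nxt <- cox_loglik(new_beta, times, events, x, w, ties)
    halvings <- 0
    while (nxt$loglik < cur$loglik && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- cox_loglik(new_beta, times, events, x, w, ties)
      halvings <- halvings + 1
    }
    done <- abs(nxt$loglik - cur$loglik) < tol
    beta <- new_beta
    cur <- nxt
    if (done) {
      converged <- TRUE
      break
    }
  }
  monotone <- abs(beta) > 15
  if (!converged && !monotone) {
    abort(
      sprintf(
        "Cox Newton iteration did not converge in %d steps (beta = %.4f, score = %.2e)",
        max_iter, beta, cur$score
      ),
      class = "btmb_convergence_error"
    )
  }
  list(beta = beta, info = cur$info, loglik = cur$loglik,
       iter = iter, converged = converged, monotone = monotone)
}
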