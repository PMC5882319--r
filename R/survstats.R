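# Censored-survival kernel: Nelson-Aalen, null-model residuals, Kaplan-Meier,
# log-rank, Cox (Breslow ties), Harrell's C. All estimators are written out
# here so they can be cross-checked against independent references in tests.

check_surv <- function(time, event) {
  assert_that(length(time) == length(event), "time and event lengths differ")
  assert_that(all(is.finite(time)) && all(time > 0), "times must be finite and positive")
  assert_that(all(event %in% c(0, 1)), "event indicators must be 0/1")
  invisible(TRUE)
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' \eqn{\hat\Lambda(t) = \sum_{t_j \le t} d_j / n_j} over distinct event
#' times, with \eqn{d_j} events and \eqn{n_j} at risk at \eqn{t_j};
#' right-continuous, non-decreasing, \eqn{\hat\Lambda(0) = 0}.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return A tibble of class `na_fit` with one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `cumhaz`.
#' @seealso [cumhaz_at()]
#' @export
nelson_aalen <- function(time, event) {
  check_surv(time, event)
  assert_that(length(time) >= 1L, "need at least one outcome")
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    out <- tibble::tibble(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), cumhaz = numeric(0))
  } else {
    n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
    n_event <- vapply(et, function(t) sum(time == t & event == 1), integer(1))
    out <- tibble::tibble(time = et, n_risk = n_risk, n_event = n_event,
                          cumhaz = cumsum(n_event / n_risk))
  }
  class(out) <- c("na_fit", class(out))
  out
}

#' Evaluate a Nelson-Aalen fit at arbitrary times
#'
#' @param fit An `na_fit` from [nelson_aalen()].
#' @param t Numeric times.
#' @return \eqn{\hat\Lambda(t)} for each `t` (0 before the first event time).
#' @export
cumhaz_at <- function(fit, t) {
  if (nrow(fit) == 0L) return(rep(0, length(t)))
  f <- stats::stepfun(fit$time, c(0, fit$cumhaz), right = FALSE)
  f(t)
}

#' Null-model martingale and deviance residuals
#'
#' Residuals from the covariate-free survival model with the Nelson-Aalen
#' cumulative hazard: \eqn{m_i = \delta_i - \hat\Lambda(t_i)} and
#' \eqn{d_i = \mathrm{sign}(m_i)\sqrt{-2[m_i + \delta_i \log(\delta_i - m_i)]}}
#' (the log term is 0 for censored samples). The deviance residual is a
#' symmetrized, censoring-aware continuous response: large positive values
#' mark early events, large negative values long event-free follow-up. Under
#' heavy censoring it is the standard surrogate response for
#' survival-supervised regression.
#'
#' @param time Positive follow-up times (>= 2 samples).
#' @param event 0/1 event indicators with at least one event.
#' @return A tibble with `time`, `event`, `cumhaz`, `martingale`, `deviance`.
#' @export
null_deviance_residuals <- function(time, event) {
  check_surv(time, event)
  assert_that(length(time) >= 2L, "need at least two outcomes")
  assert_that(sum(event) >= 1, "all-censored input: residuals carry no signal")
  na <- nelson_aalen(time, event)
  ch <- cumhaz_at(na, time)
  m <- event - ch
  logterm <- ifelse(event == 1, log(pmax(event - m, .Machine$double.eps)), 0)
  d <- sign(m) * sqrt(pmax(-2 * (m + logterm), 0))
  tibble::tibble(time = time, event = as.integer(event), cumhaz = ch,
                 martingale = m, deviance = d)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return A `km_fit`: tibble with one row per distinct observed time
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`); the median survival
#'   time (smallest time with \eqn{\hat S(t) \le 0.5}, `NA` if the curve
#'   never reaches 0.5) is available via [glance()].
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  assert_that(length(time) >= 1L, "need at least one outcome")
  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), integer(1))
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), integer(1))
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- tibble::tibble(time = tt, n_risk = n_risk, n_event = n_event,
                        n_censor = n_censor, surv = surv)
  med <- if (any(surv <= 0.5)) min(tt[surv <= 0.5]) else NA_real_
  attr(out, "median") <- med
  attr(out, "n") <- length(time)
  attr(out, "events") <- sum(event)
  class(out) <- c("km_fit", class(out))
  out
}

#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), events = attr(x, "events"),
                 median = attr(x, "median"))
}

#' Two-group log-rank test
#'
#' The classic chi-square statistic \eqn{(\sum(O-E))^2 / \sum V} accumulated
#' over distinct event times, compared to a chi-square with 1 df.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (>= 1 event overall).
#' @param group A two-level grouping (factor, character or binary).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `observed` and
#'   `expected` (events in the first group).
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  g <- as.factor(group)
  assert_that(nlevels(droplevels(g)) == 2L, "log-rank needs exactly two non-empty groups")
  assert_that(sum(event) >= 1, "log-rank needs at least one event")
  g1 <- g == levels(droplevels(g))[1L]
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  obs <- 0
  expd <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    obs <- obs + d1
    expd <- expd + e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  tibble::tibble(statistic = stat, df = 1L,
                 p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                 observed = obs, expected = expd)
}

# Breslow partial-likelihood pieces at the current beta: loglik, gradient,
# information. X is n x p, eta = X beta.
cox_breslow_pieces <- function(time, event, X, beta) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  et <- sort(unique(time[event == 1]))
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in et) {
    risk <- time >= t
    ev <- time == t & event == 1
    d <- sum(ev)
    wr <- w[risk]
    Xr <- X[risk, , drop = FALSE]
    s0 <- sum(wr)
    s1 <- drop(crossprod(Xr, wr))
    s2 <- crossprod(Xr, Xr * wr)
    ll <- ll + sum(eta[ev]) - d * log(s0)
    grad <- grad + colSums(X[ev, , drop = FALSE]) - d * s1 / s0
    info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
  }
  list(loglik = ll, grad = grad, info = info)
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Newton-Raphson maximization of the Breslow partial likelihood with
#' step-halving, Wald confidence intervals and p-values, and explicit
#' monotone-likelihood (separation) detection.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param x Covariate matrix (n x p) or data frame of numeric covariates; no
#'   covariate may be constant.
#' @param max_iter,tol Newton iteration controls.
#' @return A `survsig_cox` object; use [tidy()] for per-covariate hazard
#'   ratios, 95% CIs and Wald p-values, [glance()] for fit-level summaries.
#' @export
cox_fit <- function(time, event, x, max_iter = 30L, tol = 1e-9) {
  check_surv(time, event)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  assert_that(sum(event) >= 1, "Cox fit needs at least one event")
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stopf("constant covariate(s): %s", paste(colnames(X)[const], collapse = ", "))
  }
  assert_that(length(time) >= ncol(X) + 1L, "need n >= p + 1")
  p <- ncol(X)
  beta <- numeric(p)
  pieces <- cox_breslow_pieces(time, event, X, beta)
  ll_trace <- pieces$loglik
  converged <- FALSE
  monotone <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(pieces$info, pieces$grad),
                     error = function(e) stopf("singular information matrix"))
    step_scale <- 1
    repeat {
      beta_new <- beta + step_scale * step
      cand <- cox_breslow_pieces(time, event, X, beta_new)
      if (cand$loglik >= pieces$loglik - 1e-12 || step_scale < 1e-4) break
      step_scale <- step_scale / 2
    }
    beta <- beta_new
    delta_ll <- cand$loglik - pieces$loglik
    pieces <- cand
    ll_trace <- c(ll_trace, pieces$loglik)
    if (max(abs(beta)) > 20) {
      monotone <- TRUE
      break
    }
    if (abs(delta_ll) < tol && max(abs(pieces$grad)) < 1e-5) {
      converged <- TRUE
      break
    }
  }
  vcov <- tryCatch(solve(pieces$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = vcov,
    loglik = pieces$loglik,
    loglik_trace = ll_trace,
    converged = converged && !monotone,
    monotone = monotone,
    n = length(time),
    n_events = sum(event)
  ), class = "survsig_cox")
}

#' @export
print.survsig_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit (Breslow): n=%d, events=%d, loglik=%.4f%s\n",
              x$n, x$n_events, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `survsig_cox` object.
#' @param exponentiate Report hazard ratios (`TRUE`, default) or log hazard
#'   ratios.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.survsig_cox <- function(x, exponentiate = TRUE, conf.level = 0.95, ...) {
  z <- x$coefficients / x$se
  q <- stats::qnorm(1 - (1 - conf.level) / 2)
  est <- x$coefficients
  lo <- est - q * x$se
  hi <- est + q * x$se
  if (exponentiate) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    conf.low = unname(lo),
    conf.high = unname(hi)
  )
}

#' @export
glance.survsig_cox <- function(x, ...) {
  tibble::tibble(n = x$n, events = x$n_events, logLik = x$loglik,
                 converged = x$converged, monotone = x$monotone)
}

#' Cox score test at beta = 0
#'
#' The score (Rao) chi-square statistic of the null hypothesis beta = 0; for
#' a single binary covariate this is algebraically the log-rank statistic.
#'
#' @inheritParams cox_fit
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @export
cox_score_test <- function(time, event, x) {
  check_surv(time, event)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  pieces <- cox_breslow_pieces(time, event, X, numeric(ncol(X)))
  stat <- drop(crossprod(pieces$grad, solve(pieces$info, pieces$grad)))
  tibble::tibble(statistic = stat, df = ncol(X),
                 p.value = stats::pchisq(stat, df = ncol(X), lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' The fraction of comparable sample pairs whose risk-score ordering agrees
#' with their survival ordering. A pair is comparable iff the shorter time is
#' an observed event (equal times are never comparable); higher score must
#' mean shorter time to count as concordant; score ties count 1/2.
#'
#' @param score Per-sample real risk scores (higher = higher predicted risk).
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return C in \[0, 1\].
#' @export
harrell_c <- function(score, time, event) {
  check_surv(time, event)
  assert_that(all(is.finite(score)), "scores must be finite")
  assert_that(length(score) == length(time), "score and time lengths differ")
  n <- length(time)
  # ordered pairs (i, j) with t_i < t_j and event at i: each unordered
  # comparable pair appears exactly once
  ti <- matrix(time, n, n)
  comp <- (ti < t(ti)) & (event == 1)
  si <- matrix(score, n, n)
  conc <- comp & (si > t(si))
  tied <- comp & (si == t(si))
  n_comp <- sum(comp)
  assert_that(n_comp > 0, "no comparable pairs")
  (sum(conc) + 0.5 * sum(tied)) / n_comp
}
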