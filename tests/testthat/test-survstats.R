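test_that("Nelson-Aalen estimator matches hand computations", {
  expect_equal(nrow(nelson_aalen(c(1, 2), c(0, 0))), 0L)
  expect_equal(cumhaz_at(nelson_aalen(c(1, 2), c(0, 0)), c(0.5, 3)), c(0, 0))

  na <- nelson_aalen(c(1, 2, 3), c(1, 1, 1))
  expect_equal(na$cumhaz, cumsum(1 / c(3, 2, 1)))
  na2 <- nelson_aalen(c(1, 2, 3), c(1, 0, 1))
  expect_equal(na2$cumhaz[2], 1 / 3 + 1)
  expect_error(nelson_aalen(c(-1, 2), c(1, 0)), "positive")

  # right-continuity and monotonicity against survival::survfit
  s <- random_surv(40, seed = 3)
  na3 <- nelson_aalen(s$time, s$event)
  expect_true(all(diff(na3$cumhaz) > 0))
  sf <- survival::survfit(survival::Surv(s$time, s$event) ~ 1, ctype = 1)
  expect_equal(cumhaz_at(na3, sf$time), sf$cumhaz, tolerance = 1e-12)
})

test_that("null-model deviance residuals match closed forms", {
  # delta = 1, cumhaz 0.5: m = 0.5, d = sqrt(-2 (0.5 + ln 0.5))
  r <- null_deviance_residuals(c(1, 2), c(1, 0))
  expect_equal(r$martingale, c(0.5, -0.5))
  expect_equal(r$deviance[1], 0.62152, tolerance = 1e-5)

  # delta = 0 with cumhaz 1 -> d = -sqrt(2); delta = 0, cumhaz 0 -> 0
  r2 <- null_deviance_residuals(c(1, 1, 2), c(1, 1, 0))
  expect_equal(r2$cumhaz[3], 2 / 3)
  d_expected <- -sqrt(-2 * (-2 / 3))
  expect_equal(r2$deviance[3], d_expected, tolerance = 1e-12)

  expect_error(null_deviance_residuals(c(1, 2), c(0, 0)), "all-censored")

  # sign(d) = sign(m) and d = 0 iff m = 0 on random data
  s <- random_surv(60, seed = 9)
  rr <- null_deviance_residuals(s$time, s$event)
  expect_true(all(sign(rr$deviance) == sign(rr$martingale)))
  expect_true(all(rr$martingale <= 1))
})

test_that("martingale residuals sum to zero on random datasets", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    time <- rexp(n) + 0.01
    event <- rbinom(n, 1, runif(1, 0.2, 0.9))
    if (sum(event) == 0) event[sample(n, 1)] <- 1
    # duplicated times exercise the tie handling
    if (n > 10) time[2] <- time[1]
    r <- null_deviance_residuals(time, event)
    expect_lt(abs(sum(r$martingale)), 1e-9)
  }
})

test_that("Kaplan-Meier estimate and median match hand values", {
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  expect_true(is.na(glance(km0)$median))

  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(glance(km)$median, 2)

  # S is non-increasing and agrees with survival::survfit on random data
  set.seed(33)
  for (i in 1:20) {
    s <- random_surv(sample(5:50, 1))
    km_i <- km_estimate(s$time, s$event)
    expect_true(all(diff(km_i$surv) <= 1e-12))
    sf <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
    expect_equal(km_i$surv[km_i$time %in% sf$time],
                 sf$surv, tolerance = 1e-12)
  }
})

test_that("log-rank test matches the textbook O/E/V computation", {
  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)

  # fully separated groups, brute-force O/E/V table over the 6 event times
  time <- 1:6
  event <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)
  o_e <- 0; v <- 0
  for (t in time) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == "A")
    d <- 1
    o_e <- o_e + (group[time == t] == "A") - n1 / n
    if (n > 1) v <- v + (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, o_e^2 / v, tolerance = 1e-10)

  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "a", "a")), "two")
})

test_that("log-rank agrees with survival::survdiff and is invariant to relabeling", {
  set.seed(5)
  for (i in 1:15) {
    s <- random_surv(40)
    g <- rbinom(40, 1, 0.5)
    if (length(unique(g)) < 2) next
    lr <- logrank_test(s$time, s$event, g)
    sd_ref <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
    expect_equal(lr$statistic, sd_ref$chisq, tolerance = 1e-10)
    # relabeling the groups and shifting all times changes nothing
    lr_swap <- logrank_test(s$time + 5, s$event, 1 - g)
    expect_equal(lr_swap$statistic, lr$statistic, tolerance = 1e-12)
  }
})

test_that("Cox fit matches an independent reference implementation", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), cbind(x = c(2, 2, 2))),
               "constant")
  set.seed(17)
  for (i in 1:10) {
    n <- 60
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    time <- rexp(n, exp(0.5 * x[, 1])) + 0.01
    event <- rbinom(n, 1, 0.6)
    if (sum(event) < 3) next
    fit <- cox_fit(time, event, x)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow")
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_true(fit$converged)
    # log partial likelihood is non-decreasing across Newton iterations
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
    # CI brackets the HR
    td <- tidy(fit)
    expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  }
})

test_that("Cox score test at zero equals the log-rank statistic", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_surv(50)
    g <- rbinom(50, 1, 0.5)
    if (length(unique(g)) < 2 || sum(s$event) == 0) next
    st <- cox_score_test(s$time, s$event, cbind(g = g))
    lr <- logrank_test(s$time, s$event, g)
    expect_equal(st$statistic, lr$statistic, tolerance = 1e-8)
  }
})

test_that("monotone likelihood is flagged, not silently reported", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- cbind(sep = c(1, 1, 1, 0, 0, 0))
  fit <- cox_fit(time, event, x)
  expect_true(fit$monotone)
  expect_false(fit$converged)
})

test_that("Cox recovers a known coefficient from simulated cohorts", {
  set.seed(31)
  hits <- 0L
  for (i in 1:40) {
    n <- 300
    x <- rnorm(n)
    time <- rexp(n, 0.2 * exp(0.7 * x))
    cens <- rexp(n, 0.08)
    event <- as.integer(time <= cens)
    obs <- pmin(time, cens)
    fit <- cox_fit(obs, event, cbind(x = x))
    if (abs(fit$coefficients - 0.7) <= 3 * fit$se) hits <- hits + 1L
  }
  expect_gte(hits, 36L)
})

test_that("Harrell C matches brute-force enumeration and hand examples", {
  # perfectly anti-ordered scores and times, all events -> C = 1
  expect_equal(harrell_c(4:1, 1:4, rep(1, 4)), 1)
  # all scores tied -> 0.5
  expect_equal(harrell_c(rep(2, 5), 1:5, rep(1, 5)), 0.5)
  # worked 4-sample example: 4 concordant of 6 comparable pairs
  expect_equal(harrell_c(c(10, 1, 8, 2), c(2, 4, 6, 8), rep(1, 4)), 4 / 6)
  expect_error(harrell_c(c(1, 2), c(1, 2), c(0, 0)), "comparable")

  set.seed(47)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    s <- random_surv(n)
    s$event[which.min(s$time)] <- 1 # guarantee a comparable pair
    score <- sample(1:8, n, replace = TRUE) # ties likely
    expect_identical(harrell_c(score, s$time, s$event),
                     harrell_c_oracle(score, s$time, s$event))
  }
})

test_that("Harrell C complement identity holds without score ties", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    s <- random_surv(n)
    s$event[which.min(s$time)] <- 1
    score <- rnorm(n)
    expect_equal(harrell_c(score, s$time, s$event) +
                   harrell_c(-score, s$time, s$event), 1, tolerance = 1e-12)
  }
})
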