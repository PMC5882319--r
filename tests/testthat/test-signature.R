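test_that("response standardization yields unit mean square", {
  r <- standardize_response(c(1, 1, 1, 1))
  expect_equal(r$y, c(1, 1, 1, 1))
  expect_equal(r$scale, 1)

  r2 <- standardize_response(c(3, 4))
  expect_equal(r2$y, c(3, 4) * sqrt(2) / 5, tolerance = 1e-12)

  expect_error(standardize_response(rep(0, 5)), "zero")
  set.seed(3)
  for (i in 1:20) {
    y <- standardize_response(rnorm(sample(3:40, 1)))$y
    expect_equal(sum(y^2) / length(y), 1, tolerance = 1e-12)
  }
})

test_that("inverse-normal transform is monotone, symmetric and in (0,1)", {
  s <- c(0.2, 0.9, 0.4, 0.35, 0.99)
  t1 <- inverse_transform_scores(s)
  expect_equal(order(t1), order(s))
  expect_equal(cor(t1, s, method = "spearman"), 1)
  expect_true(all(t1 > 0 & t1 < 1))

  # symmetric ranks map symmetrically about 0.5
  t2 <- inverse_transform_scores(c(1, 2, 3, 4, 5))
  expect_equal(t2 + rev(t2), rep(1, 5), tolerance = 1e-12)

  # ties share a value
  t3 <- inverse_transform_scores(c(1, 2, 2, 3))
  expect_equal(t3[2], t3[3])
  expect_error(inverse_transform_scores(rep(1, 4)), "all equal")
})

test_that("partition cutoff equals the exhaustive-split oracle", {
  cc <- partition_cutoff(c(0.1, 0.2, 0.8, 0.9), c(-1, -1, 2, 2))
  expect_equal(as.numeric(cc), 0.5)
  expect_equal(attr(cc, "sse_before"), 9)
  expect_equal(attr(cc, "sse_after"), 0)

  # two samples: midpoint
  expect_equal(as.numeric(partition_cutoff(c(0.3, 0.7), c(0, 1))), 0.5)
  expect_error(partition_cutoff(c(0.3, 0.7), c(1, 1)), "constant")
  expect_error(partition_cutoff(c(0.5, 0.5), c(0, 1)), "no split")

  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    scores <- round(runif(n), 2)
    if (length(unique(scores)) < 2) next
    d <- rnorm(n)
    expect_identical(as.numeric(partition_cutoff(scores, d)),
                     partition_oracle(scores, d))
  }
})

test_that("partition cutoff agrees with a depth-1 rpart split", {
  set.seed(29)
  for (i in 1:10) {
    n <- 40
    scores <- runif(n)
    d <- 2 * (scores > 0.6) + rnorm(n, sd = 0.3)
    cc <- as.numeric(partition_cutoff(scores, d))
    rp <- rpart::rpart(d ~ scores, maxdepth = 1, minsplit = 2, minbucket = 1,
                       cp = 0)
    expect_equal(cc, unname(rp$splits[1, "index"]), tolerance = 1e-10)
  }
})

test_that("SVR behaves sensibly at the edges", {
  x <- make_expr(4, 10, seed = 8)
  # constant response: predictions within epsilon of the constant
  fit <- fit_svr(x, rep(2, 10))
  expect_true(all(abs(predict(fit, x) - 2) <= 0.1 + 1e-8))
  expect_error(fit_svr(x, rnorm(10), probes = character(0)), "non-empty")
  expect_error(fit_svr(x, rnorm(10), cost = -1), "positive")

  # training RMSE weakly decreases as regularization loosens
  set.seed(4)
  y <- rnorm(10)
  rmse <- sapply(c(0.01, 0.1, 1, 10, 100), function(cc) {
    f <- fit_svr(x, y, cost = cc, gamma = 1)
    sqrt(mean((y - f$train_pred)^2))
  })
  expect_true(all(diff(rmse) <= 1e-8))
})

test_that("SVR dual solution matches a brute-force small-QP oracle", {
  # 3 points, 1 feature; maximize the epsilon-SVR dual on a grid
  xs <- c(-1, 0, 1.2)
  ys <- c(-0.8, 0.3, 1)
  cost <- 1; eps <- 0.1; gam <- 0.5
  K <- exp(-gam * outer(xs, xs, function(a, b) (a - b)^2))
  dual_obj <- function(b) {
    -0.5 * drop(t(b) %*% K %*% b) - eps * sum(abs(b)) + sum(ys * b)
  }
  search <- function(c1, c2, step) {
    best <- -Inf; best_b <- c(0, 0, 0)
    for (b1 in seq(max(-cost, c1[1]), min(cost, c1[2]), by = step)) {
      for (b2 in seq(max(-cost, c2[1]), min(cost, c2[2]), by = step)) {
        b3 <- -b1 - b2
        if (abs(b3) > cost) next
        b <- c(b1, b2, b3)
        obj <- dual_obj(b)
        if (obj > best) { best <- obj; best_b <- b }
      }
    }
    best_b
  }
  coarse <- search(c(-cost, cost), c(-cost, cost), 0.005)
  best_b <- search(coarse[1] + c(-0.006, 0.006), coarse[2] + c(-0.006, 0.006),
                   0.0002)
  free <- which(abs(best_b) > 1e-9 & abs(abs(best_b) - cost) > 1e-9)
  i <- free[1]
  intercept <- ys[i] - eps * sign(best_b[i]) - drop(K[i, ] %*% best_b)
  oracle_pred <- drop(K %*% best_b) + intercept

  m <- matrix(xs, 1, 3, dimnames = list("f1", paste0("s", 1:3)))
  # undo the internal standardization so the kernel matches the oracle's
  sx <- (xs - mean(xs)) / sd(xs)
  m2 <- matrix(sx * sd(xs) + mean(xs), 1, 3, dimnames = dimnames(m))
  fit <- fit_svr(expression_matrix(m2), ys, cost = cost, epsilon = eps,
                 gamma = gam * sd(xs)^2)
  expect_equal(unname(predict(fit, expression_matrix(m2))), oracle_pred,
               tolerance = 1e-3)
})

test_that("risk scores are a strict monotone squash of predictions", {
  x <- make_expr(5, 20, seed = 12)
  set.seed(12)
  y <- rnorm(20)
  fit <- fit_svr(x, y)
  sc <- score_samples(fit, x)
  expect_true(all(sc > 0 & sc < 1))
  expect_equal(cor(sc, fit$train_pred, method = "spearman"), 1)
  # prediction at the training mean maps to 0.5
  expect_equal(unname(stats::plogis(0)), 0.5)
  mid <- score_samples(fit, x)[which.min(abs(fit$train_pred - fit$pred_mean))]
  expect_lt(abs(mid - 0.5), 0.05)
})

test_that("repeated-holdout cross-validation concentrates where it should", {
  # easy problem: response is a smooth function of one strong feature
  set.seed(6)
  n <- 60
  f <- rnorm(n)
  m <- rbind(sig = f, nse = rnorm(n))
  colnames(m) <- sprintf("s%02d", 1:n)
  x <- expression_matrix(m)
  cv_easy <- cross_validate(x, f, probes = "sig", folds = 20, seed = 2)
  expect_lt(attr(cv_easy, "mean_rmse"), 0.25)

  # pure-noise response: holdout RMSE concentrates near the noise SD
  y_noise <- rnorm(n)
  cv_noise <- cross_validate(x, y_noise, probes = "nse", folds = 50, seed = 3)
  expect_gt(attr(cv_noise, "mean_rmse"), 0.8)
  expect_lt(attr(cv_noise, "mean_rmse"), 1.2)

  expect_equal(nrow(cv_noise), 50L)
  expect_equal(attr(cv_noise, "mean_rmse"), mean(cv_noise$rmse), tolerance = 1e-12)
  expect_error(cross_validate(x, f, holdout = 0.01), "less than one")
})

test_that("ga_config validates its fields", {
  expect_error(ga_config(pop_size = 1), ">= 2")
  expect_error(ga_config(p_crossover = 1.2), "0, 1")
  expect_error(ga_config(size_min = 5, size_max = 3), "size_min")
  expect_s3_class(ga_config(), "ga_config")
})

test_that("GA finds the exhaustive optimum on a tiny pool", {
  # single-probe pool: no search possible
  set.seed(2)
  n <- 30
  m1 <- matrix(rnorm(n), 1, n, dimnames = list("only", sprintf("s%02d", 1:n)))
  s <- random_surv(n, seed = 2)
  s$event[1] <- 1
  y <- rnorm(n)
  g1 <- ga_select(expression_matrix(m1), y, s$time, s$event,
                  ga_config(pop_size = 4, generations = 2, size_min = 1,
                            size_max = 1, seed = 1), fitness = "insample")
  expect_equal(g1$probes, "only")

  # 6-probe pool, subsets of size <= 2 (21 candidates): the GA matches
  # exhaustive enumeration under the same in-sample fitness in >= 9/10 seeds
  hits <- 0L
  for (sd_ in 1:10) {
    set.seed(sd_ + 100)
    n <- 40
    m <- matrix(rnorm(6 * n), 6, n,
                dimnames = list(paste0("g", 1:6), sprintf("s%02d", 1:n)))
    risk <- m[2, ] + 0.8 * m[5, ]
    time <- rexp(n, 0.3 * exp(risk)) + 0.01
    cens <- rexp(n, 0.2)
    event <- as.integer(time <= cens)
    if (sum(event) < 3) event[1:3] <- 1
    obs <- pmin(time, cens)
    x <- expression_matrix(m)
    yresp <- standardize_response(
      null_deviance_residuals(obs, event)$deviance)$y
    # exhaustive oracle over all 21 subsets of size 1-2
    subsets <- c(as.list(1:6), combn(6, 2, simplify = FALSE))
    eval_subset <- function(idx) {
      fit <- fit_svr(x, yresp, probes = rownames(m)[idx])
      harrell_c(fit$train_pred, obs, event)
    }
    cs <- vapply(subsets, eval_subset, numeric(1))
    best_overall <- max(cs)
    ga <- ga_select(x, yresp, obs, event,
                    ga_config(pop_size = 20, generations = 30, size_min = 1,
                              size_max = 2, seed = sd_), fitness = "insample")
    if (ga$score$c_index >= best_overall - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("GA is reproducible and honours the elitism guarantee", {
  set.seed(77)
  n <- 40
  m <- matrix(rnorm(12 * n), 12, n,
              dimnames = list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:n)))
  s <- random_surv(n, seed = 77)
  if (sum(s$event) == 0) s$event[1] <- 1
  y <- rnorm(n)
  cfg <- ga_config(pop_size = 10, generations = 4, size_min = 2, size_max = 4,
                   seed = 5)
  g1 <- ga_select(expression_matrix(m), y, s$time, s$event, cfg)
  g2 <- ga_select(expression_matrix(m), y, s$time, s$event, cfg)
  expect_identical(g1$probes, g2$probes)
  expect_identical(g1$score, g2$score)
  expect_equal(nrow(g1$history), 4L)
})

test_that("classification is invariant under monotone score re-transformations", {
  set.seed(19)
  study <- generate_cohort(quick_sim(), "train", seed = 19)
  x <- batch_center(median_scale(study$expression))
  keep <- mad_filter(x, 0.3)$matrix
  r <- null_deviance_residuals(study$clinical$time_years, study$clinical$event)
  svr <- fit_svr(keep, standardize_response(r$deviance)$y,
                 probes = rownames(keep)[1:5])
  model <- signature_model(svr, score_samples(svr, keep), r$deviance)
  base <- classify(model, keep)

  # boundary score exactly at the cutoff is Favorable
  i <- which.min(abs(base$score_transformed - model$cutoff))
  m2 <- model
  m2$cutoff <- base$score_transformed[i]
  cls2 <- classify(m2, keep)
  expect_equal(as.character(cls2$class[i]), "Favorable")

  # jointly remapping transformed scores and cutoff never changes classes
  monotone_maps <- list(function(v) v^3, function(v) exp(2 * v),
                        function(v) atan(5 * v) + 2)
  for (fmap in monotone_maps) {
    mm <- model
    mm$transform$transformed <- fmap(model$transform$transformed)
    mm$cutoff <- fmap(model$cutoff)
    expect_equal(classify(mm, keep)$class, base$class)
  }
})

test_that("signature models serialize to text and reload exactly", {
  set.seed(8)
  study <- generate_cohort(quick_sim(), "train", seed = 8)
  x <- batch_center(median_scale(study$expression))
  keep <- mad_filter(x, 0.3)$matrix
  r <- null_deviance_residuals(study$clinical$time_years, study$clinical$event)
  svr <- fit_svr(keep, standardize_response(r$deviance)$y,
                 probes = rownames(keep)[1:4])
  model <- signature_model(svr, score_samples(svr, keep), r$deviance,
                           preprocess_reference = list(
                             target_median = 8,
                             probe_means = as.list(rowMeans(unclass(keep))[1:4])),
                           metadata = list(seed = 8))
  p <- withr::local_tempfile(fileext = ".json")
  write_signature_model(model, p)
  back <- read_signature_model(p)
  expect_identical(back$probes, model$probes)
  expect_equal(back$cutoff, model$cutoff)
  expect_equal(classify(back, keep)$class, classify(model, keep)$class)
  expect_equal(score_samples(back, keep), score_samples(model, keep),
               tolerance = 1e-12)
  # missing probes error
  expect_error(classify(model, keep[6:10, ]), "absent")
})
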