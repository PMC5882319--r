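# Model-selection engine: response standardization, rank-based inverse-normal
# score transform, single-split partition cutoff, repeated-holdout CV, and
# the genetic-algorithm probe-subset search.

#' Standardize a response vector to unit mean square
#'
#' Scales the deviance-residual response so its Euclidean length equals
#' \eqn{\sqrt{n}} (equivalently, mean square 1), which makes the SVR epsilon
#' band and regularization scale-free.
#'
#' @param d Numeric response vector (non-zero).
#' @return A list with `y` (scaled vector) and `scale` (the multiplier, for
#'   inversion).
#' @export
standardize_response <- function(d) {
  assert_that(all(is.finite(d)), "response must be finite")
  len <- sqrt(sum(d^2))
  assert_that(len > 0, "response vector is identically zero")
  scale <- sqrt(length(d)) / len
  list(y = d * scale, scale = scale)
}

#' Rank-based inverse-normal score transform
#'
#' Maps scores through Blom-offset normal quantiles
#' \eqn{\Phi^{-1}((r_i - 0.375)/(n + 0.25))} (average ranks for ties) and
#' affinely rescales into (0, 1). Strictly monotone, outlier-compressing, and
#' symmetric: mirrored ranks map to values symmetric about 0.5.
#'
#' @param scores Numeric vector with at least 2 distinct values.
#' @return Transformed scores in (0, 1).
#' @export
inverse_transform_scores <- function(scores) {
  assert_that(all(is.finite(scores)), "scores must be finite")
  n <- length(scores)
  assert_that(length(unique(scores)) >= 2L, "scores are all equal: nothing to transform")
  r <- rank(scores, ties.method = "average")
  z <- stats::qnorm((r - 0.375) / (n + 0.25))
  lo <- stats::qnorm(0.25 / (n + 0.25))
  (z - lo) / (-2 * lo)
}

#' Partition-analysis risk cutoff
#'
#' The single CART-style regression split of the scores against the deviance
#' residuals: the returned cutoff is the midpoint of the adjacent distinct
#' score pair whose split maximizes the between-group sum-of-squares
#' reduction of the residuals. Ties are broken toward the smaller cutoff.
#'
#' @param scores Numeric scores (>= 2 distinct values).
#' @param d Deviance residuals (not constant), same length.
#' @return The cutoff, with attributes `sse_before` and `sse_after`.
#' @export
partition_cutoff <- function(scores, d) {
  assert_that(length(scores) == length(d), "scores and residuals lengths differ")
  assert_that(length(scores) >= 2L, "need at least 2 samples")
  assert_that(length(unique(scores)) >= 2L, "scores are all equal: no split exists")
  assert_that(stats::sd(d) > 0, "constant residuals: no informative split")
  ord <- order(scores)
  s <- scores[ord]
  y <- d[ord]
  su <- unique(s)
  candidates <- (su[-length(su)] + su[-1L]) / 2
  sse <- function(v) if (length(v) == 0L) 0 else sum((v - mean(v))^2)
  total <- sse(y)
  best_c <- NA_real_
  best_after <- Inf
  for (cc in candidates) {
    left <- y[s <= cc]
    right <- y[s > cc]
    after <- sse(left) + sse(right)
    if (after < best_after - 1e-12) {
      best_after <- after
      best_c <- cc
    }
  }
  structure(best_c, sse_before = total, sse_after = best_after)
}

#' Repeated-holdout cross-validation of an SVR probe subset
#'
#' Runs `folds` independent random splits (not a partition): each repetition
#' holds out `holdout` of the samples, fits the SVR on the rest and records
#' the holdout root-mean-square error.
#'
#' @param x An [expression_matrix()].
#' @param y Numeric response per sample.
#' @param probes Probe subset to evaluate.
#' @param folds Number of repetitions (default 50).
#' @param holdout Holdout fraction in (0, 1) (default 0.10); must amount to
#'   at least one sample.
#' @param seed Integer seed.
#' @param cost,epsilon,gamma SVR hyperparameters passed to [fit_svr()].
#' @return A `cv_report` tibble (`rep`, `rmse`) with `folds`, `holdout`,
#'   `seed` and `mean_rmse` attributes; see [glance()].
#' @export
cross_validate <- function(x, y, probes = NULL, folds = 50L, holdout = 0.10,
                           seed = 1L, cost = 1, epsilon = 0.1, gamma = NULL) {
  assert_that(folds >= 1L, "`folds` must be >= 1")
  assert_that(holdout > 0 && holdout < 1, "`holdout` must be in (0, 1)")
  n <- ncol(x)
  n_hold <- floor(holdout * n)
  assert_that(n_hold >= 1L, "holdout fraction leaves less than one sample")
  probes <- probes %||% rownames(x)
  rmse <- with_seed(seed, vapply(seq_len(folds), function(i) {
    hold <- sample.int(n, n_hold)
    fit <- fit_svr(x[, -hold], y[-hold], probes = probes,
                   cost = cost, epsilon = epsilon, gamma = gamma)
    pred <- predict(fit, x[, hold])
    sqrt(mean((y[hold] - pred)^2))
  }, numeric(1)))
  out <- tibble::tibble(rep = seq_len(folds), rmse = rmse)
  attr(out, "folds") <- folds
  attr(out, "holdout") <- holdout
  attr(out, "seed") <- seed
  attr(out, "mean_rmse") <- mean(rmse)
  class(out) <- c("cv_report", class(out))
  out
}

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(folds = attr(x, "folds"), holdout = attr(x, "holdout"),
                 mean_rmse = attr(x, "mean_rmse"))
}

#' Genetic-algorithm configuration
#'
#' Hyperparameters of the probe-subset search: bit-mask encoding with
#' subset-size repair, tournament selection, uniform crossover, per-bit
#' mutation, elitism. Defaults are sized for a candidate pool of a few
#' hundred probes with a target signature of about 18 probes.
#'
#' @param pop_size Population size (>= 2); default 100.
#' @param generations Number of generations; default 50.
#' @param p_crossover Uniform-crossover probability; default 0.8.
#' @param p_mutation Per-bit mutation probability; default `1 / pool size`.
#' @param size_min,size_max Allowed subset sizes; defaults 14 and 22
#'   (centred on 18).
#' @param elitism Number of best individuals copied unchanged; default 1.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100L, generations = 50L, p_crossover = 0.8,
                      p_mutation = NULL, size_min = 14L, size_max = 22L,
                      elitism = 1L, seed = 1L) {
  assert_that(pop_size >= 2L, "population must be >= 2")
  assert_that(generations >= 1L, "generations must be >= 1")
  assert_that(p_crossover >= 0 && p_crossover <= 1, "p_crossover must be in [0, 1]")
  if (!is.null(p_mutation)) {
    assert_that(p_mutation >= 0 && p_mutation <= 1, "p_mutation must be in [0, 1]")
  }
  assert_that(size_min >= 1L && size_min <= size_max, "need 1 <= size_min <= size_max")
  assert_that(elitism >= 0L && elitism < pop_size, "elitism must be < pop_size")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 size_min = as.integer(size_min), size_max = as.integer(size_max),
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

# lexicographic model-score comparison: max C, then min AIC, min BIC, min RMSE
score_better <- function(a, b) {
  if (a$c_index != b$c_index) return(a$c_index > b$c_index)
  if (a$aic != b$aic) return(a$aic < b$aic)
  if (a$bic != b$bic) return(a$bic < b$bic)
  a$rmse < b$rmse
}

model_score <- function(pred, y, time, event, n_probes) {
  n <- length(y)
  rss <- sum((y - pred)^2)
  k <- n_probes + 1
  list(
    c_index = harrell_c(pred, time, event),
    aic = n * log(max(rss / n, .Machine$double.xmin)) + 2 * k,
    bic = n * log(max(rss / n, .Machine$double.xmin)) + k * log(n),
    rmse = sqrt(rss / n)
  )
}

#' Genetic-algorithm probe-subset selection
#'
#' Searches probe subsets (bit masks over the filtered candidate pool) that
#' maximize, lexicographically, the Harrell concordance of the SVR's
#' predictions with the survival outcomes, then minimize AIC, BIC and RMSE.
#' By default each candidate is scored on out-of-fold predictions from a
#' V-fold cross-validation whose fold assignment is drawn once per run:
#' with tens of events and hundreds of candidate probes, in-sample
#' concordance is maximized by overfit noise subsets, and only an
#' out-of-sample fitness gives the search a gradient toward real signal
#' (`fitness = "insample"` restores the naive behaviour). The initial
#' population and size-repair steps sample probes with weights proportional
#' to their marginal Spearman association with the response, biasing the
#' search toward marginally informative probes. The best individual ever
#' seen is returned; with a fixed seed the whole search is reproducible.
#'
#' @param x Filtered candidate [expression_matrix()] (pool of probes).
#' @param y Standardized response (deviance-residual scale), one per sample.
#' @param time,event Survival outcomes used for the concordance fitness.
#' @param config A [ga_config()].
#' @param cost,epsilon,gamma SVR hyperparameters.
#' @param fitness `"cv"` (default) or `"insample"`.
#' @param fitness_folds Folds of the fitness cross-validation (default 5).
#' @return A `ga_result`: `probes` (best subset), `score` (c_index, aic,
#'   bic, rmse, on the fitness predictions), `history` tibble of
#'   per-generation fitness, and the config.
#' @export
ga_select <- function(x, y, time, event, config = ga_config(),
                      cost = 1, epsilon = 0.1, gamma = NULL,
                      fitness = c("cv", "insample"), fitness_folds = 5L) {
  fitness <- match.arg(fitness)
  assert_that(inherits(config, "ga_config"), "`config` must be a ga_config")
  pool <- rownames(x)
  p <- length(pool)
  assert_that(p >= config$size_min,
              "candidate pool (%d) smaller than minimum subset size (%d)",
              p, config$size_min)
  size_max <- min(config$size_max, p)
  size_min <- config$size_min
  p_mut <- config$p_mutation %||% (1 / p)
  # marginal association weights for initialization and repair
  w <- abs(apply(unclass(x), 1L, function(v) {
    stats::cor(v, y, method = "spearman")
  }))
  w[!is.finite(w)] <- 0
  w <- w + 1e-6

  with_seed(config$seed, {
    n <- ncol(x)
    draw_folds <- function() sample(rep_len(seq_len(fitness_folds), n))
    eval_mask <- function(mask, fold_of) {
      probes <- pool[mask]
      if (fitness == "insample") {
        fit <- fit_svr(x, y, probes = probes, cost = cost, epsilon = epsilon,
                       gamma = gamma)
        pred <- fit$train_pred
      } else {
        pred <- numeric(n)
        for (v in seq_len(fitness_folds)) {
          hold <- fold_of == v
          fit <- fit_svr(x[, !hold], y[!hold], probes = probes, cost = cost,
                         epsilon = epsilon, gamma = gamma)
          pred[hold] <- predict(fit, x[, hold])
        }
      }
      model_score(pred, y, time, event, length(probes))
    }
    # evaluate a whole generation on one fold draw, deduplicating masks
    eval_generation <- function(popn) {
      fold_of <- if (fitness == "cv") draw_folds() else NULL
      keys <- vapply(popn, function(m) paste(which(m), collapse = ","), character(1))
      uniq <- !duplicated(keys)
      cache <- lapply(popn[uniq], eval_mask, fold_of = fold_of)
      names(cache) <- keys[uniq]
      lapply(keys, function(k) cache[[k]])
    }
    # averaged multi-repeat CV score used for the final model choice
    eval_final <- function(mask, reps = 3L) {
      ss <- lapply(seq_len(reps), function(r) {
        eval_mask(mask, if (fitness == "cv") draw_folds() else NULL)
      })
      list(c_index = mean(vapply(ss, `[[`, numeric(1), "c_index")),
           aic = mean(vapply(ss, `[[`, numeric(1), "aic")),
           bic = mean(vapply(ss, `[[`, numeric(1), "bic")),
           rmse = mean(vapply(ss, `[[`, numeric(1), "rmse")))
    }
    repair <- function(mask) {
      size <- sum(mask)
      while (size > size_max) {
        drop <- sample(which(mask), 1L)
        mask[drop] <- FALSE
        size <- size - 1L
      }
      while (size < size_min) {
        off <- which(!mask)
        add <- if (length(off) == 1L) off else sample(off, 1L, prob = w[off])
        mask[add] <- TRUE
        size <- size + 1L
      }
      mask
    }
    new_mask <- function() {
      size <- sample(seq(size_min, size_max), 1L)
      mask <- rep(FALSE, p)
      mask[sample.int(p, size, prob = w)] <- TRUE
      mask
    }
    rank_order <- function(scores) {
      order(-vapply(scores, `[[`, numeric(1), "c_index"),
            vapply(scores, `[[`, numeric(1), "aic"),
            vapply(scores, `[[`, numeric(1), "bic"),
            vapply(scores, `[[`, numeric(1), "rmse"))
    }
    initial_popn <- lapply(seq_len(config$pop_size), function(i) new_mask())
    popn <- initial_popn
    scores <- eval_generation(popn)
    ord <- rank_order(scores)
    gen_best_masks <- list()
    history <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      tournament <- function() {
        cand <- sample.int(config$pop_size, 2L)
        if (score_better(scores[[cand[1L]]], scores[[cand[2L]]])) cand[1L] else cand[2L]
      }
      offspring <- vector("list", config$pop_size)
      n_elite <- config$elitism
      if (n_elite > 0L) {
        for (e in seq_len(n_elite)) offspring[[e]] <- popn[[ord[e]]]
      }
      for (i in seq(n_elite + 1L, config$pop_size)) {
        p1 <- popn[[tournament()]]
        p2 <- popn[[tournament()]]
        child <- if (stats::runif(1) < config$p_crossover) {
          take1 <- stats::runif(p) < 0.5
          ifelse(take1, p1, p2)
        } else {
          p1
        }
        flip <- stats::runif(p) < p_mut
        child <- xor(child, flip)
        offspring[[i]] <- repair(child)
      }
      popn <- offspring
      scores <- eval_generation(popn)
      ord <- rank_order(scores)
      gen_best_masks[[gen]] <- popn[[ord[1L]]]
      history[[gen]] <- tibble::tibble(
        generation = gen,
        best_c = scores[[ord[1L]]]$c_index,
        mean_c = mean(vapply(scores, `[[`, numeric(1), "c_index"))
      )
    }
    # final choice: re-score every distinct finalist (initial population,
    # per-generation bests, final population) with repeated CV and keep the
    # lexicographic best under that common measure
    finalists <- c(initial_popn, gen_best_masks, popn)
    keys <- vapply(finalists, function(m) paste(which(m), collapse = ","), character(1))
    finalists <- finalists[!duplicated(keys)]
    final_scores <- lapply(finalists, eval_final)
    fo <- rank_order(final_scores)
    best_mask <- finalists[[fo[1L]]]
    best_score <- final_scores[[fo[1L]]]
    structure(list(
      probes = pool[best_mask],
      score = best_score,
      history = dplyr::bind_rows(history),
      config = config,
      fitness = fitness
    ), class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA probe selection: %d probes, C=%.4f (pop %d, %d generations)\n",
              length(x$probes), x$score$c_index, x$config$pop_size,
              x$config$generations))
  invisible(x)
}

#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(n_probes = length(x$probes), c_index = x$score$c_index,
                 aic = x$score$aic, bic = x$score$bic, rmse = x$score$rmse)
}

#' @export
tidy.ga_result <- function(x, ...) x$history

#' Assemble a complete signature model
#'
#' Bundles the fitted regressor with the score transform (stored as the
#' training raw-score / transformed-score pairs, applied to new cohorts by
#' monotone interpolation), the partition cutoff, the response scale and the
#' frozen preprocessing references needed to apply the model prospectively.
#'
#' @param svr An `svr_fit`.
#' @param train_scores Raw training scores from [score_samples()].
#' @param residuals Training deviance residuals (cutoff response).
#' @param response_scale Scale constant from [standardize_response()].
#' @param preprocess_reference List with `target_median` and named
#'   `probe_means` for frozen normalization of new cohorts.
#' @param metadata List of provenance fields (seed, config hash, ...).
#' @return A `signature_model`.
#' @export
signature_model <- function(svr, train_scores, residuals, response_scale = 1,
                            preprocess_reference = NULL, metadata = list()) {
  assert_that(inherits(svr, "svr_fit"), "`svr` must be an svr_fit")
  transformed <- inverse_transform_scores(train_scores)
  cutoff <- partition_cutoff(transformed, residuals)
  ord <- order(train_scores)
  raw_sorted <- train_scores[ord]
  trans_sorted <- transformed[ord]
  keep <- !duplicated(raw_sorted)
  rng <- range(transformed)
  assert_that(cutoff > rng[1L] && cutoff < rng[2L],
              "cutoff must lie strictly inside the transformed-score range")
  structure(list(
    probes = svr$probes,
    svr = svr,
    response_scale = response_scale,
    transform = list(raw = raw_sorted[keep], transformed = trans_sorted[keep]),
    cutoff = as.numeric(cutoff),
    classes = c("Favorable", "Non-favorable"),
    preprocess_reference = preprocess_reference,
    metadata = metadata
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d probes, cutoff %.4f (%s vs %s)\n",
              length(x$probes), x$cutoff, x$classes[1L], x$classes[2L]))
  invisible(x)
}

# apply the frozen training score transform to new raw scores by monotone
# piecewise-linear interpolation (constant beyond the training range)
apply_transform <- function(model, raw) {
  tr <- model$transform
  if (length(tr$raw) == 1L) return(rep(tr$transformed, length(raw)))
  stats::approx(tr$raw, tr$transformed, xout = raw, rule = 2, ties = "ordered")$y
}

#' Classify samples into Favorable / Non-favorable risk classes
#'
#' Scores the samples with the model's regressor, maps them through the
#' frozen training score transform, and thresholds at the stored partition
#' cutoff: transformed score > cutoff is Non-favorable (higher recurrence
#' risk), <= cutoff is Favorable. Never abstains.
#'
#' @param model A `signature_model`.
#' @param x An [expression_matrix()] containing all model probes.
#' @return A tibble with `sample_id`, `score` (raw), `score_transformed`,
#'   and `class` (factor Favorable / Non-favorable).
#' @export
classify <- function(model, x) {
  assert_that(inherits(model, "signature_model"), "`model` must be a signature_model")
  raw <- score_samples(model$svr, x)
  trans <- apply_transform(model, raw)
  cls <- factor(ifelse(trans > model$cutoff, "Non-favorable", "Favorable"),
                levels = model$classes)
  tibble::tibble(sample_id = colnames(x), score = unname(raw),
                 score_transformed = unname(trans), class = cls)
}

#' Serialize and restore a signature model
#'
#' The model is written as structured JSON text (probe ids, SVR
#' hyperparameters, support vectors, dual coefficients, score transform,
#' cutoff, preprocessing references, metadata) at full numeric precision, so
#' a reload reproduces classification bit-identically.
#'
#' @param model A `signature_model`.
#' @param path Output path (`.json`).
#' @export
write_signature_model <- function(model, path) {
  payload <- list(
    format = "survsig_signature_model",
    version = 1L,
    probes = model$probes,
    response_scale = model$response_scale,
    svr = list(
      center = as.numeric(model$svr$center),
      scale = as.numeric(model$svr$scale),
      gamma = model$svr$gamma, cost = model$svr$cost,
      epsilon = model$svr$epsilon,
      sv = model$svr$sv, dual_coefs = model$svr$dual_coefs,
      rho = model$svr$rho,
      pred_mean = model$svr$pred_mean, pred_sd = model$svr$pred_sd
    ),
    transform = model$transform,
    cutoff = model$cutoff,
    classes = model$classes,
    preprocess_reference = model$preprocess_reference,
    metadata = model$metadata
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_model
#' @return `read_signature_model()`: the restored `signature_model`.
#' @export
read_signature_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(payload$format, "survsig_signature_model"),
              "not a signature model file: %s", path)
  svr <- structure(list(
    probes = payload$probes,
    center = stats::setNames(payload$svr$center, payload$probes),
    scale = stats::setNames(payload$svr$scale, payload$probes),
    gamma = payload$svr$gamma, cost = payload$svr$cost,
    epsilon = payload$svr$epsilon,
    sv = matrix(as.numeric(payload$svr$sv), ncol = length(payload$probes)),
    dual_coefs = as.numeric(payload$svr$dual_coefs),
    rho = payload$svr$rho,
    pred_mean = payload$svr$pred_mean, pred_sd = payload$svr$pred_sd
  ), class = "svr_fit")
  ref <- payload$preprocess_reference
  if (!is.null(ref) && !is.null(ref$probe_means)) {
    ref$probe_means <- unlist(ref$probe_means)
  }
  structure(list(
    probes = payload$probes,
    svr = svr,
    response_scale = payload$response_scale,
    transform = list(raw = as.numeric(payload$transform$raw),
                     transformed = as.numeric(payload$transform$transformed)),
    cutoff = payload$cutoff,
    classes = payload$classes,
    preprocess_reference = ref,
    metadata = payload$metadata
  ), class = "signature_model")
}
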