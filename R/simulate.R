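# Synthetic paired-cohort generator. Emulates the data model the pipeline
# assumes: block-correlated log2-like expression with additive batch
# offsets, a small planted prognostic probe set whose signal is
# survival-linked (not mean-shifted), exponential proportional-hazards event
# times, and censoring calibrated to a heavy target fraction.

#' Simulation configuration
#'
#' Defaults describe the emulated study: a 127-sample training cohort across
#' 3 batches and a 62-sample single-batch validation cohort; 2000 probes of
#' which 18 carry prognostic signal; pervasive co-expression (150 background
#' blocks of 10 probes at within-block correlation 0.9, as in real microarray
#' data); censoring targets 85.83% (training) and
#' 80.65% (validation) inside a 0.05-25.42 year follow-up window.
#'
#' @param n_train,n_validation Cohort sizes.
#' @param n_probes Total probes.
#' @param n_signature Number of planted prognostic probes.
#' @param beta Effect sizes for the planted probes (on the standardized
#'   expression scale). Default: +/- 0.1 (first half positive, second half
#'   negative), which puts the oracle concordance of the true linear
#'   predictor near 0.85 under the default single prognostic program.
#' @param n_blocks,block_size,block_cor Correlated-block structure of the
#'   background probes.
#' @param signature_cor Loading-squared of the planted probes on their
#'   prognostic program (default 0.93): high enough that the program forms a
#'   tight co-expression cluster that survives the correlation-radius
#'   redundancy filter and that every member is marginally associated with
#'   outcome; each probe's residual component still enters the hazard.
#' @param n_signature_modules Number of latent prognostic programs the
#'   planted probes load on (default 1: a single aggressiveness axis whose
#'   member genes are up- or down-regulated according to `sign(beta)`,
#'   mirroring how recurrence signatures present in real expression data as
#'   coherent co-expression programs; 0 = mutually independent planted
#'   probes, which makes individual probe identities essentially
#'   undetectable at these sample sizes).
#' @param n_batches_train,n_batches_validation Batches per cohort.
#' @param batch_sd SD of the per-batch, per-probe additive offsets.
#' @param sd_range Range of per-probe residual SDs (uniform draw), chosen so
#'   probe MADs straddle the 0.5 filter threshold.
#' @param lambda0 Baseline hazard (events/year); `NULL` = calibrate
#'   numerically to the cohort's censoring target.
#' @param censoring_train,censoring_validation Target censoring fractions.
#' @param followup_min,followup_max Administrative follow-up window (years).
#' @param weibull_shape Shape of the baseline time distribution (1 =
#'   exponential).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_train = 127L, n_validation = 62L, n_probes = 2000L,
                       n_signature = 18L, beta = NULL,
                       n_blocks = 150L, block_size = 10L, block_cor = 0.9,
                       signature_cor = 0.93, n_signature_modules = 1L,
                       n_batches_train = 3L, n_batches_validation = 1L,
                       batch_sd = 0.3, sd_range = c(0.25, 1.0),
                       lambda0 = NULL,
                       censoring_train = 0.8583, censoring_validation = 0.8065,
                       followup_min = 0.05, followup_max = 25.42,
                       weibull_shape = 1) {
  assert_that(n_train > 0 && n_validation > 0 && n_probes > 0 && n_signature > 0,
              "all counts must be positive")
  assert_that(n_signature <= n_probes, "more signature probes than probes")
  assert_that(censoring_train > 0 && censoring_train < 1 &&
              censoring_validation > 0 && censoring_validation < 1,
              "censoring targets must be in (0, 1)")
  assert_that(block_cor >= 0 && block_cor < 1, "block correlation must be in [0, 1)")
  assert_that(signature_cor >= 0 && signature_cor < 1, "signature correlation must be in [0, 1)")
  assert_that(n_blocks * block_size <= n_probes, "block structure exceeds probe count")
  assert_that(followup_min > 0 && followup_min < followup_max,
              "need 0 < followup_min < followup_max")
  assert_that(n_signature_modules >= 0, "`n_signature_modules` must be >= 0")
  half <- ceiling(n_signature / 2)
  beta <- beta %||% (0.1 * c(rep(1, half), rep(-1, n_signature - half)))
  assert_that(length(beta) == n_signature, "need one effect size per signature probe")
  structure(list(
    n_train = as.integer(n_train), n_validation = as.integer(n_validation),
    n_probes = as.integer(n_probes), n_signature = as.integer(n_signature),
    beta = beta, n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), block_cor = block_cor,
    signature_cor = signature_cor,
    n_batches_train = as.integer(n_batches_train),
    n_batches_validation = as.integer(n_batches_validation),
    batch_sd = batch_sd, sd_range = sd_range, lambda0 = lambda0,
    n_signature_modules = as.integer(n_signature_modules),
    censoring_train = censoring_train,
    censoring_validation = censoring_validation,
    followup_min = followup_min, followup_max = followup_max,
    weibull_shape = weibull_shape
  ), class = "sim_config")
}

# shared across cohorts: probe ids, block membership, per-probe mean/sd,
# planted probes and effect signs; derived deterministically from the seed so
# the training and validation cohorts describe the same assay
sim_structure <- function(config, seed) {
  with_seed(seed, {
    probes <- sprintf("probe_%05d", seq_len(config$n_probes))
    block_of <- rep(NA_integer_, config$n_probes)
    block_probes <- sample.int(config$n_probes, config$n_blocks * config$block_size)
    block_of[block_probes] <- rep(seq_len(config$n_blocks), each = config$block_size)
    free <- setdiff(seq_len(config$n_probes), block_probes)
    planted <- sample(free, config$n_signature)
    # planted probes load on shared prognostic programs (appended after the
    # background blocks as extra latent factors); the loading sign follows
    # sign(beta), so one program carries both up- and down-regulated genes
    ms <- config$n_signature_modules
    if (ms > 0) {
      module <- rep_len(rep(seq_len(ms), each = ceiling(config$n_signature / ms)),
                        config$n_signature)
      block_of[planted] <- config$n_blocks + module
    }
    sd <- stats::runif(config$n_probes, config$sd_range[1L], config$sd_range[2L])
    # prognostic probes are simulated as high-variability probes: a signature
    # discoverable by a MAD-filtered workflow is necessarily variable, so the
    # planted truth must not be removed by the pipeline's own filters
    hi <- max(config$sd_range[2L] - 0.15, mean(config$sd_range))
    sd[planted] <- stats::runif(config$n_signature, hi, config$sd_range[2L])
    list(
      probes = probes,
      block_of = block_of,
      planted = probes[planted],
      planted_idx = planted,
      mu = stats::rnorm(config$n_probes, mean = 8, sd = 1.5),
      sd = sd
    )
  })
}

# expected censoring fraction with T ~ Weibull(shape, rate lambda_i) and
# dropout U ~ Unif(a, W): P(censored_i) = E_U[ S_i(U) ], averaged over i
expected_censoring <- function(lambda, shape, a, W) {
  grid <- seq(a, W, length.out = 200L)
  surv <- vapply(grid, function(u) mean(exp(-(lambda * u)^shape)), numeric(1))
  mean(surv) # uniform weight over the grid approximates the U-average
}

calibrate_lambda0 <- function(eta, target, shape, a, W) {
  f <- function(log_l0) {
    lam <- exp((log_l0 + eta) / shape) # (lambda0 * exp(eta))^(1/shape) scale
    expected_censoring(lam, shape, a, W) - target
  }
  lo <- log(1e-6); hi <- log(50)
  if (f(lo) < 0) stopf("censoring target %.3f infeasible: even hazard %g censors less", target, 1e-6)
  if (f(hi) > 0) stopf("censoring target %.3f infeasible: hazard %g still censors more", target, 50)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Generate one synthetic cohort
#'
#' Expression values are built from shared per-block latent factors (giving
#' within-block correlation), independent probe noise, per-batch additive
#' offsets and a log2-like baseline. The planted probes' standardized,
#' batch-free values define the linear predictor
#' \eqn{\eta_i = \sum_g \beta_g z_{gi}}; event times are drawn from a
#' proportional-hazards Weibull (exponential by default) with baseline rate
#' calibrated so the expected censoring fraction under uniform dropout in
#' the follow-up window hits the cohort target. A WHO-grade-like covariate
#' is generated correlated with \eqn{\eta}; the remaining clinical
#' covariates are drawn independently with realistic frequencies.
#'
#' @param config A [sim_config()].
#' @param cohort `"train"` or `"validation"`.
#' @param seed Integer seed. The assay structure (probe identities, blocks,
#'   planted set, effect sizes) is derived from `seed` alone, so the two
#'   cohorts of one study share it when generated with the same seed.
#' @return A list with `expression` ([expression_matrix()]), `clinical`
#'   (tibble), and `truth` (planted probe ids, `beta`, `eta`, true event and
#'   censoring times, batch assignment, realized censoring fraction,
#'   calibrated `lambda0`).
#' @export
generate_cohort <- function(config, cohort = c("train", "validation"), seed = 1L) {
  cohort <- match.arg(cohort)
  stru <- sim_structure(config, seed)
  n <- if (cohort == "train") config$n_train else config$n_validation
  n_batches <- if (cohort == "train") config$n_batches_train else config$n_batches_validation
  target <- if (cohort == "train") config$censoring_train else config$censoring_validation
  draw_seed <- stage_seed(seed, if (cohort == "train") "simulate" else "simulate_validation")
  for (attempt in 0:9) {
    out <- with_seed(draw_seed + attempt * 1000L, {
      p <- config$n_probes
      # latent block/module factors and probe-level noise, standardized scale
      n_fac <- config$n_blocks + config$n_signature_modules
      fac <- matrix(stats::rnorm(n_fac * n), n_fac, n)
      z <- matrix(stats::rnorm(p * n), p, n)
      inb <- !is.na(stru$block_of)
      rho_of <- ifelse(stru$block_of <= config$n_blocks,
                       config$block_cor, config$signature_cor)
      z[inb, ] <- sqrt(rho_of[inb]) * fac[stru$block_of[inb], , drop = FALSE] +
        sqrt(1 - rho_of[inb]) * z[inb, , drop = FALSE]
      if (config$n_signature_modules > 0) {
        z[stru$planted_idx, ] <- sign(config$beta) * z[stru$planted_idx, , drop = FALSE]
      }
      eta <- drop(crossprod(z[stru$planted_idx, , drop = FALSE], config$beta))
      # batch structure and observed expression
      batch_sizes <- diff(round(seq(0, n, length.out = n_batches + 1L)))
      batch <- rep(sprintf("batch%d", seq_len(n_batches)), times = batch_sizes)
      offs <- matrix(stats::rnorm(p * n_batches, sd = config$batch_sd), p, n_batches)
      values <- stru$mu + stru$sd * z +
        offs[, match(batch, sprintf("batch%d", seq_len(n_batches))), drop = FALSE]
      dimnames(values) <- list(stru$probes, sprintf("%s_s%03d", cohort, seq_len(n)))
      # survival under proportional hazards
      shape <- config$weibull_shape
      lambda0 <- config$lambda0 %||%
        calibrate_lambda0(eta, target, shape, config$followup_min, config$followup_max)
      scale_i <- 1 / (lambda0 * exp(eta))^(1 / shape)
      t_true <- stats::rweibull(n, shape = shape, scale = scale_i)
      dropout <- stats::runif(n, config$followup_min, config$followup_max)
      time <- pmin(t_true, dropout)
      event <- as.integer(t_true <= dropout)
      # WHO-grade-like covariate correlated with the hazard
      eta_std <- if (stats::sd(eta) > 0) (eta - mean(eta)) / stats::sd(eta) else rep(0, n)
      gl <- eta_std + stats::rnorm(n)
      grade <- cut(gl, breaks = stats::quantile(gl, c(0, 0.72, 0.97, 1)),
                   labels = c("I", "II", "III"), include.lowest = TRUE)
      clinical <- tibble::tibble(
        sample_id = colnames(values),
        time_years = pmax(time, 1e-3),
        event = event,
        who_grade = factor(grade, levels = c("I", "II", "III")),
        mitotic_category = factor(sample(c("<=2", "3-4", ">=5"), n, TRUE,
                                         prob = c(0.63, 0.22, 0.15)),
                                  levels = c("<=2", "3-4", ">=5")),
        simpson_grade = factor(sample(c("1", "2", "3", "4"), n, TRUE,
                                      prob = c(0.47, 0.27, 0.07, 0.19)),
                               levels = c("1", "2", "3", "4")),
        sex = factor(sample(c("F", "M"), n, TRUE, prob = c(0.69, 0.31)),
                     levels = c("F", "M")),
        location = factor(sample(c("skull-base", "non-skull-base"), n, TRUE,
                                 prob = c(0.71, 0.29)),
                          levels = c("non-skull-base", "skull-base"))
      )
      truth <- structure(list(
        planted = stru$planted, beta = config$beta, eta = eta,
        t_true = t_true, censor_time = dropout, batch = batch,
        lambda0 = lambda0, censoring_fraction = mean(event == 0L),
        cohort = cohort, seed = seed
      ), class = "synthetic_truth")
      list(expression = expression_matrix(values, batch = batch),
           clinical = clinical, truth = truth)
    })
    if (sum(out$clinical$event) > 0L) break
    warning(sprintf("degenerate draw with zero events (attempt %d); regenerating", attempt + 1L))
  }
  assert_that(sum(out$clinical$event) > 0L, "could not generate a cohort with events")
  out
}

#' Generate a paired training/validation study
#'
#' Convenience wrapper calling [generate_cohort()] for both cohorts with a
#' shared assay structure.
#'
#' @inheritParams generate_cohort
#' @return A list with elements `train` and `validation`.
#' @export
generate_study <- function(config = sim_config(), seed = 1L) {
  list(train = generate_cohort(config, "train", seed),
       validation = generate_cohort(config, "validation", seed))
}

#' Write a generated cohort to plain-text fixtures
#'
#' Emits `expression.tsv`, `clinical.tsv`, `batch.tsv` and `truth.json` under
#' `dir`, all at full numeric precision so [read_fixtures()] round-trips the
#' in-memory objects exactly and regeneration under the same seed is
#' byte-identical.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Target directory (created if missing).
#' @param overwrite Overwrite existing files? Default `FALSE` (error on
#'   collision).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(cohort, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "clinical.tsv", "batch.tsv", "truth.json"))
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !overwrite) {
    stopf("output file(s) already exist (use overwrite = TRUE): %s",
          paste(basename(existing), collapse = ", "))
  }
  write_expression(cohort$expression, paths[1L])
  write_clinical(cohort$clinical, paths[2L])
  b <- expr_batch(cohort$expression)
  writeLines(c("sample_id\tbatch", paste(names(b), b, sep = "\t")), paths[3L])
  tr <- cohort$truth
  jsonlite::write_json(list(
    planted = tr$planted, beta = tr$beta, eta = tr$eta, t_true = tr$t_true,
    censor_time = tr$censor_time, batch = tr$batch, lambda0 = tr$lambda0,
    censoring_fraction = tr$censoring_fraction, cohort = tr$cohort,
    seed = tr$seed
  ), paths[4L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(dir) {
  expression <- read_expression(file.path(dir, "expression.tsv"),
                                batch = file.path(dir, "batch.tsv"))
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- structure(list(
    planted = tj$planted, beta = tj$beta, eta = tj$eta, t_true = tj$t_true,
    censor_time = tj$censor_time, batch = tj$batch, lambda0 = tj$lambda0,
    censoring_fraction = tj$censoring_fraction, cohort = tj$cohort,
    seed = tj$seed
  ), class = "synthetic_truth")
  list(expression = expression, clinical = clinical, truth = truth)
}
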