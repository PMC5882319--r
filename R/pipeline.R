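# End-to-end orchestration: discovery on a training cohort, frozen
# application to a validation cohort, and text-artifact persistence.

#' Pipeline run configuration
#'
#' @param mad_cutoff MAD filter threshold (log2 units); default 0.5.
#' @param cor_radius Correlation radius of the k-means redundancy filter;
#'   default 0.95.
#' @param kmeans_k Cluster count for the redundancy filter; `NULL` = the
#'   filter's default.
#' @param ga A [ga_config()]. Its seed is overridden by the run seed.
#' @param cv_folds,cv_holdout Repeated-holdout CV settings for the final
#'   model (defaults 50 and 0.10).
#' @param cost,epsilon,gamma SVR hyperparameters.
#' @param seed Top-level run seed; every stochastic stage derives its own
#'   seed from it.
#' @param outdir Optional directory: when set, all reports and the model
#'   artifact are persisted there.
#' @return A `run_config` list.
#' @export
run_config <- function(mad_cutoff = 0.5, cor_radius = 0.95, kmeans_k = NULL,
                       ga = ga_config(), cv_folds = 50L, cv_holdout = 0.10,
                       cost = 1, epsilon = 0.1, gamma = NULL,
                       seed = 1L, outdir = NULL) {
  assert_that(mad_cutoff >= 0, "`mad_cutoff` must be >= 0")
  assert_that(cor_radius >= -1 && cor_radius <= 1, "`cor_radius` must be in [-1, 1]")
  assert_that(inherits(ga, "ga_config"), "`ga` must be a ga_config")
  structure(list(mad_cutoff = mad_cutoff, cor_radius = cor_radius,
                 kmeans_k = kmeans_k, ga = ga, cv_folds = as.integer(cv_folds),
                 cv_holdout = cv_holdout, cost = cost, epsilon = epsilon,
                 gamma = gamma, seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

align_samples <- function(x, clinical) {
  ids_x <- colnames(x)
  ids_c <- clinical$sample_id
  only_x <- setdiff(ids_x, ids_c)
  only_c <- setdiff(ids_c, ids_x)
  if (length(only_x) > 0 || length(only_c) > 0) {
    stopf("sample-id mismatch between expression and clinical tables: %s",
          paste(utils::head(c(only_x, only_c), 5L), collapse = ", "))
  }
  clinical[match(ids_x, ids_c), , drop = FALSE]
}

#' Run signature discovery on a training cohort
#'
#' Executes the full training workflow: median scaling, batch mean-centring,
#' MAD and correlation-radius k-means probe filters, null-model deviance
#' residuals, response standardization, genetic-algorithm probe selection
#' over RBF support-vector regression, repeated-holdout cross-validation of
#' the selected model, probability-like scoring, rank-based inverse-normal
#' score transformation, partition-analysis risk cutoff, classification and
#' evaluation of the training cohort. All randomness derives from
#' `config$seed`. With `config$outdir` set, every intermediate report, the
#' model artifact and a reproducibility manifest are written as text files.
#'
#' @param expression Training [expression_matrix()] with batch labels.
#' @param clinical Clinical tibble (see [as_clinical()]) covering the same
#'   samples.
#' @param config A [run_config()].
#' @return A `discovery_run` list: `model` ([signature_model()]),
#'   `filter_reports`, `residuals`, `ga`, `cv`, `classes`, `evaluation`,
#'   `config`.
#' @export
run_discovery <- function(expression, clinical, config = run_config()) {
  assert_that(inherits(config, "run_config"), "`config` must be a run_config")
  clinical <- as_clinical(clinical)
  clinical <- align_samples(expression, clinical)

  normalized <- median_scale(expression)
  target_median <- attr(normalized, "target_median")
  normalized <- batch_center(normalized)
  probe_ref <- attr(normalized, "probe_reference")

  mf <- mad_filter(normalized, cutoff = config$mad_cutoff)
  assert_that(!is.null(mf$matrix), "no probes survive the MAD filter (cutoff %.3g)",
              config$mad_cutoff)
  kf <- kmeans_redundancy_filter(mf$matrix, radius = config$cor_radius,
                                 k = config$kmeans_k,
                                 seed = stage_seed(config$seed, "kmeans"))
  assert_that(!is.null(kf$matrix), "no probes survive the redundancy filter")
  filter_reports <- dplyr::bind_rows(mf$report, kf$report)
  candidates <- kf$matrix

  resid <- null_deviance_residuals(clinical$time_years, clinical$event)
  std <- standardize_response(resid$deviance)

  ga_cfg <- config$ga
  ga_cfg$seed <- stage_seed(config$seed, "ga")
  ga <- ga_select(candidates, std$y, clinical$time_years, clinical$event,
                  config = ga_cfg, cost = config$cost, epsilon = config$epsilon,
                  gamma = config$gamma)

  svr <- fit_svr(candidates, std$y, probes = ga$probes, cost = config$cost,
                 epsilon = config$epsilon, gamma = config$gamma)
  cv <- cross_validate(candidates, std$y, probes = ga$probes,
                       folds = config$cv_folds, holdout = config$cv_holdout,
                       seed = stage_seed(config$seed, "cv"),
                       cost = config$cost, epsilon = config$epsilon,
                       gamma = config$gamma)

  train_scores <- score_samples(svr, candidates)
  cfg_for_hash <- unclass(config)[setdiff(names(config), "outdir")]
  cfg_for_hash$ga <- unclass(cfg_for_hash$ga)
  model <- signature_model(
    svr, train_scores, resid$deviance, response_scale = std$scale,
    preprocess_reference = list(
      target_median = target_median,
      probe_means = as.list(probe_ref[ga$probes])
    ),
    metadata = list(seed = config$seed, config_hash = hash_object(cfg_for_hash),
                    package_version = as.character(utils::packageVersion("survsig")))
  )
  classes <- classify(model, candidates)
  evaluation <- evaluate_cohort(classes, clinical, covariates = "who_grade")

  run <- structure(list(
    model = model, filter_reports = filter_reports, residuals = resid,
    ga = ga, cv = cv, classes = classes, evaluation = evaluation,
    config = config, clinical = clinical
  ), class = "discovery_run")
  if (!is.null(config$outdir)) persist_discovery(run, config$outdir)
  run
}

#' @export
print.discovery_run <- function(x, ...) {
  cat("Discovery run\n")
  cat(sprintf("  candidate pool: %d -> %d probes after filters\n",
              x$filter_reports$n_input[1L],
              x$filter_reports$n_retained[nrow(x$filter_reports)]))
  print(x$model)
  cat(sprintf("  CV mean RMSE: %.4f (%d x %.0f%% holdout)\n",
              attr(x$cv, "mean_rmse"), attr(x$cv, "folds"),
              100 * attr(x$cv, "holdout")))
  invisible(x)
}

#' @export
glance.discovery_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_probes_selected = length(x$model$probes),
                   cutoff = x$model$cutoff,
                   train_c_index = x$ga$score$c_index,
                   cv_rmse = attr(x$cv, "mean_rmse")),
    glance(x$evaluation)
  )
}

persist_discovery <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_signature_model(run$model, file.path(outdir, "model.json"))
  fr <- run$filter_reports
  fr$eliminated <- vapply(fr$eliminated, function(v) paste(v, collapse = ";"),
                          character(1))
  utils::write.table(fr, file.path(outdir, "filter_reports.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$cv), file.path(outdir, "cv_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$classes),
                     file.path(outdir, "training_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "discovery", seed = run$config$seed,
         config_hash = run$model$metadata$config_hash,
         package_version = run$model$metadata$package_version,
         thresholds = list(mad_cutoff = run$config$mad_cutoff,
                           cor_radius = run$config$cor_radius),
         ga = unclass(run$config$ga),
         n_samples = nrow(run$clinical),
         n_events = sum(run$clinical$event),
         filters = list(n_input = fr$n_input, n_retained = fr$n_retained)),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

#' Apply a frozen signature model to a validation cohort
#'
#' Normalizes the validation expression with the training references stored
#' in the model (median target and per-probe batch-centring locations),
#' scores and classifies with the stored transform and cutoff — no refitting
#' of any kind — and evaluates the resulting risk classes. A cohort with no
#' events yields a partial, flagged report.
#'
#' @param model A [signature_model()] (or a path to a serialized one).
#' @param expression Validation [expression_matrix()]; must contain all
#'   model probes.
#' @param clinical Clinical tibble for the validation samples.
#' @param covariates Covariates for the Cox tables.
#' @return A `validation_run` list: `classes`, `evaluation`, `flags`.
#' @export
run_validation <- function(model, expression, clinical,
                           covariates = c("who_grade", "mitotic_category",
                                          "simpson_grade", "sex", "location")) {
  if (is.character(model)) model <- read_signature_model(model)
  assert_that(inherits(model, "signature_model"), "`model` must be a signature_model")
  clinical <- as_clinical(clinical)
  clinical <- align_samples(expression, clinical)
  miss <- setdiff(model$probes, rownames(expression))
  assert_that(length(miss) == 0L, "validation matrix lacks model probe(s): %s",
              paste(utils::head(miss, 5L), collapse = ", "))

  ref <- model$preprocess_reference
  x <- expression
  if (!is.null(ref)) {
    x <- median_scale(x, target = ref$target_median)
    x <- x[model$probes, ]
    x <- batch_center(x, reference = unlist(ref$probe_means))
  } else {
    x <- x[model$probes, ]
  }
  classes <- classify(model, x)
  flags <- character(0)
  if (sum(clinical$event) == 0L) {
    flags <- c(flags, "no events in validation cohort: partial report")
  }
  evaluation <- evaluate_cohort(classes, clinical, covariates = covariates)
  structure(list(classes = classes, evaluation = evaluation,
                 flags = c(flags, evaluation$flags), model_probes = model$probes),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat("Validation run (frozen model)\n")
  print(x$evaluation)
  invisible(x)
}

#' @export
glance.validation_run <- function(x, ...) glance(x$evaluation)
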