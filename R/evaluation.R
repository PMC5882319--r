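# Evaluation surface: misclassification among recurrences, risk-class
# survival summaries, and uni/multivariable Cox tables with the reference
# levels used throughout (WHO I, mitotic <=2, Simpson 1, F, non-skull-base,
# Favorable).

#' Misclassification rate among event samples
#'
#' Under the convention that every recurrence belongs in the Non-favorable
#' class, returns the fraction of event samples classified Favorable. Labels
#' of non-event samples are irrelevant.
#'
#' @param class Per-sample class labels (Favorable / Non-favorable).
#' @param event 0/1 event indicators (at least one event).
#' @return A number in \[0, 1\].
#' @export
misclassification_among_events <- function(class, event) {
  assert_that(length(class) == length(event), "class and event lengths differ")
  assert_that(sum(event == 1) >= 1, "no event samples: rate undefined")
  mean(as.character(class)[event == 1] == "Favorable")
}

#' Per-class survival summary with log-rank comparison
#'
#' Kaplan-Meier curve and median recurrence-free survival per risk class,
#' plus the two-group log-rank test across classes. When only one class is
#' present a partial report is returned with the log-rank omitted and a flag
#' recorded.
#'
#' @param class Per-sample class labels.
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return A `class_survival` list: `summary` tibble (class, n, events,
#'   median_rfs), `logrank` tibble or `NULL`, per-class `km` fits, `flags`.
#' @export
class_survival_summary <- function(class, time, event) {
  check_surv(time, event)
  cls <- factor(as.character(class), levels = c("Favorable", "Non-favorable"))
  present <- levels(cls)[table(cls) > 0]
  flags <- character(0)
  km <- list()
  rows <- lapply(present, function(cl) {
    idx <- cls == cl
    fit <- km_estimate(time[idx], event[idx])
    km[[cl]] <<- fit
    tibble::tibble(class = cl, n = sum(idx), events = sum(event[idx]),
                   median_rfs = attr(fit, "median"))
  })
  summary <- dplyr::bind_rows(rows)
  logrank <- NULL
  if (length(present) == 2L && sum(event) >= 1) {
    logrank <- logrank_test(time, event, cls)
  } else {
    flags <- c(flags, "single class present: log-rank omitted")
  }
  structure(list(summary = summary, logrank = logrank, km = km, flags = flags),
            class = "class_survival")
}

#' @export
print.class_survival <- function(x, ...) {
  print(x$summary)
  if (!is.null(x$logrank)) {
    cat(sprintf("log-rank chi-square = %.4f, p = %.4g\n",
                x$logrank$statistic, x$logrank$p.value))
  }
  for (f in x$flags) cat("flag:", f, "\n")
  invisible(x)
}

covariate_reference_levels <- list(
  gep_class = "Favorable",
  who_grade = "I",
  mitotic_category = "<=2",
  simpson_grade = "1",
  sex = "F",
  location = "non-skull-base"
)

# expand one covariate into 0/1 contrast columns against its reference level;
# numeric covariates pass through as a single column
expand_covariate <- function(values, name) {
  if (is.numeric(values)) {
    m <- matrix(values, ncol = 1L, dimnames = list(NULL, name))
    return(m)
  }
  v <- factor(as.character(values))
  ref <- covariate_reference_levels[[name]]
  lv <- levels(v)
  if (!is.null(ref) && ref %in% lv) lv <- c(ref, setdiff(lv, ref))
  v <- factor(v, levels = lv)
  others <- lv[-1L]
  m <- vapply(others, function(l) as.numeric(v == l), numeric(length(v)))
  m <- matrix(m, ncol = length(others))
  colnames(m) <- sprintf("%s: %s vs. %s", name, others, lv[1L])
  m
}

fit_cox_rows <- function(time, event, X, analysis) {
  res <- tryCatch(cox_fit(time, event, X), error = function(e) e)
  if (inherits(res, "error")) {
    return(tibble::tibble(
      term = colnames(X), analysis = analysis,
      hr = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      p.value = NA_real_, n = length(time), n_events = sum(event),
      flag = conditionMessage(res)
    ))
  }
  td <- tidy(res)
  tibble::tibble(
    term = td$term, analysis = analysis,
    hr = td$estimate, conf.low = td$conf.low, conf.high = td$conf.high,
    p.value = td$p.value, n = res$n, n_events = res$n_events,
    flag = if (res$monotone) "monotone likelihood (non-estimable stratum)"
           else if (!res$converged) "did not converge" else NA_character_
  )
}

#' Uni- and multivariable Cox tables for a risk classification
#'
#' Reproduces the standard evaluation table: a univariate Cox fit for the
#' signature class and for each requested clinical covariate, then one
#' multivariable fit with all of them. Categorical covariates are expanded
#' against fixed reference levels (WHO I, mitotic index <=2, Simpson 1,
#' female, non-skull-base, Favorable). Samples missing a covariate are
#' dropped for that covariate's univariate fit and listwise for the
#' multivariable fit; non-estimable rows are flagged, never silently
#' dropped.
#'
#' @param clinical Clinical tibble (see [as_clinical()]).
#' @param class Optional per-sample class labels aligned with `clinical`;
#'   included as covariate `gep_class` when given.
#' @param covariates Character vector of clinical covariate columns.
#' @return A tibble with `term`, `analysis` (univariate / multivariate),
#'   `hr`, `conf.low`, `conf.high`, `p.value`, `n`, `n_events`, `flag`.
#' @export
cox_tables <- function(clinical, class = NULL,
                       covariates = c("who_grade", "mitotic_category",
                                      "simpson_grade", "sex", "location")) {
  covariates <- intersect(covariates, names(clinical))
  df <- tibble::as_tibble(clinical)
  if (!is.null(class)) {
    assert_that(length(class) == nrow(df), "class labels must align with clinical rows")
    df$gep_class <- factor(as.character(class), levels = c("Favorable", "Non-favorable"))
    covariates <- c("gep_class", covariates)
  }
  time <- df$time_years
  event <- df$event
  uni <- lapply(covariates, function(cv) {
    vals <- df[[cv]]
    ok <- !is.na(vals)
    if (sum(ok) == 0L) {
      return(tibble::tibble(term = cv, analysis = "univariate",
                            hr = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, p.value = NA_real_,
                            n = 0L, n_events = 0L, flag = "all values missing"))
    }
    X <- expand_covariate(vals[ok], cv)
    fit_cox_rows(time[ok], event[ok], X, "univariate")
  })
  complete <- stats::complete.cases(df[, covariates, drop = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("multivariable fit: %d sample(s) dropped listwise for missing covariates",
                    n_dropped))
  }
  multi <- NULL
  if (sum(complete) > 0L) {
    Xs <- lapply(covariates, function(cv) expand_covariate(df[[cv]][complete], cv))
    X <- do.call(cbind, Xs)
    keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
    dropped_terms <- colnames(X)[!keep]
    multi <- fit_cox_rows(time[complete], event[complete],
                          X[, keep, drop = FALSE], "multivariate")
    if (length(dropped_terms) > 0) {
      multi <- dplyr::bind_rows(multi, tibble::tibble(
        term = dropped_terms, analysis = "multivariate",
        hr = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
        p.value = NA_real_, n = sum(complete), n_events = sum(event[complete]),
        flag = "constant after listwise deletion"))
    }
  }
  out <- dplyr::bind_rows(c(uni, list(multi)))
  attr(out, "n_dropped_listwise") <- n_dropped
  out
}

#' Full evaluation report for a classified cohort
#'
#' Combines the per-class survival summary, the log-rank comparison, the
#' misclassification rate among recurrences, and the Cox tables into one
#' report object.
#'
#' @param classes A tibble from [classify()] (or a vector of class labels).
#' @param clinical Clinical tibble aligned by `sample_id` (or by position
#'   when `classes` is a bare vector).
#' @param covariates Clinical covariates for [cox_tables()].
#' @return A `signature_eval` list with elements `class_survival`,
#'   `misclassification`, `cox`, `flags`; see [tidy()] and [glance()].
#' @export
evaluate_cohort <- function(classes, clinical,
                            covariates = c("who_grade", "mitotic_category",
                                           "simpson_grade", "sex", "location")) {
  if (is.data.frame(classes)) {
    idx <- match(clinical$sample_id, classes$sample_id)
    assert_that(!anyNA(idx), "classes missing sample(s) present in clinical table")
    cls <- classes$class[idx]
  } else {
    assert_that(length(classes) == nrow(clinical),
                "class labels must align with clinical rows")
    cls <- classes
  }
  flags <- character(0)
  cs <- class_survival_summary(cls, clinical$time_years, clinical$event)
  flags <- c(flags, cs$flags)
  mis <- if (sum(clinical$event) >= 1) {
    misclassification_among_events(cls, clinical$event)
  } else {
    flags <- c(flags, "no events: misclassification undefined")
    NA_real_
  }
  cox <- tryCatch(cox_tables(clinical, class = cls, covariates = covariates),
                  error = function(e) {
                    flags <<- c(flags, paste("cox tables failed:", conditionMessage(e)))
                    NULL
                  })
  structure(list(class_survival = cs, misclassification = mis, cox = cox,
                 flags = flags, n = nrow(clinical),
                 n_events = sum(clinical$event)),
            class = "signature_eval")
}

#' @export
print.signature_eval <- function(x, ...) {
  cat(sprintf("Evaluation: n=%d, events=%d, misclassification among events=%s\n",
              x$n, x$n_events,
              ifelse(is.na(x$misclassification), "NA",
                     sprintf("%.4f", x$misclassification))))
  print(x$class_survival)
  if (!is.null(x$cox)) {
    cat("\nCox tables:\n")
    print(as.data.frame(x$cox[, c("term", "analysis", "hr", "conf.low",
                                  "conf.high", "p.value", "flag")]),
          digits = 4)
  }
  invisible(x)
}

#' @export
tidy.signature_eval <- function(x, ...) {
  if (is.null(x$cox)) return(tibble::tibble())
  x$cox
}

#' @export
glance.signature_eval <- function(x, ...) {
  lr <- x$class_survival$logrank
  s <- x$class_survival$summary
  med <- function(cl) {
    v <- s$median_rfs[s$class == cl]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble::tibble(
    n = x$n, events = x$n_events,
    misclassification = x$misclassification,
    logrank_statistic = if (is.null(lr)) NA_real_ else lr$statistic,
    logrank_p = if (is.null(lr)) NA_real_ else lr$p.value,
    median_rfs_favorable = med("Favorable"),
    median_rfs_nonfavorable = med("Non-favorable")
  )
}
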