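#' Median-scale an expression matrix
#'
#' Shifts every sample column by a constant so that all column medians equal a
#' common target: by default the grand median of the input matrix, or an
#' explicit `target` when applying the normalization of a training cohort to a
#' new cohort. Purely additive per column, so within-sample probe differences
#' are preserved exactly and the operation is idempotent.
#'
#' @param x An [expression_matrix()].
#' @param target Optional scalar: the median every column is shifted to.
#' @return An `expr_matrix` of the same dimensions. The realized target is
#'   attached as attribute `"target_median"`.
#' @export
median_scale <- function(x, target = NULL) {
  assert_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  vals <- unclass(x)
  target <- target %||% stats::median(vals)
  col_med <- apply(vals, 2L, stats::median)
  out <- sweep(vals, 2L, col_med - target, `-`)
  out <- expression_matrix(out, batch = unname(expr_batch(x)))
  attr(out, "target_median") <- target
  out
}

#' Mean-centre batch effects
#'
#' Per probe, shifts each batch by a constant so the batch mean lands on the
#' probe's grand mean (discovery use) or on a supplied per-probe reference
#' location (frozen application to a validation cohort). Within-batch
#' deviations are untouched.
#'
#' @param x An [expression_matrix()] whose samples carry batch labels.
#' @param reference Optional named numeric vector of per-probe target
#'   locations (names = probe ids, covering all probes of `x`). When `NULL`,
#'   each probe's own grand mean is used and returned in attribute
#'   `"probe_reference"` so it can be frozen for later cohorts.
#' @return An `expr_matrix` with attribute `"probe_reference"`.
#' @export
batch_center <- function(x, reference = NULL) {
  assert_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  batch <- expr_batch(x)
  assert_that(!anyNA(batch), "every sample needs a batch label")
  vals <- unclass(x)
  if (!is.null(reference)) {
    assert_that(is.numeric(reference) && !is.null(names(reference)),
                "`reference` must be a named numeric vector")
    miss <- setdiff(rownames(vals), names(reference))
    assert_that(length(miss) == 0L,
                "reference lacks %d probe(s), e.g. %s", length(miss),
                paste(utils::head(miss, 3L), collapse = ", "))
    ref <- reference[rownames(vals)]
  } else {
    ref <- rowMeans(vals)
  }
  out <- vals
  for (b in unique(batch)) {
    idx <- which(batch == b)
    bm <- rowMeans(vals[, idx, drop = FALSE])
    out[, idx] <- vals[, idx, drop = FALSE] - (bm - ref)
  }
  out <- expression_matrix(out, batch = unname(batch))
  attr(out, "probe_reference") <- ref
  out
}

new_filter_report <- function(stage, threshold, retained, eliminated) {
  tibble::tibble(
    stage = stage,
    threshold = threshold,
    n_input = length(retained) + length(eliminated),
    n_retained = length(retained),
    n_eliminated = length(eliminated),
    eliminated = list(eliminated)
  )
}

#' Filter probes by median absolute deviation
#'
#' Retains probes whose raw MAD (median absolute deviation about the probe
#' median, no consistency constant) is at least `cutoff`. On log2 expression
#' data this is the classic variability filter that discards flat,
#' uninformative probes before model selection.
#'
#' @param x An [expression_matrix()] with at least 2 samples.
#' @param cutoff Non-negative MAD threshold (log2 units); default 0.5.
#' @return A list with `matrix` (the retained probes) and `report`, a one-row
#'   tibble with the n_input / n_retained / n_eliminated bookkeeping and the
#'   eliminated probe ids as a list-column.
#' @export
mad_filter <- function(x, cutoff = 0.5) {
  assert_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  assert_that(ncol(x) >= 2L, "MAD filter needs at least 2 samples")
  assert_that(is.numeric(cutoff) && cutoff >= 0, "`cutoff` must be >= 0")
  vals <- unclass(x)
  mads <- apply(vals, 1L, function(v) stats::median(abs(v - stats::median(v))))
  keep <- mads >= cutoff
  report <- new_filter_report("mad", cutoff, rownames(vals)[keep], rownames(vals)[!keep])
  matrix <- if (any(keep)) x[which(keep), ] else NULL
  list(matrix = matrix, report = report)
}

#' Correlation-radius k-means redundancy filter
#'
#' Probes (row-standardized) are k-means clustered; a probe is retained only
#' if its Pearson correlation with its assigned cluster centroid is at least
#' `radius`. With a stringent radius this keeps probes in tight correlated
#' clusters (and effectively-singleton probes) while discarding probes that
#' fail to cluster tightly with anything.
#'
#' @param x An [expression_matrix()] with no zero-variance probes (run after
#'   [mad_filter()]).
#' @param radius Correlation radius in \[-1, 1\]; default 0.95.
#' @param k Number of clusters; default `max(2, round(n_probes / 2.5))`. On
#'   expression data with pervasive co-expression this gives every tight
#'   co-expression group its own cluster (retaining its members) while
#'   free-floating probes are absorbed into clusters they correlate poorly
#'   with and eliminated — exactly the probes most prone to spurious chance
#'   association downstream. The realized retention on block-structured
#'   data is ~80%.
#' @param seed Integer seed for the k-means restarts (10 restarts, best
#'   within-cluster sum of squares kept).
#' @return A list with `matrix` and a one-row `report` tibble, as in
#'   [mad_filter()].
#' @export
kmeans_redundancy_filter <- function(x, radius = 0.95, k = NULL, seed = 1L) {
  assert_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  assert_that(radius >= -1 && radius <= 1, "`radius` must be in [-1, 1]")
  vals <- unclass(x)
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    stopf("zero-variance probe(s): %s",
          paste(utils::head(rownames(vals)[sds == 0], 5L), collapse = ", "))
  }
  k <- k %||% max(2L, as.integer(round(nrow(vals) / 2.5)))
  assert_that(k >= 1L, "`k` must be >= 1")
  assert_that(k <= nrow(vals), "`k` cannot exceed the number of probes")
  z <- (vals - rowMeans(vals)) / sds
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = 10L, iter.max = 100L))
  centroid_cor <- vapply(seq_len(nrow(z)), function(i) {
    ctr <- km$centers[km$cluster[i], ]
    if (stats::sd(ctr) == 0) return(0)
    stats::cor(z[i, ], ctr)
  }, numeric(1))
  keep <- centroid_cor >= radius
  report <- new_filter_report("kmeans_redundancy", radius,
                              rownames(vals)[keep], rownames(vals)[!keep])
  matrix <- if (any(keep)) x[which(keep), ] else NULL
  list(matrix = matrix, report = report, centroid_cor = centroid_cor, k = k)
}

#' Unsupervised hierarchical sample grouping
#'
#' Clusters samples with average-linkage hierarchical clustering on
#' 1 - Pearson correlation distance (computed across probes) and cuts the
#' tree into `n_groups` groups — the standard exploratory 2-group split of an
#' expression heatmap.
#'
#' @param x An [expression_matrix()].
#' @param n_groups Number of groups to cut into (default 2).
#' @return A tibble with `sample_id` and `group` (factor `1..n_groups`);
#'   linkage and distance recorded as attributes.
#' @export
hierarchical_groups <- function(x, n_groups = 2L) {
  assert_that(inherits(x, "expr_matrix"), "`x` must be an expr_matrix")
  assert_that(n_groups >= 1L, "`n_groups` must be >= 1")
  assert_that(n_groups <= ncol(x), "more groups than samples")
  vals <- unclass(x)
  if (n_groups == 1L) {
    labels <- rep(1L, ncol(vals))
  } else {
    d <- stats::as.dist(1 - stats::cor(vals))
    hc <- stats::hclust(d, method = "average")
    labels <- unname(stats::cutree(hc, k = n_groups))
  }
  out <- tibble::tibble(sample_id = colnames(vals), group = factor(labels))
  attr(out, "linkage") <- "average"
  attr(out, "distance") <- "1 - Pearson correlation"
  out
}
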