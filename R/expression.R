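#' Construct a probe-by-sample expression matrix
#'
#' The package's container for log2 expression data: a numeric matrix with
#' probes as rows and samples as columns, carrying one batch label per sample.
#' All values must be finite and row/column names duplicate-free.
#'
#' @param values Numeric matrix, probes x samples, with rownames (probe ids)
#'   and colnames (sample ids).
#' @param batch Character vector of per-sample batch labels, length
#'   `ncol(values)`. Defaults to a single batch.
#' @return An `expr_matrix`: the matrix with a `batch` attribute.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' x <- expression_matrix(m, batch = c("a", "a", "b", "b"))
#' expr_batch(x)
#' @export
expression_matrix <- function(values, batch = NULL) {
  assert_that(is.matrix(values) && is.numeric(values), "`values` must be a numeric matrix")
  assert_that(nrow(values) > 0L && ncol(values) > 0L, "expression matrix must be non-empty")
  assert_that(all(is.finite(values)), "expression values must all be finite")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "expression matrix needs probe rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(values)), "duplicate probe ids")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample ids")
  batch <- batch %||% rep("batch1", ncol(values))
  assert_that(length(batch) == ncol(values), "one batch label per sample required")
  batch <- as.character(batch)
  names(batch) <- colnames(values)
  structure(values, batch = batch, class = c("expr_matrix", "matrix", "array"))
}

#' @describeIn expression_matrix Per-sample batch labels of an `expr_matrix`.
#' @param x An `expr_matrix`.
#' @export
expr_batch <- function(x) attr(x, "batch")

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  b <- attr(x, "batch")
  y <- unclass(x)
  attr(y, "batch") <- NULL
  y <- y[i, j, drop = FALSE]
  if (missing(j)) bj <- b else bj <- b[j]
  expression_matrix(y, batch = unname(bj))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples, %d batch(es)\n",
              nrow(x), ncol(x), length(unique(expr_batch(x)))))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  invisible(x)
}

#' Convert an expression matrix to a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `batch`, `value`.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  b <- expr_batch(x)
  tibble::tibble(
    probe_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    batch = rep(unname(b), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Read and write expression matrices
#'
#' `read_expression()` reads a tab-delimited matrix (first column probe ids,
#' header row of sample ids). Files whose first line is `#1.2` are parsed as
#' GCT: the two-line header is skipped and the `Description` column dropped.
#' `write_expression()` emits plain TSV at full double precision so a write /
#' read round trip reproduces the matrix exactly.
#'
#' @param path File path.
#' @param batch Optional per-sample batch labels (or a path to a two-column
#'   sample_id / batch TSV).
#' @return `read_expression()`: an [expression_matrix()].
#' @export
read_expression <- function(path, batch = NULL) {
  first <- readLines(path, n = 1L)
  gct <- identical(substr(first, 1L, 4L), "#1.2")
  df <- utils::read.delim(path, skip = if (gct) 2L else 0L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (gct && tolower(names(df)[1L]) == "description") df <- df[, -1L, drop = FALSE]
  values <- as.matrix(df)
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (is.character(batch) && length(batch) == 1L && file.exists(batch)) {
    bt <- utils::read.delim(batch, stringsAsFactors = FALSE)
    batch <- bt$batch[match(colnames(values), bt$sample_id)]
  }
  expression_matrix(values, batch = batch)
}

#' @rdname read_expression
#' @param x An `expr_matrix` to write.
#' @export
write_expression <- function(x, path) {
  vals <- unclass(x)
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("probe_id", colnames(vals)), collapse = "\t"), body), path)
  invisible(path)
}

#' Read a clinical outcome table
#'
#' Expects tab-delimited columns `sample_id`, `time_years`, `event` and
#' optionally `who_grade`, `mitotic_category`, `simpson_grade`, `sex`,
#' `location`. Categorical columns are coerced to factors with the reference
#' level first (WHO I, mitotic <=2, Simpson 1, female, non-skull-base).
#'
#' @param path File path.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_clinical(df)
}

#' Validate and type a clinical table
#'
#' @param df A data frame with at least `sample_id`, `time_years`, `event`.
#' @return A tibble with typed columns.
#' @export
as_clinical <- function(df) {
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(df))
  assert_that(length(miss) == 0L, "clinical table missing column(s): %s",
              paste(miss, collapse = ", "))
  out <- tibble::as_tibble(df)
  out$sample_id <- as.character(out$sample_id)
  assert_that(!anyDuplicated(out$sample_id), "duplicate sample ids in clinical table")
  out$time_years <- as.numeric(out$time_years)
  out$event <- as.integer(out$event)
  assert_that(all(is.finite(out$time_years)) && all(out$time_years > 0),
              "follow-up times must be finite and positive")
  assert_that(all(out$event %in% c(0L, 1L)), "event must be 0/1")
  lvls <- list(
    who_grade = c("I", "II", "III"),
    mitotic_category = c("<=2", "3-4", ">=5"),
    simpson_grade = c("1", "2", "3", "4"),
    sex = c("F", "M"),
    location = c("non-skull-base", "skull-base")
  )
  for (nm in names(lvls)) {
    if (nm %in% names(out)) {
      v <- as.character(out[[nm]])
      bad <- setdiff(stats::na.omit(unique(v)), lvls[[nm]])
      assert_that(length(bad) == 0L, "column %s has unknown level(s): %s",
                  nm, paste(bad, collapse = ", "))
      out[[nm]] <- factor(v, levels = lvls[[nm]])
    }
  }
  out
}

#' @rdname read_clinical
#' @param clinical A clinical tibble.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  df <- as.data.frame(clinical)
  df$time_years <- sprintf("%.17g", df$time_years)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
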