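# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derivation from one top-level seed. Offsets are
# fixed per stage name so every source of randomness is reproducible from the
# run seed alone.
stage_seed <- function(seed, stage) {
  offsets <- c(kmeans = 1L, ga = 2L, cv = 3L, simulate = 4L, simulate_validation = 5L)
  off <- offsets[[stage]]
  (as.integer(seed) + off * 10007L) %% .Machine$integer.max
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

# md5 of an arbitrary in-memory object via its canonical JSON serialization
hash_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Jaccard overlap between two identifier sets
#'
#' The ratio of intersection to union size, used to quantify how much of a
#' planted probe set a fitted signature recovered.
#'
#' @param a,b Character vectors of identifiers.
#' @return A number in \[0, 1\]; 1 when both sets are empty.
#' @export
jaccard_overlap <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
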