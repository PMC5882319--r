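# shared fixture builders; everything is generated in code

make_expr <- function(n_probes = 6, n_samples = 8, batch = NULL, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_probes * n_samples, mean = 8), n_probes, n_samples,
              dimnames = list(sprintf("p%02d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, batch = batch)
}

# a small, quick simulation configuration for unit tests
quick_sim <- function(...) {
  args <- list(n_train = 60L, n_validation = 40L, n_probes = 240L,
               n_signature = 6L, n_blocks = 18L, block_size = 10L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# reduced-budget run configuration for fast end-to-end tests
quick_run <- function(seed = 1L, ...) {
  run_config(ga = ga_config(pop_size = 16L, generations = 6L,
                            size_min = 4L, size_max = 8L, seed = seed),
             cv_folds = 10L, seed = seed, ...)
}

random_surv <- function(n, event_rate = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(time = rexp(n) + 0.01, event = rbinom(n, 1, event_rate))
}

# brute-force concordance oracle: explicit O(n^2) loop over ordered pairs
harrell_c_oracle <- function(score, time, event) {
  n <- length(time)
  conc <- 0; tied <- 0; comp <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / comp
}

# exhaustive single-split oracle for the partition cutoff
partition_oracle <- function(scores, d) {
  su <- sort(unique(scores))
  cand <- (su[-length(su)] + su[-1]) / 2
  sse <- function(v) if (!length(v)) 0 else sum((v - mean(v))^2)
  best <- Inf; best_c <- NA
  for (cc in cand) {
    val <- sse(d[scores <= cc]) + sse(d[scores > cc])
    if (val < best - 1e-12) { best <- val; best_c <- cc }
  }
  best_c
}
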