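# Radial-basis support-vector regression on a probe subset. Feature scaling
# is done here (not inside the svm call) so the fitted machine is a plain
# parametric object: support vectors, dual coefficients, intercept and the
# per-probe centring/scaling, all serializable as text and reproducible
# without the fitting library.

#' Fit epsilon-SVR with an RBF kernel on a probe subset
#'
#' Features are the per-probe standardized expression values of the selected
#' probes; the response is typically the (standardized) null-model deviance
#' residual, so the machine learns to predict recurrence risk from expression.
#'
#' @param x An [expression_matrix()] (probes x samples).
#' @param y Numeric response, one value per sample.
#' @param probes Probe ids to use as features (default: all rows of `x`).
#' @param cost Regularization parameter C (> 0).
#' @param epsilon Epsilon-insensitive band (> 0).
#' @param gamma RBF kernel bandwidth; default `0.1 / n_features` on the
#'   standardized feature scale — a deliberately smooth kernel, since the
#'   machine's in-sample concordance drives model selection and a sharper
#'   kernel interpolates any probe subset, leaving selection no signal.
#' @return An `svr_fit` holding the dual solution, the feature scaling, and
#'   the training predictions with their mean and SD (used by
#'   [score_samples()]).
#' @export
fit_svr <- function(x, y, probes = NULL, cost = 1, epsilon = 0.1, gamma = NULL) {
  assert_that(inherits(x, "expr_matrix") || is.matrix(x), "`x` must be a matrix")
  probes <- probes %||% rownames(x)
  assert_that(length(probes) >= 1L, "probe subset must be non-empty")
  miss <- setdiff(probes, rownames(x))
  assert_that(length(miss) == 0L, "probe(s) absent from matrix: %s",
              paste(utils::head(miss, 5L), collapse = ", "))
  assert_that(ncol(x) >= 3L, "need at least 3 samples")
  assert_that(length(y) == ncol(x), "response length must equal sample count")
  assert_that(all(is.finite(y)), "response must be finite")
  assert_that(cost > 0 && epsilon > 0, "SVR hyperparameters must be positive")
  feat <- t(unclass(x)[probes, , drop = FALSE])
  center <- colMeans(feat)
  scl <- apply(feat, 2L, stats::sd)
  scl[scl == 0] <- 1
  fz <- sweep(sweep(feat, 2L, center), 2L, scl, `/`)
  gamma <- gamma %||% (0.1 / ncol(fz))
  assert_that(gamma > 0, "SVR hyperparameters must be positive")
  fit <- e1071::svm(x = fz, y = y, type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = cost, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  obj <- structure(list(
    probes = probes,
    center = center, scale = scl,
    gamma = gamma, cost = cost, epsilon = epsilon,
    sv = if (is.null(fit$SV) || nrow(fit$SV) == 0L) {
      matrix(0, 0L, ncol(fz))
    } else {
      unname(as.matrix(fit$SV))
    },
    dual_coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho)
  ), class = "svr_fit")
  pred <- predict(obj, x)
  obj$train_pred <- unname(pred)
  obj$pred_mean <- mean(pred)
  obj$pred_sd <- stats::sd(pred)
  obj
}

# squared Euclidean cross-distances, rows of a vs rows of b
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  x <- newdata
  miss <- setdiff(object$probes, rownames(x))
  assert_that(length(miss) == 0L, "probe(s) absent from matrix: %s",
              paste(utils::head(miss, 5L), collapse = ", "))
  feat <- t(unclass(x)[object$probes, , drop = FALSE])
  fz <- sweep(sweep(feat, 2L, object$center), 2L, object$scale, `/`)
  if (length(object$dual_coefs) == 0L) {
    return(rep(-object$rho, nrow(fz)))
  }
  K <- exp(-object$gamma * pmax(cross_dist2(fz, object$sv), 0))
  drop(K %*% object$dual_coefs) - object$rho
}

#' Map raw SVR predictions to (0, 1) risk scores
#'
#' Predictions are standardized by the training-prediction mean and SD and
#' squashed through the logistic function, giving a strictly monotone
#' probability-like score: 0.5 at the training mean, higher score = higher
#' predicted deviance residual = higher recurrence risk.
#'
#' @param model An `svr_fit` (or a `signature_model`, whose regressor is used).
#' @param x An [expression_matrix()] containing all model probes.
#' @return Scores in (0, 1), one per sample of `x`.
#' @export
score_samples <- function(model, x) {
  if (inherits(model, "signature_model")) model <- model$svr
  assert_that(inherits(model, "svr_fit"), "`model` must be an svr_fit or signature_model")
  pred <- predict(model, x)
  s <- if (model$pred_sd > 1e-12) model$pred_sd else 1
  stats::plogis((pred - model$pred_mean) / s)
}
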