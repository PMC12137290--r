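#' Fit a stacked ensemble with a non-negative meta-combiner
#'
#' Each base learner produces out-of-fold predictions over a seeded k-fold
#' split; the meta-weights are the non-negative least-squares regression of
#' the response on those out-of-fold predictions plus an intercept column
#' (so the stacker never sees in-fold leakage). The base learners are then
#' refit on the full data.
#'
#' @param X Predictor tibble (see [apply_features()]).
#' @param y Numeric response.
#' @param specs List of [base_learner_spec()]s (default: forest, booster, ELM).
#' @param oof_folds Out-of-fold split count (default 5).
#' @param seed Seed for the split.
#'
#' @return An object of class `fohem_stack` with elements `base_models`,
#'   `meta_weights` (intercept first, all >= 0), `oof_predictions`, and
#'   `oof_mse` per learner.
#' @export
stack_fit <- function(X, y, specs = default_base_specs(seed), oof_folds = 5,
                      seed = 1) {
  if (oof_folds < 2) abort("stack_fit: oof_folds must be >= 2")
  n <- nrow(X)
  splits <- kfold_split(n, k = oof_folds, seed = seed)
  oof <- matrix(NA_real_, nrow = n, ncol = length(specs))
  for (sp in splits) {
    models <- purrr::map(specs, function(s) {
      train_one_learner(X[sp$train, , drop = FALSE], y[sp$train], s)
    })
    for (j in seq_along(models)) {
      oof[sp$test, j] <- predict(models[[j]], X[sp$test, , drop = FALSE])
    }
  }
  colnames(oof) <- vapply(specs, `[[`, character(1), "kind")
  A <- cbind(intercept = 1, oof)
  w <- pracma::lsqnonneg(A, y)$x
  names(w) <- colnames(A)
  base_models <- purrr::map(specs, function(s) train_one_learner(X, y, s))
  oof_mse <- colMeans((oof - y)^2)
  structure(list(base_models = base_models, meta_weights = w,
                 oof_folds = as.integer(oof_folds), seed = as.integer(seed),
                 oof_predictions = oof, oof_mse = oof_mse,
                 oof_stack_mse = mean((as.numeric(A %*% w) - y)^2)),
            class = "fohem_stack")
}

#' @export
predict.fohem_stack <- function(object, newdata, ...) {
  preds <- vapply(object$base_models, predict, numeric(nrow(newdata)),
                  newdata = newdata)
  if (!is.matrix(preds)) preds <- matrix(preds, nrow = nrow(newdata))
  as.numeric(cbind(1, preds) %*% object$meta_weights)
}

#' @export
print.fohem_stack <- function(x, ...) {
  cat("Stacked ensemble (", length(x$base_models), " base learners, ",
      x$oof_folds, "-fold out-of-fold meta-fit)\n", sep = "")
  cat("meta-weights:\n")
  print(round(x$meta_weights, 4))
  invisible(x)
}
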