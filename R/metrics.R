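#' Regression metrics for yield predictions
#'
#' MSE, MAE, RMSE (`sqrt(MSE)`), and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the mean of
#' `y_true`. With fewer than 2 observations or a zero-variance truth,
#' `r2` is reported as `NA` with a warning.
#'
#' @param y_true,y_pred Equal-length finite numeric vectors.
#' @param group Optional group label attached to the report row.
#' @return A one-row tibble: `group`, `n`, `mse`, `mae`, `rmse`, `r2`.
#' @export
#' @examples
#' regression_metrics(c(1, 3), c(1, 2))
regression_metrics <- function(y_true, y_pred, group = NA_character_) {
  if (length(y_true) != length(y_pred)) {
    abort("regression_metrics: y_true and y_pred must have equal length")
  }
  if (!length(y_true)) abort("regression_metrics: empty input")
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred))) {
    abort("regression_metrics: inputs must be finite")
  }
  res <- y_true - y_pred
  mse <- mean(res^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (length(y_true) < 2 || ss_tot == 0) {
    warn("regression_metrics: r2 undefined (zero-variance or singleton y_true)")
    NA_real_
  } else {
    1 - sum(res^2) / ss_tot
  }
  tibble::tibble(group = group, n = length(y_true), mse = mse,
                 mae = mean(abs(res)), rmse = sqrt(mse), r2 = r2)
}

#' Cross-validate a fitting procedure
#'
#' Splits the dataset with [kfold_split()], trains `fit_fn` on each training
#' fold with a fold-specific derived seed, scores predictions on the held-out
#' fold, and summarises fold-wise metrics. `fit_fn(train_data, seed)` must
#' return an object whose `predict(object, newdata)` yields a numeric vector.
#'
#' @param data Dataset tibble with a `yield` column.
#' @param fit_fn Function `(train_data, seed) -> model`.
#' @param k Number of folds (default 5).
#' @param seed Split seed; fold `i` trains with seed `seed + i`.
#' @return An object of class `fohem_cv`: list with `per_fold` (tibble of
#'   fold metrics) and `mean_r2`.
#' @export
#' @examples
#' d <- simulate_yield_data(generator_config(n_records = 60, seed = 1))
#' cv <- cross_validate(d, function(tr, seed) {
#'   elm_train(tr[, c("total_biomass", "LAI")], tr$yield, hidden = 30, seed = seed)
#' }, k = 3, seed = 1)
#' cv$mean_r2
cross_validate <- function(data, fit_fn, k = 5, seed = 1) {
  schema <- data_schema(data)
  splits <- kfold_split(nrow(data), k = k, seed = seed)
  per_fold <- purrr::map_dfr(seq_along(splits), function(i) {
    sp <- splits[[i]]
    tryCatch({
      train <- data[sp$train, ]
      test <- data[sp$test, ]
      attr(train, "schema") <- schema
      attr(test, "schema") <- schema
      model <- fit_fn(train, stage_seed(seed, i))
      pred <- predict(model, test)
      if (is.data.frame(pred)) pred <- pred$yield_pred
      dplyr::mutate(regression_metrics(test$yield, pred,
                                       group = sprintf("fold%d", i)),
                    fold = i, .before = 1)
    }, error = function(e) {
      abort(sprintf("cross_validate: fold %d failed: %s", i, conditionMessage(e)))
    })
  })
  structure(list(per_fold = per_fold, mean_r2 = mean(per_fold$r2), k = k,
                 seed = seed),
            class = "fohem_cv")
}

#' @export
print.fohem_cv <- function(x, ...) {
  cat(x$k, "-fold cross-validation\n", sep = "")
  print(as.data.frame(x$per_fold[, c("fold", "mse", "mae", "rmse", "r2")]))
  cat(sprintf("Mean R^2: %.4f\n", x$mean_r2))
  invisible(x)
}

#' Per-group performance report
#'
#' One metrics row per observed treatment-by-location group, in fixed order
#' (treatments SS, SM, 2M2S, 2M3S; locations alphabetical), followed by an
#' `overall` row. Singleton groups get metrics without `r2` (with a warning
#' from [regression_metrics()]).
#'
#' @param data Dataset tibble with `treatment`, `location`, `yield`.
#' @param y_pred Numeric predictions aligned with `data` rows.
#' @return A tibble of metric rows.
#' @export
group_report <- function(data, y_pred) {
  if (nrow(data) != length(y_pred)) {
    abort("group_report: y_pred must align with data rows")
  }
  keys <- tidyr::expand_grid(treatment = TREATMENTS, location = sort(LOCATIONS))
  obs <- group_key(data$treatment, data$location)
  rows <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    key <- group_key(keys$treatment[i], keys$location[i])
    idx <- which(obs == key)
    if (!length(idx)) return(NULL)
    regression_metrics(data$yield[idx], y_pred[idx], group = key)
  })
  dplyr::bind_rows(rows, regression_metrics(data$yield, y_pred, group = "overall"))
}
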