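#' Tidy the blend weights of a fitted hybrid model
#'
#' @param x A `fohem_model`.
#' @param ... Unused.
#' @return A tibble with one row per weight group: `group`, `w_fis`, `w_ens`.
#' @export
tidy.fohem_model <- function(x, ...) {
  tibble::as_tibble(x$weights)
}

#' One-row summary of a fitted hybrid model
#'
#' Reports validation-split performance of the blend and of each component,
#' plus feature counts.
#'
#' @param x A `fohem_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.fohem_model <- function(x, ...) {
  v <- x$validation
  w <- vapply(v$groups, weight_for_group, numeric(1), weights = x$weights)
  blend <- w * v$y_fis + (1 - w) * v$y_ens
  m_blend <- regression_metrics(v$y_true, blend)
  m_fis <- regression_metrics(v$y_true, v$y_fis)
  m_ens <- regression_metrics(v$y_true, v$y_ens)
  tibble::tibble(
    n_validation = length(v$y_true),
    n_features = sum(x$features$mask),
    n_engineered = nrow(x$features$engineered),
    weight_mode = attr(x$weights, "mode"),
    r2_blend = m_blend$r2, r2_fis = m_fis$r2, r2_ensemble = m_ens$r2,
    mse_blend = m_blend$mse, mse_fis = m_fis$mse, mse_ensemble = m_ens$mse
  )
}

#' Tidy a GA run
#'
#' @param x A `fohem_ga_result`.
#' @param ... Unused.
#' @return Tibble with `generation` and `best_fitness`.
#' @export
tidy.fohem_ga_result <- function(x, ...) ga_history(x)

#' @export
glance.fohem_ga_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 generations_run = x$generations_run,
                 n_genes = length(x$best$genes))
}

#' Tidy a cross-validation report
#'
#' @param x A `fohem_cv`.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @export
tidy.fohem_cv <- function(x, ...) x$per_fold

#' @export
glance.fohem_cv <- function(x, ...) {
  tibble::tibble(k = x$k, mean_r2 = x$mean_r2,
                 mean_rmse = mean(x$per_fold$rmse))
}

#' @export
tidy.fohem_featopt <- function(x, ...) {
  tibble::tibble(feature = names(x$mask), included = unname(x$mask))
}

#' @export
glance.fohem_featopt <- function(x, ...) {
  tibble::tibble(n_selected = sum(x$mask), n_engineered = nrow(x$engineered),
                 cv_score = x$cv_score)
}

#' @export
generics::tidy

#' @export
generics::glance
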