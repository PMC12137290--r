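#' Permutation feature importance
#'
#' Importance of feature `j` is the mean (over seeded repeats) increase in
#' MSE when column `j` is randomly permuted:
#' `mean_r[ MSE(y, f(X with j permuted)) ] - MSE(y, f(X))`. Features the
#' model ignores score ~0 within Monte-Carlo noise.
#'
#' @param model_fn Prediction function: data frame -> numeric vector.
#' @param X Predictor data frame.
#' @param y Observed response aligned with `X`.
#' @param repeats Number of permutation repeats (>= 2, default 10).
#' @param seed Seed for the permutations.
#' @return A tibble of class `fohem_importance` with columns `feature`,
#'   `importance`, `sd`, sorted by decreasing importance; attributes
#'   `method` and `baseline_mse`.
#' @export
permutation_importance <- function(model_fn, X, y, repeats = 10, seed = 1) {
  if (repeats < 2) abort("permutation_importance: repeats must be >= 2")
  if (nrow(X) != length(y)) abort("permutation_importance: X rows must match length(y)")
  base_mse <- mean((y - model_fn(X))^2)
  res <- with_seed(seed, {
    purrr::map_dfr(names(X), function(nm) {
      deltas <- vapply(seq_len(repeats), function(r) {
        Xp <- X
        Xp[[nm]] <- Xp[[nm]][sample.int(nrow(X))]
        mean((y - model_fn(Xp))^2) - base_mse
      }, numeric(1))
      tibble::tibble(feature = nm, importance = mean(deltas),
                     sd = stats::sd(deltas))
    })
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$importance))
  structure(res, class = c("fohem_importance", class(res)),
            method = "permutation", baseline_mse = base_mse, seed = seed)
}

#' Monte-Carlo Shapley feature contributions
#'
#' Sampling estimator of Shapley values for one instance: for each of
#' `n_samples` draws, a random feature ordering and a random background row
#' are taken, and each feature's marginal effect is the change in `f` when
#' that feature switches from the background value to the instance value,
#' given the features before it in the ordering already switched. Satisfies
#' the efficiency identity in expectation:
#' `sum(phi) = f(x) - mean(f(background))`.
#'
#' @param model_fn Prediction function: data frame -> numeric vector.
#' @param X_background Background data frame (the reference population).
#' @param x_instance Single-row data frame to explain.
#' @param n_samples Monte-Carlo samples (>= 50, default 200).
#' @param seed Seed.
#' @return A tibble of class `fohem_shapley` with columns `feature`, `phi`,
#'   `se`; attributes `fx` (model at the instance) and `baseline`
#'   (mean model output over the background).
#' @export
shapley_sampling <- function(model_fn, X_background, x_instance,
                             n_samples = 200, seed = 1) {
  if (n_samples < 50) abort("shapley_sampling: n_samples must be >= 50")
  if (!nrow(X_background)) abort("shapley_sampling: background must be non-empty")
  x_instance <- x_instance[1, , drop = FALSE]
  if (!identical(names(X_background), names(x_instance))) {
    abort("shapley_sampling: background and instance columns must match")
  }
  p <- ncol(x_instance)
  nb <- nrow(X_background)
  contrib <- matrix(0, nrow = n_samples, ncol = p,
                    dimnames = list(NULL, names(x_instance)))
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      ord <- sample.int(p)
      bg <- X_background[sample.int(nb, 1L), , drop = FALSE]
      # walk the ordering: p + 1 hybrid rows evaluated in one model call
      rows <- bg[rep(1L, p + 1L), , drop = FALSE]
      for (step in seq_len(p)) {
        switched <- ord[seq_len(step)]
        rows[step + 1L, switched] <- x_instance[1L, switched]
      }
      f <- model_fn(rows)
      contrib[s, ord] <- diff(f)
    }
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_samples)
  res <- tibble::tibble(feature = names(phi), phi = unname(phi), se = unname(se))
  structure(res, class = c("fohem_shapley", class(res)),
            fx = as.numeric(model_fn(x_instance)),
            baseline = mean(model_fn(X_background)), seed = seed)
}

#' Local sparse linear surrogate explanation
#'
#' Explains one prediction by fitting a proximity-weighted sparse linear
#' model to the black box's outputs on Gaussian perturbations around the
#' instance. Perturbations use per-feature standard deviations from
#' `X_stats`; proximity weights are `exp(-d^2 / kernel_width^2)` with `d`
#' the standardized Euclidean distance. The surrogate is a weighted ridge
#' fit restricted to the `sparsity_k` features with the largest weighted
#' correlation with the model output; zero-spread features are held fixed.
#'
#' @param model_fn Prediction function: data frame -> numeric vector.
#' @param x_instance Single-row data frame of numeric features.
#' @param X_stats Data frame whose columns give the perturbation scale
#'   (their standard deviations are used), or a tibble with `feature`/`sd`.
#' @param n_perturb Number of perturbations (>= 100, default 500).
#' @param kernel_width Proximity kernel width; default `0.75 * sqrt(p)`.
#' @param sparsity_k Maximum number of nonzero coefficients (default 8).
#' @param seed Seed.
#' @return An object of class `fohem_local_explanation`: tibble with
#'   `feature`, `coefficient` (signed; 0 for unselected features), plus
#'   attributes `intercept` and `fidelity_r2` (weighted R^2 of the
#'   surrogate on the perturbation sample).
#' @export
local_surrogate <- function(model_fn, x_instance, X_stats, n_perturb = 500,
                            kernel_width = NULL, sparsity_k = 8, seed = 1) {
  if (n_perturb < 100) abort("local_surrogate: n_perturb must be >= 100")
  x_instance <- x_instance[1, , drop = FALSE]
  p <- ncol(x_instance)
  kernel_width <- kernel_width %||% (0.75 * sqrt(p))
  if (is.data.frame(X_stats) && all(c("feature", "sd") %in% names(X_stats))) {
    sds <- stats::setNames(X_stats$sd, X_stats$feature)[names(x_instance)]
  } else {
    sds <- vapply(as.data.frame(X_stats)[names(x_instance)], stats::sd, numeric(1))
  }
  fixed <- !is.finite(sds) | sds == 0
  sds[fixed] <- 0
  x0 <- as.numeric(x_instance[1, ])
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_perturb * p), ncol = p)
    Z <- sweep(Z, 2, sds, "*")
    Xp <- sweep(Z, 2, x0, "+")
    colnames(Xp) <- names(x_instance)
    Xp_df <- tibble::as_tibble(as.data.frame(Xp))
    f <- model_fn(Xp_df)
    dist2 <- rowSums(sweep(Z, 2, pmax(sds, 1e-12), "/")^2 *
                       rep(!fixed, each = n_perturb))
    w <- exp(-dist2 / kernel_width^2)
    # screen: weighted correlation of each perturbable feature with f
    wc <- vapply(seq_len(p), function(j) {
      if (fixed[j]) return(0)
      abs(stats::cov.wt(cbind(Xp[, j], f), wt = w, cor = TRUE)$cor[1, 2])
    }, numeric(1))
    wc[!is.finite(wc)] <- 0
    k <- min(sparsity_k, sum(!fixed))
    keep <- order(-wc, seq_len(p))[seq_len(k)]
    A <- Xp[, keep, drop = FALSE]
    # weighted ridge with a tiny stabilising penalty
    sw <- sqrt(w)
    Aw <- cbind(1, A) * sw
    fw <- f * sw
    lam <- 1e-8
    coef <- solve(crossprod(Aw) + diag(c(0, rep(lam, k))), crossprod(Aw, fw))
    fitted <- as.numeric(cbind(1, A) %*% coef)
    fbar <- sum(w * f) / sum(w)
    fidelity <- 1 - sum(w * (f - fitted)^2) / sum(w * (f - fbar)^2)
    coefs <- numeric(p)
    coefs[keep] <- coef[-1]
    res <- tibble::tibble(feature = names(x_instance), coefficient = coefs)
    structure(res, class = c("fohem_local_explanation", class(res)),
              intercept = coef[1], fidelity_r2 = fidelity, seed = seed,
              weights = w)
  })
}
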