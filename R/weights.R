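#' Optimize the FIS / ensemble blend weights
#'
#' Finds, for each treatment-by-location group (or globally), the convex
#' blend weight `w_fis` minimizing the validation MSE of
#' `w_fis * y_fis + (1 - w_fis) * y_ens`. A real-chromosome GA (one gene per
#' group, bounds `[0, 1]`) does the search; because the objective is
#' separable and quadratic in each gene, every gene is then polished by a
#' bounded 1-D line search and checked against the endpoints, so the
#' returned blend never does worse than either component on the validation
#' data. Weights always satisfy `w_fis + w_ens = 1`, both non-negative.
#'
#' A `global` row fitted on all records is always included as the fallback
#' for unseen groups; groups with fewer than 2 validation records are merged
#' into it with a warning.
#'
#' @param y_true,y_fis,y_ens Equal-length numeric vectors of observed yields
#'   and the two components' predictions on a validation split.
#' @param groups Factor/character of group keys (`"treatment|location"`),
#'   or NULL for global-only.
#' @param config A [ga_config()] for the weight search.
#' @param mode `"global"`, `"per_group"`, or `"auto"` (per-group when every
#'   group has at least `min_group_n` records).
#' @param min_group_n Per-group threshold used by `"auto"` (default 10).
#'
#' @return An object of class `fohem_weights`: a tibble with columns
#'   `group`, `w_fis`, `w_ens` (always containing a `"global"` row), plus
#'   attributes `mode` and `ga_history`.
#' @export
#' @examples
#' set.seed(1)
#' y <- rnorm(80, 8); f <- y + rnorm(80, 0, 0.2); e <- y + rnorm(80, 0, 0.6)
#' optimize_weights(y, f, e, config = ga_config(max_generations = 20, seed = 1))
optimize_weights <- function(y_true, y_fis, y_ens, groups = NULL,
                             config = ga_config(), mode = c("auto", "global",
                                                            "per_group"),
                             min_group_n = 10) {
  mode <- match.arg(mode)
  n <- length(y_true)
  if (length(y_fis) != n || length(y_ens) != n) {
    abort("optimize_weights: y_true, y_fis, y_ens must have equal length")
  }
  if (is.null(groups)) mode <- "global"
  if (mode == "auto") {
    counts <- table(as.character(groups))
    mode <- if (length(counts) > 1 && all(counts >= min_group_n)) "per_group" else "global"
  }

  blend_mse <- function(w, idx) {
    r <- w * y_fis[idx] + (1 - w) * y_ens[idx] - y_true[idx]
    mean(r^2)
  }
  # GA search followed by a bounded quadratic polish per gene; endpoints
  # kept as candidates so the blend dominates both components.
  solve_groups <- function(index_sets) {
    k <- length(index_sets)
    fitness <- function(ch) {
      -sum(vapply(seq_len(k), function(j) {
        idx <- index_sets[[j]]
        length(idx) * blend_mse(ch$genes[j], idx)
      }, numeric(1)))
    }
    bounds <- matrix(rep(c(0, 1), each = k), ncol = 2)
    res <- run_ga(config,
                  init = function() real_chromosome(stats::runif(k), bounds),
                  fitness = fitness)
    w <- res$best$genes
    polished <- vapply(seq_len(k), function(j) {
      idx <- index_sets[[j]]
      opt <- stats::optimize(function(v) blend_mse(v, idx),
                             interval = c(0, 1), tol = 1e-8)$minimum
      cand <- c(w[j], opt, 0, 1)
      cand[which.min(vapply(cand, blend_mse, numeric(1), idx = idx))]
    }, numeric(1))
    list(w = polished, history = res$history)
  }

  global_fit <- solve_groups(list(seq_len(n)))
  out <- tibble::tibble(group = "global", w_fis = global_fit$w)
  history <- list(global = global_fit$history)

  if (mode == "per_group") {
    keys <- as.character(groups)
    counts <- table(keys)
    small <- names(counts)[counts < 2]
    if (length(small)) {
      warn(sprintf("optimize_weights: group(s) %s have < 2 validation records; merged into global",
                   paste(small, collapse = ", ")))
    }
    big <- setdiff(names(counts), small)
    if (length(big)) {
      index_sets <- purrr::map(big, function(g) which(keys == g))
      fit <- solve_groups(index_sets)
      out <- dplyr::bind_rows(out, tibble::tibble(group = big, w_fis = fit$w))
      history$per_group <- fit$history
    }
  }
  out$w_ens <- 1 - out$w_fis
  structure(out, class = c("fohem_weights", class(out)),
            mode = mode, ga_history = history)
}

weight_for_group <- function(weights, key) {
  i <- match(key, weights$group)
  if (is.na(i)) i <- match("global", weights$group)
  weights$w_fis[i]
}
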