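#' Candidate pool of engineered features
#'
#' Ranks the base numeric features by absolute Pearson correlation with
#' yield, takes the `top_k`, and proposes their squares, `log1p` transforms
#' (only for features whose range is non-negative), and all pairwise
#' products. With every `log1p` admissible the pool has
#' `2 * top_k + choose(top_k, 2)` candidates; deterministic given the data.
#'
#' @param data Dataset tibble with a `yield` column.
#' @param top_k How many top-correlated base features to expand (>= 1).
#' @param schema Feature schema (defaults to the one attached to `data`).
#'
#' @return A tibble with columns `kind` (`square`, `log1p`, `product`),
#'   `op1`, `op2` (NA except for products), and `name`.
#' @export
#' @examples
#' d <- simulate_yield_data(generator_config(n_records = 60, seed = 1))
#' candidate_pool(d, top_k = 3)
candidate_pool <- function(data, top_k = 8, schema = NULL) {
  if (top_k < 1) abort("candidate_pool: top_k must be >= 1")
  schema <- schema %||% data_schema(data)
  base <- schema$name
  if (top_k > length(base)) {
    abort(sprintf("candidate_pool: top_k (%d) exceeds number of base features (%d)",
                  top_k, length(base)))
  }
  cors <- vapply(base, function(nm) {
    s <- stats::sd(data[[nm]])
    if (s == 0) 0 else abs(stats::cor(data[[nm]], data$yield))
  }, numeric(1))
  top <- base[order(-cors, seq_along(base))][seq_len(top_k)]
  nonneg <- schema$name[schema$low >= 0]
  sq <- tibble::tibble(kind = "square", op1 = top, op2 = NA_character_,
                       name = paste0(top, "^2"))
  lg <- tibble::tibble(kind = "log1p", op1 = intersect(top, nonneg),
                       op2 = NA_character_)
  lg$name <- paste0("log1p_", lg$op1)
  pr <- if (top_k >= 2) {
    cmb <- utils::combn(top, 2)
    tibble::tibble(kind = "product", op1 = cmb[1, ], op2 = cmb[2, ],
                   name = paste0(cmb[1, ], "_x_", cmb[2, ]))
  } else {
    tibble::tibble(kind = character(), op1 = character(), op2 = character(),
                   name = character())
  }
  dplyr::bind_rows(sq, lg, pr)
}

engineered_column <- function(data, kind, op1, op2) {
  switch(kind,
         square = data[[op1]]^2,
         log1p = log1p(data[[op1]]),
         product = data[[op1]] * data[[op2]],
         abort(sprintf("unknown engineered-feature kind '%s'", kind)))
}

#' Materialize the design under a feature mask and engineered features
#'
#' Builds the model frame used by every learner: base features kept by
#' `mask` (in schema order), then engineered columns (in pool order), then
#' `treatment` and `location` as factors.
#'
#' @param data Dataset tibble.
#' @param mask Named logical vector over the base features (TRUE = keep),
#'   or NULL to keep all.
#' @param engineered Tibble of engineered features as from [candidate_pool()]
#'   (possibly zero rows).
#' @return A tibble of predictor columns.
#' @export
apply_features <- function(data, mask = NULL, engineered = NULL) {
  schema <- data_schema(data)
  base <- schema$name
  if (is.null(mask)) mask <- stats::setNames(rep(TRUE, length(base)), base)
  keep <- base[mask[base]]
  out <- data[, keep, drop = FALSE]
  if (!is.null(engineered) && nrow(engineered)) {
    ops <- unique(stats::na.omit(c(engineered$op1, engineered$op2)))
    missing_ops <- setdiff(ops, names(data))
    if (length(missing_ops)) {
      abort(sprintf("apply_features: missing operand column '%s'", missing_ops[1]))
    }
    for (i in seq_len(nrow(engineered))) {
      out[[engineered$name[i]]] <-
        engineered_column(data, engineered$kind[i], engineered$op1[i],
                          engineered$op2[i])
    }
  }
  out$treatment <- factor(as.character(data$treatment), levels = TREATMENTS)
  out$location <- factor(as.character(data$location), levels = LOCATIONS)
  tibble::as_tibble(out)
}

#' Default cross-validated evaluator for feature fitness
#'
#' Returns a memoising closure `f(X)` scoring a candidate predictor frame by
#' its mean out-of-fold R-squared over an internal k-fold split. Two model
#' backends serve different purposes: `"forest"` (a small random forest)
#' detects any form of dependence and drives feature *selection*;
#' `"linear"` (ridge-stabilized least squares) is sensitive to the explicit
#' functional form of a column and drives feature *engineering*, where a
#' tree model scores a transformation and any monotone surrogate of it
#' identically. All seeds fixed, so the evaluator is deterministic; results
#' are cached by column signature.
#'
#' @param data Dataset tibble (provides `yield`).
#' @param folds Internal folds (default 3).
#' @param num_trees Forest size (default 50; kept small because the GA calls
#'   this thousands of times).
#' @param seed Seed for the fold split and forests.
#' @param model `"forest"` (default) or `"linear"`.
#' @return A function taking a predictor tibble and returning a scalar score.
#' @export
cv_evaluator <- function(data, folds = 3, num_trees = 50, seed = 1,
                         model = c("forest", "linear")) {
  model <- match.arg(model)
  y <- data$yield
  splits <- kfold_split(nrow(data), k = folds, seed = seed)
  cache <- new.env(parent = emptyenv())
  fold_r2 <- function(X, sp) {
    yt <- y[sp$test]
    pred <- if (model == "forest") {
      Xdf <- as.data.frame(X)
      fit <- ranger::ranger(x = Xdf[sp$train, , drop = FALSE], y = y[sp$train],
                            num.trees = num_trees, seed = seed,
                            num.threads = 1)
      stats::predict(fit, data = Xdf[sp$test, , drop = FALSE])$predictions
    } else {
      enc <- encode_design(X[sp$train, , drop = FALSE])
      mu <- colMeans(enc$mat)
      sds <- apply(enc$mat, 2, stats::sd)
      sds[sds == 0] <- 1
      A <- cbind(1, sweep(sweep(enc$mat, 2, mu, "-"), 2, sds, "/"))
      beta <- solve(crossprod(A) + 1e-6 * diag(ncol(A)),
                    crossprod(A, y[sp$train]))
      Mt <- encode_design(X[sp$test, , drop = FALSE], enc$template)$mat
      At <- cbind(1, sweep(sweep(Mt, 2, mu, "-"), 2, sds, "/"))
      as.numeric(At %*% beta)
    }
    1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
  }
  function(X) {
    key <- paste(names(X), collapse = "\r")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- mean(vapply(splits, function(sp) fold_r2(X, sp), numeric(1)))
    assign(key, val, envir = cache)
    val
  }
}

#' GA feature selection over a binary inclusion mask
#'
#' Evolves a binary mask over the base features, scoring each candidate by
#' `evaluator(design) - lambda * n_included / n_total` — cross-validated
#' accuracy under a parsimony penalty. All-zero masks are repaired by
#' activating one uniformly random gene before evaluation.
#'
#' @param data Dataset tibble.
#' @param config A [ga_config()].
#' @param evaluator Scoring closure as from [cv_evaluator()]; built with
#'   seed `config$seed` when NULL.
#' @param lambda Parsimony weight (default 0.05).
#'
#' @return A list of class `fohem_featopt`: `mask` (named logical),
#'   `engineered` (empty tibble), `fitness_history`, `cv_score` (penalty-free
#'   re-evaluation of the final mask), and the GA result.
#' @export
ga_select_features <- function(data, config = ga_config(), evaluator = NULL,
                               lambda = 0.05) {
  schema <- data_schema(data)
  base <- schema$name
  p <- length(base)
  evaluator <- evaluator %||% cv_evaluator(data, seed = config$seed)
  empty_pool <- candidate_pool(data, top_k = 1, schema = schema)[0, ]
  fitness <- function(ch) {
    genes <- ch$genes
    if (!any(genes == 1L)) genes[sample.int(p, 1L)] <- 1L
    mask <- stats::setNames(genes == 1L, base)
    evaluator(apply_features(data, mask, NULL)) - lambda * sum(genes) / p
  }
  res <- run_ga(config,
                init = function() binary_chromosome(stats::rbinom(p, 1, 0.5)),
                fitness = fitness)
  genes <- res$best$genes
  if (!any(genes == 1L)) genes[1L] <- 1L
  mask <- stats::setNames(genes == 1L, base)
  cv_score <- evaluator(apply_features(data, mask, NULL))
  structure(list(mask = mask, engineered = empty_pool,
                 fitness_history = res$history, cv_score = cv_score,
                 ga = res, schema = schema),
            class = "fohem_featopt")
}

#' GA feature engineering over a transformation pool
#'
#' Starting from a selected base mask, evolves a binary inclusion vector
#' over the [candidate_pool()] of squares, log transforms, and interaction
#' products. A transformation set is retained only if its penalty-free
#' cross-validated score is at least that of the base mask alone; otherwise
#' the engineered list is empty.
#'
#' @inheritParams ga_select_features
#' @param base_mask Named logical mask from [ga_select_features()].
#' @param top_k Pool width passed to [candidate_pool()]; capped at the
#'   number of selected base features.
#' @return A `fohem_featopt` with both `mask` and `engineered` filled in.
#' @export
ga_engineer_features <- function(data, base_mask, config = ga_config(),
                                 evaluator = NULL, lambda = 0.05, top_k = 8) {
  schema <- data_schema(data)
  evaluator <- evaluator %||% cv_evaluator(data, seed = config$seed,
                                           model = "linear")
  selected <- names(base_mask)[base_mask]
  sub_schema <- schema[schema$name %in% selected, , drop = FALSE]
  top_k <- min(top_k, nrow(sub_schema))
  pool <- candidate_pool(data, top_k = top_k, schema = sub_schema)
  m <- nrow(pool)
  base_score <- evaluator(apply_features(data, base_mask, NULL))
  fitness <- function(ch) {
    sel <- pool[ch$genes == 1L, , drop = FALSE]
    evaluator(apply_features(data, base_mask, sel)) - lambda * sum(ch$genes) / m
  }
  res <- run_ga(config,
                init = function() binary_chromosome(stats::rbinom(m, 1, 0.2)),
                fitness = fitness)
  engineered <- pool[res$best$genes == 1L, , drop = FALSE]
  cv_score <- evaluator(apply_features(data, base_mask, engineered))
  if (cv_score < base_score) {
    engineered <- pool[0, ]
    cv_score <- base_score
  }
  structure(list(mask = base_mask, engineered = engineered,
                 fitness_history = res$history, cv_score = cv_score,
                 ga = res, schema = schema, pool = pool),
            class = "fohem_featopt")
}
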