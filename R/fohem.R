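#' Configuration for the full hybrid fit
#'
#' One global `seed` fans out to per-stage seeds by fixed offsets, so a
#' single integer reproduces an entire fit. The GA protocol for the blend
#' weights uses the standard settings (population 100, rates 0.8 / 0.02,
#' 50 generations); the feature-selection and engineering GAs run a
#' smaller population and budget because each fitness call refits a
#' cross-validated forest.
#'
#' @param seed Global integer seed.
#' @param ga_features [ga_config()] for feature selection/engineering.
#' @param ga_weights [ga_config()] for blend-weight optimization.
#' @param n_fis_inputs How many top selected features feed the fuzzy system
#'   (2-4, default 3).
#' @param lambda Parsimony penalty for the feature GAs.
#' @param evaluator_trees,evaluator_folds Size of the forest evaluator.
#' @param oof_folds Out-of-fold folds for the stacker.
#' @param weight_mode `"auto"`, `"global"`, or `"per_group"` (see
#'   [optimize_weights()]).
#' @param val_fraction Fraction held out (stratified by group) to fit the
#'   blend weights.
#' @return A list of class `fohem_config`.
#' @export
fohem_config <- function(seed = 42,
                         ga_features = ga_config(population_size = 30L,
                                                 max_generations = 15L,
                                                 patience = 5L,
                                                 seed = stage_seed(seed, 1)),
                         ga_weights = ga_config(seed = stage_seed(seed, 2)),
                         n_fis_inputs = 3,
                         lambda = 0.05,
                         evaluator_trees = 50,
                         evaluator_folds = 3,
                         oof_folds = 5,
                         weight_mode = "auto",
                         val_fraction = 0.2) {
  if (n_fis_inputs < 2 || n_fis_inputs > 4) {
    abort("fohem_config: n_fis_inputs must be between 2 and 4")
  }
  structure(list(seed = as.integer(seed), ga_features = ga_features,
                 ga_weights = ga_weights, n_fis_inputs = as.integer(n_fis_inputs),
                 lambda = lambda, evaluator_trees = evaluator_trees,
                 evaluator_folds = evaluator_folds, oof_folds = oof_folds,
                 weight_mode = weight_mode, val_fraction = val_fraction),
            class = "fohem_config")
}

# stratified fit/validation split by treatment x location
stratified_split <- function(data, val_fraction, seed) {
  keys <- group_key(data$treatment, data$location)
  with_seed(seed, {
    val <- integer(0)
    for (g in unique(keys)) {
      idx <- which(keys == g)
      n_val <- max(1L, round(length(idx) * val_fraction))
      val <- c(val, sample(idx, n_val))
    }
    list(fit = setdiff(seq_len(nrow(data)), val), val = sort(val))
  })
}

#' Fit the fuzzy-optimized hybrid ensemble
#'
#' Runs the full pipeline on a yield dataset:
#' 1. split into fit/validation parts (stratified by treatment x location);
#' 2. GA feature selection, then GA feature engineering, on the fit part;
#' 3. build the fuzzy rule base on the top selected features;
#' 4. fit the stacked ensemble (forest + booster + ELM) on the engineered
#'    design of the fit part;
#' 5. optimize the FIS/ensemble blend weights on the validation part;
#' 6. refit the ensemble on all data.
#' Every stage seed derives from `config$seed`, so the fit is reproducible
#' from one integer.
#'
#' @param data Dataset tibble (>= 40 records) with schema attached, as from
#'   [simulate_yield_data()] or [read_yield_csv()].
#' @param config A [fohem_config()].
#'
#' @return An object of class `fohem_model` bundling the rule base, the
#'   stacked ensemble, the blend weights, the feature artifacts, and
#'   validation diagnostics.
#' @export
#' @examples
#' \donttest{
#' d <- simulate_yield_data(generator_config(n_records = 120, seed = 7))
#' m <- fohem_fit(d, fohem_config(seed = 7))
#' glance(m)
#' }
fohem_fit <- function(data, config = fohem_config()) {
  stopifnot(inherits(config, "fohem_config"))
  validate_dataset(data)
  if (nrow(data) < 40) {
    abort(sprintf("fohem_fit: need at least 40 records, got %d", nrow(data)))
  }
  schema <- data_schema(data)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }

  split <- stratified_split(data, config$val_fraction, stage_seed(config$seed, 11))
  d_fit <- data[split$fit, ]
  d_val <- data[split$val, ]
  attr(d_fit, "schema") <- schema
  attr(d_val, "schema") <- schema

  evaluator <- cv_evaluator(d_fit, folds = config$evaluator_folds,
                            num_trees = config$evaluator_trees,
                            seed = stage_seed(config$seed, 21))
  sel <- stage("feature_selection",
               ga_select_features(d_fit, config$ga_features, evaluator,
                                  lambda = config$lambda))
  # engineering is scored by the linear backend: a tree evaluator cannot
  # distinguish a transformation from any monotone surrogate of it
  eng_evaluator <- cv_evaluator(d_fit, folds = config$evaluator_folds,
                                seed = stage_seed(config$seed, 22),
                                model = "linear")
  eng <- stage("feature_engineering",
               ga_engineer_features(d_fit, sel$mask, config$ga_features,
                                    eng_evaluator, lambda = config$lambda))

  selected <- names(eng$mask)[eng$mask]
  cors <- vapply(selected, function(nm) abs(stats::cor(d_fit[[nm]], d_fit$yield)),
                 numeric(1))
  fis_feats <- selected[order(-cors)][seq_len(min(config$n_fis_inputs,
                                                  length(selected)))]
  if (length(fis_feats) < 2) {
    extra <- setdiff(schema$name, fis_feats)
    fis_feats <- c(fis_feats, extra[seq_len(2 - length(fis_feats))])
  }
  fis <- stage("fis_build",
               build_yield_fis(schema[match(fis_feats, schema$name), ]))

  X_fit <- apply_features(d_fit, eng$mask, eng$engineered)
  ensemble <- stage("stack_fit",
                    stack_fit(X_fit, d_fit$yield,
                              specs = default_base_specs(stage_seed(config$seed, 31)),
                              oof_folds = config$oof_folds,
                              seed = stage_seed(config$seed, 32)))

  X_val <- apply_features(d_val, eng$mask, eng$engineered)
  y_fis_val <- stage("fis_predict", suppressWarnings(fis_predict(fis, d_val)))
  y_ens_val <- predict(ensemble, X_val)
  weights <- stage("weight_optimization",
                   optimize_weights(d_val$yield, y_fis_val, y_ens_val,
                                    groups = group_key(d_val$treatment,
                                                       d_val$location),
                                    config = config$ga_weights,
                                    mode = config$weight_mode))

  X_all <- apply_features(data, eng$mask, eng$engineered)
  ensemble_full <- stage("ensemble_refit",
                         stack_fit(X_all, data$yield,
                                   specs = default_base_specs(stage_seed(config$seed, 31)),
                                   oof_folds = config$oof_folds,
                                   seed = stage_seed(config$seed, 32)))

  structure(list(fis = fis, ensemble = ensemble_full, weights = weights,
                 features = eng, schema = schema, config = config,
                 validation = list(
                   index = split$val,
                   y_true = d_val$yield, y_fis = y_fis_val, y_ens = y_ens_val,
                   groups = group_key(d_val$treatment, d_val$location)),
                 selection_history = sel$fitness_history,
                 engineering_history = eng$fitness_history),
            class = "fohem_model")
}

#' Predict yields from a fitted hybrid model
#'
#' Computes the FIS and ensemble predictions for each record and blends them
#' with the record's group weight (`w_fis * y_fis + (1 - w_fis) * y_ens`);
#' groups unseen at fit time fall back to the global weight.
#'
#' @param object A [fohem_fit()] model.
#' @param newdata Dataset tibble with the schema's feature columns plus
#'   `treatment` and `location`.
#' @param type `"response"` for the blended vector, `"components"` for a
#'   tibble with `yield_pred`, `yield_fis`, `yield_ens`, `w_fis`.
#' @param ... Unused.
#' @return Numeric vector or tibble, one entry per row of `newdata`.
#' @export
predict.fohem_model <- function(object, newdata,
                                type = c("response", "components"), ...) {
  type <- match.arg(type)
  validate_dataset(newdata, object$schema, require_yield = FALSE)
  y_fis <- suppressWarnings(fis_predict(object$fis, newdata))
  X <- apply_features(newdata, object$features$mask, object$features$engineered)
  y_ens <- predict(object$ensemble, X)
  keys <- group_key(newdata$treatment, newdata$location)
  w <- vapply(keys, weight_for_group, numeric(1), weights = object$weights)
  blend <- w * y_fis + (1 - w) * y_ens
  if (type == "response") return(unname(blend))
  tibble::tibble(yield_pred = unname(blend), yield_fis = y_fis,
                 yield_ens = y_ens, w_fis = unname(w))
}

#' @export
print.fohem_model <- function(x, ...) {
  cat("Fuzzy-optimized hybrid ensemble model\n")
  cat("  selected features:", sum(x$features$mask), "of",
      length(x$features$mask), "\n")
  cat("  engineered features:", nrow(x$features$engineered), "\n")
  cat("  FIS inputs:", paste(names(x$fis$input_vars), collapse = ", "), "\n")
  cat("  blend weights (", attr(x$weights, "mode"), "):\n", sep = "")
  print(as.data.frame(x$weights))
  invisible(x)
}
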