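#' Base-learner specification
#'
#' The three base learners of the ensemble: a random forest, a gradient
#' booster with native categorical handling for `treatment`/`location`, and
#' the in-package extreme learning machine. The forest and booster are
#' delegated to `ranger` and `xgboost`; the ELM is [elm_train()].
#'
#' @param kind One of `"random_forest"`, `"gradient_boosting_categorical"`,
#'   `"elm"`.
#' @param hyperparameters Named list overriding the defaults
#'   (forest: 300 trees; booster: 300 rounds, learning rate 0.1, depth 4;
#'   elm: 100 sigmoid hidden units, ridge 1e-3).
#' @param seed Integer seed for the learner.
#' @return A list of class `fohem_learner_spec`.
#' @export
base_learner_spec <- function(kind = c("random_forest",
                                       "gradient_boosting_categorical", "elm"),
                              hyperparameters = list(), seed = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "fohem_learner_spec")
}

#' Default ensemble roster
#'
#' @param seed Base seed; each learner gets a distinct derived seed.
#' @return List of three [base_learner_spec()]s.
#' @export
default_base_specs <- function(seed = 1) {
  list(base_learner_spec("random_forest", seed = stage_seed(seed, 101)),
       base_learner_spec("gradient_boosting_categorical", seed = stage_seed(seed, 202)),
       base_learner_spec("elm", seed = stage_seed(seed, 303)))
}

#' Train the base learners
#'
#' @param X Predictor tibble (numeric columns plus `treatment`/`location`
#'   factors, as produced by [apply_features()]).
#' @param y Numeric yield vector.
#' @param specs List of [base_learner_spec()]s.
#' @return List of trained learners (class `fohem_base_learner`), one per spec.
#' @export
train_base_learners <- function(X, y, specs = default_base_specs()) {
  if (!length(specs)) abort("train_base_learners: specs must be non-empty")
  purrr::map(specs, function(sp) train_one_learner(X, y, sp))
}

train_one_learner <- function(X, y, sp) {
  stopifnot(inherits(sp, "fohem_learner_spec"))
  hp <- sp$hyperparameters
  fit <- switch(
    sp$kind,
    random_forest = ranger::ranger(x = as.data.frame(X), y = y,
                                   num.trees = hp$num_trees %||% 300,
                                   seed = sp$seed, num.threads = 1),
    gradient_boosting_categorical = {
      xgboost::xgboost(as.data.frame(X), y,
                       nrounds = hp$nrounds %||% 300,
                       learning_rate = hp$learning_rate %||% 0.1,
                       max_depth = hp$max_depth %||% 4,
                       nthreads = 1, seed = sp$seed, verbosity = 0)
    },
    elm = elm_train(X, y,
                    hidden = hp$hidden %||% 100,
                    activation = hp$activation %||% "sigmoid",
                    ridge_lambda = hp$ridge_lambda %||% 1e-3,
                    seed = sp$seed),
    abort(sprintf("train_base_learners: unknown learner kind '%s'", sp$kind))
  )
  structure(list(kind = sp$kind, fit = fit, spec = sp, columns = names(X)),
            class = "fohem_base_learner")
}

#' @export
predict.fohem_base_learner <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$columns, names(newdata))
  if (length(missing_cols)) {
    abort(sprintf("predict: missing predictor column '%s'", missing_cols[1]))
  }
  newdata <- newdata[, object$columns, drop = FALSE]
  switch(object$kind,
         random_forest = stats::predict(object$fit,
                                        data = as.data.frame(newdata))$predictions,
         gradient_boosting_categorical =
           as.numeric(stats::predict(object$fit, as.data.frame(newdata))),
         elm = stats::predict(object$fit, newdata))
}
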