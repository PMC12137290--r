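# shared small fitted model: one fit, many assertions
tiny_fohem_config <- function(seed = 11) {
  fohem_config(
    seed = seed,
    ga_features = ga_config(population_size = 10, max_generations = 4,
                            patience = 2, seed = stage_seed(seed, 1)),
    ga_weights = ga_config(population_size = 40, max_generations = 25,
                           patience = 8, seed = stage_seed(seed, 2)),
    evaluator_trees = 30, oof_folds = 3
  )
}

fitted_cache <- new.env()
get_fitted <- function() {
  if (is.null(fitted_cache$m)) {
    fitted_cache$d <- simulate_yield_data(generator_config(n_records = 100,
                                                           seed = 11))
    fitted_cache$m <- fohem_fit(fitted_cache$d, tiny_fohem_config())
  }
  list(d = fitted_cache$d, m = fitted_cache$m)
}

test_that("undersized datasets are rejected with the minimum size", {
  d <- simulate_yield_data(generator_config(n_records = 20, seed = 1))
  expect_error(fohem_fit(d, tiny_fohem_config()), "at least 40 records")
})

test_that("the fitted model carries coherent artifacts", {
  fm <- get_fitted()
  m <- fm$m
  expect_s3_class(m, "fohem_model")
  expect_gte(sum(m$features$mask), 1)
  expect_true(all(names(m$fis$input_vars) %in% names(m$features$mask)))
  expect_true(dplyr::between(length(m$fis$input_vars), 2, 4))
  # simplex invariant on every stored weight pair
  w <- tidy(m)
  expect_true(all(w$w_fis >= 0 & w$w_ens >= 0))
  expect_equal(w$w_fis + w$w_ens, rep(1, nrow(w)))
  expect_true("global" %in% w$group)
  g <- glance(m)
  expect_equal(g$n_validation, length(m$validation$y_true))
  # the blend never loses to both components on its own validation split
  expect_lte(g$mse_blend, min(g$mse_fis, g$mse_ensemble) + 1e-9)
})

test_that("prediction is the per-record convex blend of FIS and ensemble", {
  fm <- get_fitted()
  p <- predict(fm$m, fm$d, type = "components")
  expect_equal(nrow(p), nrow(fm$d))
  expect_equal(p$yield_pred, p$w_fis * p$yield_fis + (1 - p$w_fis) * p$yield_ens,
               tolerance = 1e-9)
  expect_true(all(is.finite(p$yield_pred)))
  vec <- predict(fm$m, fm$d)
  expect_equal(vec, p$yield_pred)
  # endpoint identities: forcing the weights reproduces each component exactly
  m1 <- fm$m
  m1$weights$w_fis[] <- 1
  m1$weights$w_ens[] <- 0
  expect_equal(predict(m1, fm$d), p$yield_fis)
  m0 <- fm$m
  m0$weights$w_fis[] <- 0
  m0$weights$w_ens[] <- 1
  expect_equal(predict(m0, fm$d), p$yield_ens)
  # half-half weight blends the components arithmetically
  mh <- fm$m
  mh$weights$w_fis[] <- 0.5
  mh$weights$w_ens[] <- 0.5
  expect_equal(predict(mh, fm$d), (p$yield_fis + p$yield_ens) / 2)
})

test_that("unseen groups fall back to the global weight", {
  fm <- get_fitted()
  w <- fm$m$weights
  expect_equal(weight_for_group(w, "not|agroup"),
               w$w_fis[w$group == "global"])
})

test_that("refitting with the same seed reproduces the model", {
  fm <- get_fitted()
  m2 <- fohem_fit(fm$d, tiny_fohem_config())
  expect_identical(tidy(fm$m), tidy(m2))
  expect_identical(fm$m$features$mask, m2$features$mask)
  expect_equal(predict(fm$m, fm$d), predict(m2, fm$d))
})

test_that("invalid data fails validation; in-stage failures carry the stage name", {
  d <- simulate_yield_data(generator_config(n_records = 60, seed = 3))
  d_broken <- d
  d_broken$yield[1] <- NA_real_
  expect_error(fohem_fit(d_broken, tiny_fohem_config()), "missing values")
  # a constant target makes the fold R-squared undefined inside selection
  d_const <- d
  d_const$yield <- rep(5, nrow(d))
  expect_error(suppressWarnings(fohem_fit(d_const, tiny_fohem_config())),
               "\\[feature_selection\\]")
})

test_that("model bundles round-trip through disk", {
  fm <- get_fitted()
  dir <- withr::local_tempdir()
  write_fohem_bundle(fm$m, dir)
  expect_true(all(file.exists(file.path(dir, c("manifest.json", "fis.json",
                                               "weights.csv", "features.json",
                                               "convergence.csv", "model.rds")))))
  m2 <- read_fohem_bundle(dir)
  expect_equal(predict(m2, fm$d), predict(fm$m, fm$d))
  wtab <- readr::read_csv(file.path(dir, "weights.csv"), show_col_types = FALSE)
  expect_equal(wtab$w_fis, fm$m$weights$w_fis)
  conv <- readr::read_csv(file.path(dir, "convergence.csv"), show_col_types = FALSE)
  expect_true(all(c("feature_selection", "feature_engineering") %in% conv$stage))
})

test_that("autoplot and tidy accessors return well-formed objects", {
  fm <- get_fitted()
  res <- run_ga(ga_config(population_size = 10, max_generations = 5, seed = 1),
                init = function() binary_chromosome(rbinom(4, 1, 0.5)),
                fitness = function(ch) sum(ch$genes))
  expect_s3_class(autoplot(res), "ggplot")
  expect_equal(names(tidy(res)), c("generation", "best_fitness"))
  expect_s3_class(plot_membership(fm$m$fis$output_var), "ggplot")
  p <- predict(fm$m, fm$d)
  expect_s3_class(plot_predictions(fm$d, p), "ggplot")
  X <- fm$d[, 1:5]
  imp <- permutation_importance(function(Z) rowSums(as.matrix(Z)), X,
                                fm$d$yield, repeats = 3, seed = 1)
  expect_s3_class(autoplot(imp), "ggplot")
})
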