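test_that("candidate pool has the predicted size and composition", {
  d <- small_dataset(n = 60, seed = 1)
  p3 <- candidate_pool(d, top_k = 3)
  expect_equal(nrow(p3), 2 * 3 + choose(3, 2))  # 9
  p5 <- candidate_pool(d, top_k = 5)
  expect_equal(nrow(p5), 2 * 5 + choose(5, 2))  # 20
  expect_setequal(unique(p3$kind), c("square", "log1p", "product"))
  expect_error(candidate_pool(d, top_k = 0), "top_k")
})

test_that("log1p candidates are excluded for features that can go negative", {
  sc <- dplyr::bind_rows(
    feature_spec("pos", "soil", 0, 10, effect = 1),
    feature_spec("neg", "soil", -5, 5, effect = 1)
  )
  d <- simulate_yield_data(generator_config(n_records = 40, schema = sc,
                                            noise_sd = 0, seed = 1))
  pool <- candidate_pool(d, top_k = 2, schema = sc)
  expect_true("log1p_pos" %in% pool$name)
  expect_false("log1p_neg" %in% pool$name)
  expect_equal(nrow(pool), 2 + 1 + 1)  # 2 squares, 1 log1p, 1 product
})

test_that("apply_features materializes exactly the requested design", {
  d <- small_dataset(n = 30, seed = 2)
  sc <- attr(d, "schema")
  X <- apply_features(d)
  expect_equal(names(X), c(sc$name, "treatment", "location"))
  expect_equal(X$total_biomass, d$total_biomass)

  mask <- stats::setNames(sc$name %in% c("total_biomass", "iron"), sc$name)
  eng <- tibble::tibble(kind = c("square", "product"),
                        op1 = c("total_biomass", "total_biomass"),
                        op2 = c(NA, "iron"),
                        name = c("total_biomass^2", "total_biomass_x_iron"))
  X2 <- apply_features(d, mask, eng)
  # base columns come out in schema order (iron precedes total_biomass there)
  expect_equal(names(X2), c("iron", "total_biomass", "total_biomass^2",
                            "total_biomass_x_iron", "treatment", "location"))
  expect_equal(X2[["total_biomass^2"]], d$total_biomass^2)
  expect_equal(X2[["total_biomass_x_iron"]], d$total_biomass * d$iron)
  bad <- dplyr::mutate(eng, op1 = "nope")
  expect_error(apply_features(d, mask, bad), "missing operand")
})

test_that("parsimony pressure shrinks masks when accuracy is constant", {
  sc <- tiny_schema(2, 6)
  d <- simulate_yield_data(generator_config(n_records = 50, schema = sc,
                                            noise_sd = 0.1, seed = 5))
  res <- ga_select_features(d, ga_config(population_size = 20,
                                         max_generations = 12, seed = 5),
                            evaluator = function(X) 0.5, lambda = 0.05)
  expect_lte(sum(res$mask), 2)
  expect_gte(sum(res$mask), 1)
})

test_that("feature selection is deterministic under fixed seeds", {
  sc <- tiny_schema(3, 4)
  d <- simulate_yield_data(generator_config(n_records = 80, schema = sc,
                                            noise_sd = 0.2, seed = 3))
  cfg <- ga_config(population_size = 12, max_generations = 6, patience = 3, seed = 9)
  r1 <- ga_select_features(d, cfg, cv_evaluator(d, folds = 3, num_trees = 30, seed = 9))
  r2 <- ga_select_features(d, cfg, cv_evaluator(d, folds = 3, num_trees = 30, seed = 9))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$fitness_history, r2$fitness_history)
  expect_true(all(diff(r1$fitness_history) >= 0))
  # the reported cv_score re-evaluates the final mask
  ev <- cv_evaluator(d, folds = 3, num_trees = 30, seed = 9)
  expect_equal(r1$cv_score, ev(apply_features(d, r1$mask, NULL)), tolerance = 1e-9)
})

test_that("selection recovers planted informative features", {
  sc <- dplyr::bind_rows(tiny_schema(5, 0),
                         tiny_schema(0, 8))
  d <- simulate_yield_data(generator_config(n_records = 120, schema = sc,
                                            noise_sd = 0.1, seed = 21))
  res <- ga_select_features(
    d, ga_config(population_size = 20, max_generations = 10, patience = 4, seed = 21),
    cv_evaluator(d, folds = 3, num_trees = 40, seed = 21))
  informative <- paste0("sig", 1:5)
  expect_gte(sum(res$mask[informative]), 4)
})

test_that("engineering keeps a planted quadratic and rejects useless transforms", {
  sc <- tiny_schema(2, 1)
  d <- simulate_yield_data(generator_config(n_records = 120, schema = sc,
                                            noise_sd = 0, seed = 31))
  # plant a strong quadratic in sig1 on top of a linear sig2 signal
  z1 <- (d$sig1 - 5) / 5
  set.seed(31)
  d$yield <- 5 + 3 * z1^2 + 0.5 * (d$sig2 - 5) / 5 + rnorm(nrow(d), 0, 0.05)
  attr(d, "schema") <- sc
  base_mask <- stats::setNames(c(TRUE, TRUE, FALSE), sc$name)
  cfg <- ga_config(population_size = 20, max_generations = 10, patience = 4, seed = 31)
  res <- ga_engineer_features(d, base_mask, cfg,
                              cv_evaluator(d, folds = 3, seed = 31,
                                           model = "linear"))
  expect_true("sig1^2" %in% res$engineered$name)
  expect_gte(res$cv_score, 0.9)

  # a purely linear target: retention rule keeps only score-improving sets
  d2 <- simulate_yield_data(generator_config(n_records = 120, schema = sc,
                                             noise_sd = 0.05, seed = 32))
  ev2 <- cv_evaluator(d2, folds = 3, seed = 32, model = "linear")
  res2 <- ga_engineer_features(d2, base_mask, cfg, ev2)
  base_score <- ev2(apply_features(d2, base_mask, NULL))
  expect_gte(res2$cv_score, base_score)
})
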