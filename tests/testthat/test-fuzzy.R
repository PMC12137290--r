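test_that("triangular membership is exact at peak, feet, and midpoints", {
  mf <- tri_mf(0, 5, 10)
  expect_equal(mf_eval(mf, 5), 1)
  expect_equal(mf_eval(mf, 2.5), 0.5)
  expect_equal(mf_eval(mf, 12), 0)
  expect_equal(mf_eval(mf, -1), 0)

  set.seed(11)
  for (i in 1:200) {
    abc <- sort(runif(3, -50, 50))
    if (abc[1] == abc[2] || abc[2] == abc[3]) next
    mf <- tri_mf(abc[1], abc[2], abc[3])
    expect_equal(mf_eval(mf, abc[2]), 1)
    expect_equal(mf_eval(mf, abc[1]), 0)
    expect_equal(mf_eval(mf, abc[3]), 0)
    expect_equal(mf_eval(mf, (abc[1] + abc[2]) / 2), 0.5)
    x <- runif(20, abc[1] - 10, abc[3] + 10)
    mu <- mf_eval(mf, x)
    expect_true(all(mu >= 0 & mu <= 1))
  }
})

test_that("degenerate segments and shoulders evaluate as saturated membership", {
  expect_equal(mf_eval(tri_mf(5, 5, 10), 5), 1)
  expect_equal(mf_eval(tri_mf(0, 5, 5), 5), 1)
  lo <- tri_mf(0, 2, 6, left_shoulder = TRUE)
  expect_equal(mf_eval(lo, c(-3, 0, 1, 2)), rep(1, 4))
  expect_equal(mf_eval(lo, 4), 0.5)
  hi <- tri_mf(4, 8, 10, right_shoulder = TRUE)
  expect_equal(mf_eval(hi, c(8, 9, 10, 99)), rep(1, 4))
  expect_equal(mf_eval(hi, 6), 0.5)
  expect_error(tri_mf(3, 2, 5), "a <= b <= c")
})

simple_base <- function(and_operator = "min") {
  v1 <- fuzzy_variable("x1", c(0, 10), list(
    low = tri_mf(0, 0, 10, left_shoulder = TRUE), high = tri_mf(0, 10, 10)))
  v2 <- fuzzy_variable("x2", c(0, 10), list(
    low = tri_mf(0, 0, 10, left_shoulder = TRUE), high = tri_mf(0, 10, 10)))
  out <- fuzzy_variable("y", c(0, 10), list(
    low = tri_mf(0, 2, 4), mid = tri_mf(7.5, 8.25, 9), high = tri_mf(6, 8, 10)))
  fuzzy_rulebase(list(v1, v2), out,
                 list(fuzzy_rule(c(x1 = "high", x2 = "high"), "mid"),
                      fuzzy_rule(c(x1 = "low", x2 = "low"), "low")),
                 and_operator = and_operator)
}

test_that("rule strength AND-combines memberships with min or product", {
  base <- simple_base("min")
  # x1 = 8 -> mu_high = 0.8; x2 = 3 -> mu_high = 0.3
  r <- fuzzy_rule(c(x1 = "high", x2 = "high"), "mid")
  expect_equal(rule_strength(r, c(x1 = 8, x2 = 3), base), 0.3)
  base_p <- simple_base("product")
  expect_equal(rule_strength(r, c(x1 = 8, x2 = 3), base_p), 0.24)
  r1 <- fuzzy_rule(c(x1 = "high"), "mid")
  expect_equal(rule_strength(r1, c(x1 = 7), base), 0.7)
  expect_error(rule_strength(r, c(x1 = 8), base), "missing input variable 'x2'")
})

test_that("min-AND strength never exceeds any antecedent membership", {
  base <- simple_base("min")
  set.seed(4)
  for (i in 1:50) {
    x <- runif(2, 0, 10)
    s <- rule_strength(fuzzy_rule(c(x1 = "high", x2 = "high"), "mid"),
                       c(x1 = x[1], x2 = x[2]), base)
    expect_lte(s, mf_eval(base$input_vars$x1$sets$high, x[1]) + 1e-12)
    expect_lte(s, mf_eval(base$input_vars$x2$sets$high, x[2]) + 1e-12)
  }
})

test_that("inference recovers the axis of symmetry of symmetric consequents", {
  base <- simple_base()
  # both inputs at 10: only the 'mid' rule fires, at strength 1
  res <- fis_infer(base, c(x1 = 10, x2 = 10))
  expect_equal(res$crisp, 8.25, tolerance = 1e-2)
  # two equal-strength rules with consequents symmetric about 8
  v <- fuzzy_variable("x1", c(0, 1), list(on = tri_mf(0, 1, 1)))
  out <- fuzzy_variable("y", c(0, 16), list(
    a = tri_mf(5, 7, 9), b = tri_mf(7, 9, 11)))
  b2 <- fuzzy_rulebase(list(v), out,
                       list(fuzzy_rule(c(x1 = "on"), "a"),
                            fuzzy_rule(c(x1 = "on"), "b")))
  expect_equal(fis_infer(b2, c(x1 = 1))$crisp, 8, tolerance = 1e-2)
})

test_that("no fired rule raises a typed error; crisp stays inside the universe", {
  base <- simple_base()
  # x1 = 10 (low = 0), x2 = 0 (high = 0): both rules have strength 0
  expect_error(fis_infer(base, c(x1 = 10, x2 = 0)), "no rule fired")
  set.seed(5)
  for (i in 1:25) {
    x <- runif(2, 0.5, 9.5)
    crisp <- fis_infer(base, c(x1 = x[1], x2 = x[2]))$crisp
    expect_true(crisp >= 0 && crisp <= 10)
  }
})

test_that("crisp output matches an independent dense-grid oracle", {
  set.seed(42)
  for (case in 1:30) {
    base <- random_rulebase(k = 2, resolution = 1000)
    inputs <- c(x1 = runif(1), x2 = runif(1))
    got <- fis_infer(base, inputs)$crisp
    want <- oracle_infer(base, inputs, n_grid = 1e4)
    expect_lt(abs(got - want), 1e-3 * 10)
  }
})

test_that("doubling the defuzzification resolution barely moves the output", {
  set.seed(21)
  base <- random_rulebase(k = 2, resolution = 1000)
  base2 <- base
  base2$resolution <- 2000L
  for (case in 1:20) {
    inputs <- c(x1 = runif(1), x2 = runif(1))
    c1 <- fis_infer(base, inputs)$crisp
    c2 <- fis_infer(base2, inputs)$crisp
    expect_lt(abs(c1 - c2), 0.005 * 10)
  }
})

test_that("default yield rule base has the expert structure", {
  sc <- crop_schema()
  feats <- sc[sc$name %in% c("total_biomass", "M_residue_biomass"), ]
  fis <- build_yield_fis(feats)
  expect_length(fis$rules, 9)
  expect_setequal(names(fis$input_vars), c("total_biomass", "M_residue_biomass"))
  med <- fis$output_var$sets$medium
  expect_equal(c(med$a, med$c), c(7.5, 9))
  expect_equal(med$b, 8.25)
  # all-high inputs land in the high-yield support
  res <- fis_infer(fis, c(total_biomass = 19, M_residue_biomass = 9500))
  expect_gte(res$crisp, 9)
  # all-low inputs land low
  res_lo <- fis_infer(fis, c(total_biomass = 1, M_residue_biomass = 500))
  expect_lt(res_lo$crisp, 7.5)
  expect_error(build_yield_fis(feats[0, ]), "empty")
  expect_error(build_yield_fis(feats[1, ]), "2-4")
})

test_that("a crisp 8.3 t/ha prediction is classified as medium yield", {
  sc <- crop_schema()
  fis <- build_yield_fis(sc[sc$name %in% c("total_biomass", "M_residue_biomass"), ])
  expect_equal(classify_yield(fis, 8.3), "medium")
  expect_equal(classify_yield(fis, c(2, 8.3, 9.8)), c("low", "medium", "high"))
})

test_that("batch prediction is deterministic, bounded, and falls back gracefully", {
  sc <- crop_schema()
  fis <- build_yield_fis(sc[sc$name %in% c("total_biomass", "M_residue_biomass",
                                           "transpiration"), ])
  d <- simulate_yield_data(generator_config(n_records = 40, seed = 2))
  rep5 <- d[rep(3, 5), ]
  preds <- fis_predict(fis, rep5)
  expect_true(all(preds == preds[1]))
  all_preds <- fis_predict(fis, d)
  expect_true(all(all_preds >= 0 & all_preds <= 10))
  expect_error(fis_predict(fis, d[, 1:3]), "missing feature column")
  # a rule base with a hole: no rule covers mid-range inputs
  v <- fuzzy_variable("total_biomass", c(0, 20),
                      list(low = tri_mf(0, 0, 5, left_shoulder = TRUE)))
  out <- fuzzy_variable("y", c(0, 10), list(low = tri_mf(0, 2, 4)))
  holey <- fuzzy_rulebase(list(v), out, list(fuzzy_rule(c(total_biomass = "low"), "low")))
  expect_warning(p <- fis_predict(holey, tibble::tibble(total_biomass = c(1, 18))),
                 "no rule fired")
  expect_equal(p[2], 5)  # universe midpoint fallback
})

test_that("rule bases survive a serialization round trip", {
  sc <- crop_schema()
  fis <- build_yield_fis(sc[sc$name %in% c("total_biomass", "LAI"), ])
  path <- withr::local_tempfile(fileext = ".json")
  write_fis(fis, path)
  fis2 <- read_fis(path)
  set.seed(8)
  for (i in 1:10) {
    inputs <- c(total_biomass = runif(1, 0, 20), LAI = runif(1, 0, 8))
    expect_equal(fis_infer(fis2, inputs)$crisp, fis_infer(fis, inputs)$crisp)
  }
})
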