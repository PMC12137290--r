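genes_key <- function(pop) sort(vapply(pop, function(ch) paste(ch$genes, collapse = ""),
                                       character(1)))

test_that("without variation operators the population passes through unchanged", {
  cfg <- ga_config(population_size = 20, crossover_rate = 0, mutation_rate = 0,
                   elitism_count = 20, max_generations = 5, patience = 100,
                   seed = 1)
  init_pop <- with_seed(1, purrr::map(1:20, ~binary_chromosome(rbinom(6, 1, 0.5))))
  counter <- 0
  res <- run_ga(cfg,
                init = function() {
                  counter <<- counter + 1
                  init_pop[[counter]]
                },
                fitness = function(ch) sum(ch$genes))
  expect_identical(genes_key(res$final_population), genes_key(init_pop))
})

test_that("GA finds the exhaustively-known optimum of a 10-bit problem", {
  # fitness -sum(genes): unique global optimum over all 2^10 states is all-zeros
  cfg <- ga_config(population_size = 100, crossover_rate = 0.8,
                   mutation_rate = 0.02, max_generations = 50, seed = 7)
  res <- run_ga(cfg,
                init = function() binary_chromosome(rbinom(10, 1, 0.5)),
                fitness = function(ch) -sum(ch$genes))
  expect_equal(res$best$genes, rep(0L, 10))
  expect_equal(res$best_fitness, 0)
})

test_that("elitism makes the best-fitness history monotone non-decreasing", {
  target <- c(1, 0, 1, 1, 0, 0, 1, 0)
  for (seed in 1:5) {
    res <- run_ga(ga_config(population_size = 30, max_generations = 25,
                            elitism_count = 1, seed = seed, patience = 50),
                  init = function() binary_chromosome(rbinom(8, 1, 0.5)),
                  fitness = function(ch) -sum((ch$genes - target)^2))
    expect_true(all(diff(res$history) >= 0))
    expect_equal(length(res$history), res$generations_run)
  }
})

test_that("identical seeds reproduce the full GA trajectory", {
  cfg <- ga_config(population_size = 40, max_generations = 15, seed = 3)
  fit <- function(ch) sum(ch$genes * seq_along(ch$genes))
  init <- function() binary_chromosome(rbinom(12, 1, 0.5))
  r1 <- run_ga(cfg, init, fit)
  r2 <- run_ga(cfg, init, fit)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best$genes, r2$best$genes)
})

test_that("early stopping respects patience", {
  # constant fitness: stagnates immediately, stops after `patience` generations
  res <- run_ga(ga_config(population_size = 10, max_generations = 50,
                          patience = 4, seed = 2),
                init = function() binary_chromosome(rbinom(4, 1, 0.5)),
                fitness = function(ch) 1)
  expect_equal(res$generations_run, 4)
  expect_true(all(res$history == 1))
})

test_that("real chromosomes respect their bounds through crossover and mutation", {
  bounds <- cbind(rep(0, 5), rep(1, 5))
  res <- run_ga(ga_config(population_size = 30, max_generations = 20,
                          mutation_rate = 0.5, seed = 6),
                init = function() real_chromosome(runif(5), bounds),
                fitness = function(ch) -sum((ch$genes - 0.9)^2))
  for (ch in res$final_population) {
    expect_true(all(ch$genes >= 0 & ch$genes <= 1))
  }
  expect_true(all(abs(res$best$genes - 0.9) < 0.2))
})

test_that("non-finite fitness is reported with its generation and chromosome", {
  expect_error(
    run_ga(ga_config(population_size = 5, max_generations = 2, seed = 1),
           init = function() binary_chromosome(rbinom(3, 1, 0.5)),
           fitness = function(ch) NaN),
    "non-finite fitness at generation 0, chromosome 1")
})

test_that("large tournaments pick the drawn maximum; ties break to the lowest index", {
  pop <- purrr::map(1:3, ~binary_chromosome(rbinom(3, 1, 0.5)))
  # tie at the top: with k = 50 draws both tied members are (essentially
  # always) drawn, so the lowest index must win every time
  fits <- c(7, 7, 2)
  set.seed(1)
  for (i in 1:50) expect_equal(tournament_select(pop, fits, k = 50), 1)
  # distinct fitnesses: a large tournament almost always contains the best
  fits2 <- c(1, 5, 3)
  picks <- vapply(1:50, function(i) tournament_select(pop, fits2, k = 50),
                  numeric(1))
  expect_true(all(picks == 2))
  expect_error(tournament_select(list(), numeric(0), 1), "empty population")
})

test_that("k = 2 tournament selection follows the analytic win probabilities", {
  # with replacement over fitnesses (1,2,3): P = (1/9, 3/9, 5/9)
  pop <- purrr::map(1:3, ~binary_chromosome(0))
  fits <- c(1, 2, 3)
  draws <- with_seed(99, vapply(1:10000, function(i) {
    tournament_select(pop, fits, k = 2)
  }, numeric(1)))
  p <- as.numeric(table(factor(draws, levels = 1:3))) / 10000
  expect_lt(abs(p[1] - 1 / 9), 0.03)
  expect_lt(abs(p[2] - 3 / 9), 0.03)
  expect_lt(abs(p[3] - 5 / 9), 0.03)
})
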