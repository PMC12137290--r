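#' Genetic-algorithm configuration
#'
#' Defaults follow the optimization protocol used throughout the package:
#' population 100, crossover rate 0.8, mutation rate 0.02, tournament
#' selection, and a 50-generation budget with early stopping once the best
#' fitness has stagnated for `patience` generations.
#'
#' @param population_size Number of chromosomes per generation.
#' @param crossover_rate Probability a selected pair is recombined.
#' @param mutation_rate Per-gene mutation probability.
#' @param tournament_size Tournament size for selection (>= 2).
#' @param max_generations Generation budget.
#' @param elitism_count Number of top chromosomes copied unchanged.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param patience Generations without improvement before stopping early.
#'
#' @return A list of class `fohem_ga_config`.
#' @export
ga_config <- function(population_size = 100L, crossover_rate = 0.8,
                      mutation_rate = 0.02, tournament_size = 3L,
                      max_generations = 50L, elitism_count = 1L,
                      seed = 1L, patience = 10L) {
  if (crossover_rate < 0 || crossover_rate > 1) abort("ga_config: crossover_rate must be in [0, 1]")
  if (mutation_rate < 0 || mutation_rate > 1) abort("ga_config: mutation_rate must be in [0, 1]")
  if (tournament_size < 2) abort("ga_config: tournament_size must be >= 2")
  if (elitism_count < 1 || elitism_count > population_size) {
    abort("ga_config: elitism_count must be in [1, population_size]")
  }
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 max_generations = as.integer(max_generations),
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed), patience = as.integer(patience)),
            class = "fohem_ga_config")
}

#' Chromosome constructors
#'
#' Binary chromosomes hold 0/1 genes (e.g. feature-inclusion masks); real
#' chromosomes hold bounded continuous genes (e.g. blend weights).
#'
#' @param genes Numeric vector of gene values.
#' @param bounds Two-column matrix of per-gene `[lo, hi]` (real kind only).
#' @return A list of class `fohem_chromosome`.
#' @export
binary_chromosome <- function(genes) {
  genes <- as.integer(genes)
  if (!all(genes %in% c(0L, 1L))) abort("binary_chromosome: genes must be 0/1")
  structure(list(kind = "binary", genes = genes, bounds = NULL),
            class = "fohem_chromosome")
}

#' @rdname binary_chromosome
#' @export
real_chromosome <- function(genes, bounds) {
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (nrow(bounds) != length(genes)) abort("real_chromosome: one bounds row per gene")
  if (any(genes < bounds[, 1] - 1e-12) || any(genes > bounds[, 2] + 1e-12)) {
    abort("real_chromosome: genes outside bounds")
  }
  structure(list(kind = "real", genes = as.numeric(genes), bounds = bounds),
            class = "fohem_chromosome")
}

#' Tournament selection
#'
#' Draws `k` members uniformly with replacement and returns the index of the
#' fittest; ties are broken by the lowest index.
#'
#' @param population List of chromosomes (only its length is used).
#' @param fitnesses Numeric vector of fitness values (higher is better).
#' @param k Tournament size.
#' @return The selected index into `population`.
#' @export
tournament_select <- function(population, fitnesses, k) {
  n <- length(population)
  if (n == 0L) abort("tournament_select: empty population")
  if (k < 1) abort("tournament_select: k must be >= 1")
  cand <- sample.int(n, k, replace = TRUE)
  mx <- max(fitnesses[cand])
  min(cand[fitnesses[cand] == mx])
}

crossover_pair <- function(p1, p2) {
  ng <- length(p1$genes)
  if (p1$kind == "binary") {
    if (ng < 2) return(list(p1, p2))
    cut <- sample.int(ng - 1L, 1L)
    g1 <- c(p1$genes[1:cut], p2$genes[(cut + 1):ng])
    g2 <- c(p2$genes[1:cut], p1$genes[(cut + 1):ng])
    list(binary_chromosome(g1), binary_chromosome(g2))
  } else {
    alpha <- stats::runif(1)
    g1 <- alpha * p1$genes + (1 - alpha) * p2$genes
    g2 <- alpha * p2$genes + (1 - alpha) * p1$genes
    list(real_chromosome(g1, p1$bounds), real_chromosome(g2, p1$bounds))
  }
}

mutate_chromosome <- function(ch, rate) {
  hit <- stats::runif(length(ch$genes)) < rate
  if (!any(hit)) return(ch)
  if (ch$kind == "binary") {
    ch$genes[hit] <- 1L - ch$genes[hit]
  } else {
    sd <- 0.1 * (ch$bounds[, 2] - ch$bounds[, 1])
    ch$genes[hit] <- ch$genes[hit] + stats::rnorm(sum(hit), 0, sd[hit])
    ch$genes <- pmin(pmax(ch$genes, ch$bounds[, 1]), ch$bounds[, 2])
  }
  ch
}

#' Run a seeded genetic algorithm
#'
#' Generic GA over binary or bounded-real chromosomes: tournament selection,
#' one-point crossover (binary) or arithmetic blend (real) applied with
#' probability `crossover_rate`, per-gene mutation (bit flip, or Gaussian
#' perturbation with sd `0.1 * (hi - lo)` clamped to bounds), and elitism.
#' Fitness is always maximized; stops after `max_generations` or once the
#' best fitness has not improved for `patience` generations.
#'
#' @param config A [ga_config()].
#' @param init A zero-argument factory returning a random chromosome
#'   ([binary_chromosome()] or [real_chromosome()]); called under the run's
#'   seeded RNG.
#' @param fitness Function chromosome -> finite numeric fitness to maximize.
#'   Must be deterministic (fix any internal seeds).
#'
#' @return A list of class `fohem_ga_result`: `best` chromosome,
#'   `best_fitness`, `history` (per-generation best, non-decreasing under
#'   elitism), `generations_run`, and `final_population`.
#' @export
#' @examples
#' res <- run_ga(ga_config(population_size = 30, max_generations = 20, seed = 1),
#'               init = function() binary_chromosome(stats::rbinom(8, 1, 0.5)),
#'               fitness = function(ch) sum(ch$genes))
#' res$best_fitness
run_ga <- function(config, init, fitness) {
  stopifnot(inherits(config, "fohem_ga_config"))
  with_seed(config$seed, {
    pop <- purrr::map(seq_len(config$population_size), ~init())
    evaluate <- function(population, gen) {
      f <- vapply(seq_along(population), function(i) {
        v <- fitness(population[[i]])
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
          abort(sprintf("run_ga: non-finite fitness at generation %d, chromosome %d",
                        gen, i))
        }
        v
      }, numeric(1))
      f
    }
    fit <- evaluate(pop, 0L)
    history <- numeric(0)
    best_idx <- which.max(fit)
    best <- pop[[best_idx]]
    best_fit <- fit[best_idx]
    stagnant <- 0L
    gens <- 0L
    for (gen in seq_len(config$max_generations)) {
      ord <- order(fit, decreasing = TRUE)
      elites <- pop[ord[seq_len(config$elitism_count)]]
      children <- list()
      while (length(children) < config$population_size - config$elitism_count) {
        i1 <- tournament_select(pop, fit, config$tournament_size)
        i2 <- tournament_select(pop, fit, config$tournament_size)
        pair <- list(pop[[i1]], pop[[i2]])
        if (stats::runif(1) < config$crossover_rate) {
          pair <- crossover_pair(pair[[1]], pair[[2]])
        }
        pair <- purrr::map(pair, mutate_chromosome, rate = config$mutation_rate)
        children <- c(children, pair)
      }
      children <- children[seq_len(config$population_size - config$elitism_count)]
      pop <- c(elites, children)
      fit <- evaluate(pop, gen)
      gens <- gen
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best_fit <- fit[gen_best]
        best <- pop[[gen_best]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      history <- c(history, best_fit)
      if (stagnant >= config$patience) break
    }
    structure(list(best = best, best_fitness = best_fit, history = history,
                   generations_run = gens, final_population = pop),
              class = "fohem_ga_result")
  })
}

#' Export a GA convergence history
#'
#' @param result A [run_ga()] result.
#' @return A tibble with columns `generation` and `best_fitness`.
#' @export
ga_history <- function(result) {
  stopifnot(inherits(result, "fohem_ga_result"))
  tibble::tibble(generation = seq_along(result$history),
                 best_fitness = result$history)
}
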