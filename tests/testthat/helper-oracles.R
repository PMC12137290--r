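# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately naive and written without reusing the
# package's inference/solver code paths.

# --- dense-grid Mamdani oracle -------------------------------------------
# Loop-based re-implementation of clipped-max Mamdani inference with
# centroid defuzzification on an arbitrary grid size.
oracle_tri_mu <- function(a, b, c, left, right, x) {
  if (left && x <= b) return(1)
  if (right && x >= b) return(1)
  if (x == b) return(1)
  if (x < a || x > c) return(0)
  if (x < b) return((x - a) / (b - a))
  if (c > b) return((c - x) / (c - b))
  0
}

# vectorized-over-grid variant of the oracle membership (piecewise ifelse)
oracle_tri_mu_vec <- function(mf, x) {
  up <- if (mf$b > mf$a) (x - mf$a) / (mf$b - mf$a) else rep(1, length(x))
  down <- if (mf$c > mf$b) (mf$c - x) / (mf$c - mf$b) else rep(1, length(x))
  mu <- pmax(0, pmin(up, down, 1))
  mu[x == mf$b] <- 1
  if (mf$left_shoulder) mu[x <= mf$b] <- 1
  if (mf$right_shoulder) mu[x >= mf$b] <- 1
  mu
}

oracle_infer <- function(base, inputs, n_grid = 1e4) {
  strengths <- sapply(base$rules, function(r) {
    mus <- sapply(names(r$antecedents), function(vn) {
      mf <- base$input_vars[[vn]]$sets[[r$antecedents[[vn]]]]
      oracle_tri_mu(mf$a, mf$b, mf$c, mf$left_shoulder, mf$right_shoulder,
                    inputs[[vn]])
    })
    if (base$and_operator == "min") min(mus) else prod(mus)
  })
  uni <- base$output_var$universe
  grid <- seq(uni[1], uni[2], length.out = n_grid)
  agg <- numeric(n_grid)
  for (i in seq_along(base$rules)) {
    if (strengths[i] <= 0) next
    mf <- base$output_var$sets[[base$rules[[i]]$consequent]]
    agg <- pmax(agg, pmin(oracle_tri_mu_vec(mf, grid), strengths[i]))
  }
  if (all(agg == 0)) return(NA_real_)
  sum(grid * agg) / sum(agg)
}

# random rule base over k input variables on [0, 1], output on [0, 10]
random_rulebase <- function(k = 2, n_sets = 3, resolution = 1000) {
  make_var <- function(name, lo, hi) {
    centers <- sort(runif(n_sets, lo, hi))
    sets <- lapply(seq_len(n_sets), function(i) {
      a <- if (i == 1) lo else centers[i - 1]
      cc <- if (i == n_sets) hi else centers[i + 1]
      tri_mf(a, centers[i], cc,
             left_shoulder = (i == 1), right_shoulder = (i == n_sets))
    })
    names(sets) <- paste0("s", seq_len(n_sets))
    fuzzy_variable(name, c(lo, hi), sets)
  }
  input_vars <- lapply(seq_len(k), function(i) make_var(paste0("x", i), 0, 1))
  output_var <- make_var("y", 0, 10)
  combos <- expand.grid(rep(list(paste0("s", seq_len(n_sets))), k),
                        stringsAsFactors = FALSE)
  names(combos) <- paste0("x", seq_len(k))
  rules <- lapply(seq_len(nrow(combos)), function(i) {
    fuzzy_rule(unlist(combos[i, , drop = FALSE]),
               sample(paste0("s", seq_len(n_sets)), 1))
  })
  fuzzy_rulebase(input_vars, output_var, rules, resolution = resolution)
}

# --- generic ridge oracle -------------------------------------------------
# argmin ||intercept + H beta - y||^2 + lambda ||beta||^2 via centered
# normal equations (the package solves the same problem by SVD).
oracle_ridge <- function(H, y, lambda) {
  h_mu <- colMeans(H)
  Hc <- sweep(H, 2, h_mu, "-")
  beta <- solve(crossprod(Hc) + lambda * diag(ncol(H)), crossprod(Hc, y - mean(y)))
  intercept <- mean(y) - sum(h_mu * beta)
  c(intercept, as.numeric(beta))
}

# closed-form optimum of the 1-D blend weight (projection, clamped to [0,1])
oracle_blend_weight <- function(y_true, y_fis, y_ens) {
  d <- y_fis - y_ens
  if (sum(d^2) == 0) return(0.5)
  min(max(sum((y_true - y_ens) * d) / sum(d^2), 0), 1)
}

# --- small fixtures -------------------------------------------------------
tiny_schema <- function(p_signal = 2, p_noise = 1) {
  specs <- list()
  for (i in seq_len(p_signal)) {
    specs[[length(specs) + 1]] <-
      feature_spec(paste0("sig", i), "soil", 0, 10, effect = 0.8)
  }
  for (i in seq_len(p_noise)) {
    specs[[length(specs) + 1]] <-
      feature_spec(paste0("noise", i), "soil", 0, 10, noise_only = TRUE)
  }
  do.call(dplyr::bind_rows, specs)
}

small_dataset <- function(n = 60, seed = 1, noise_sd = 0.2, schema = NULL) {
  cfg <- generator_config(n_records = n, schema = schema %||% crop_schema(),
                          noise_sd = noise_sd, seed = seed)
  simulate_yield_data(cfg)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
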