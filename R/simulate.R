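#' Simulate a synthetic intercropping yield dataset
#'
#' Draws `n_records` plot-season records under the configured schema.
#' Feature values are uniform within their expert-defined `[low, high]`
#' ranges; treatment and location are assigned near-balanced (every
#' treatment-by-location group gets within one record of `n/8`) and then
#' shuffled. Yield is
#' `base + treatment_effect + location_effect + sum(effect_j * z_j) + N(0, noise_sd)`
#' clipped at zero, where `z_j` standardizes feature `j` to `[-1, 1]`
#' within its range. Identical seeds give identical datasets.
#'
#' @param config A [generator_config()].
#'
#' @return A tibble with one column per schema feature, plus `treatment`
#'   and `location` (factors) and `yield` (t/ha). The schema is attached
#'   as attribute `"schema"`.
#' @export
#' @examples
#' d <- simulate_yield_data(generator_config(n_records = 40, seed = 1))
#' dplyr::count(d, treatment, location)
simulate_yield_data <- function(config = generator_config()) {
  if (!inherits(config, "fohem_generator_config")) {
    abort("simulate_yield_data: `config` must come from generator_config()")
  }
  schema <- config$schema
  n <- config$n_records
  with_seed(config$seed, {
    groups <- tidyr::expand_grid(treatment = TREATMENTS, location = LOCATIONS)
    idx <- rep(seq_len(nrow(groups)), length.out = n)
    idx <- sample(idx)
    feats <- purrr::map(seq_len(nrow(schema)), function(j) {
      stats::runif(n, schema$low[j], schema$high[j])
    })
    names(feats) <- schema$name
    feats <- tibble::as_tibble(feats)
    mid <- (schema$low + schema$high) / 2
    half <- (schema$high - schema$low) / 2
    z <- sweep(sweep(as.matrix(feats), 2, mid, "-"), 2, half, "/")
    signal <- as.numeric(z %*% schema$effect)
    treatment <- factor(groups$treatment[idx], levels = TREATMENTS)
    location <- factor(groups$location[idx], levels = LOCATIONS)
    noise <- stats::rnorm(n, 0, config$noise_sd)
    yield <- config$base_yield +
      unname(config$treatment_effects[as.character(treatment)]) +
      unname(config$location_effects[as.character(location)]) +
      signal + noise
    out <- dplyr::mutate(feats, treatment = treatment, location = location,
                         yield = pmax(yield, 0))
    attr(out, "schema") <- schema
    out
  })
}

data_schema <- function(data) {
  sc <- attr(data, "schema")
  if (is.null(sc)) {
    # reconstruct a minimal schema from observed numeric columns
    nm <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "yield")
    sc <- dplyr::bind_rows(purrr::map(nm, function(x) {
      lo <- min(data[[x]], na.rm = TRUE)
      hi <- max(data[[x]], na.rm = TRUE)
      if (lo >= hi) hi <- lo + 1
      feature_spec(x, "soil", lo, hi)
    }))
  }
  sc
}

validate_dataset <- function(data, schema = NULL, require_yield = TRUE) {
  if (!is.data.frame(data)) abort("dataset must be a data frame")
  schema <- schema %||% data_schema(data)
  missing_cols <- setdiff(c(schema$name, "treatment", "location",
                            if (require_yield) "yield"), names(data))
  if (length(missing_cols)) {
    abort(sprintf("missing column: %s", missing_cols[1]))
  }
  for (nm in c(schema$name, if (require_yield) "yield")) {
    if (!is.numeric(data[[nm]])) {
      abort(sprintf("column '%s' must be numeric", nm))
    }
    if (anyNA(data[[nm]])) {
      abort(sprintf("column '%s' contains missing values (first at row %d)",
                    nm, which(is.na(data[[nm]]))[1]))
    }
  }
  bad_t <- setdiff(unique(as.character(data$treatment)), TREATMENTS)
  if (length(bad_t)) {
    abort(sprintf("unknown treatment code '%s'; valid codes: %s",
                  bad_t[1], paste(TREATMENTS, collapse = ", ")))
  }
  bad_l <- setdiff(unique(as.character(data$location)), LOCATIONS)
  if (length(bad_l)) {
    abort(sprintf("unknown location code '%s'; valid codes: %s",
                  bad_l[1], paste(LOCATIONS, collapse = ", ")))
  }
  invisible(data)
}

#' Write / read a yield dataset as CSV
#'
#' Plain RFC-4180 CSV with a header row: feature columns in schema order,
#' then `treatment`, `location`, `yield`. `read_yield_csv()` validates the
#' header against the schema, coerces `treatment`/`location` to factors with
#' the canonical code sets, and fails loudly on missing columns, non-numeric
#' cells, or unknown codes.
#'
#' @param data A dataset tibble (from [simulate_yield_data()] or compatible).
#' @param path File path.
#' @param schema Feature schema; defaults to the schema attached to the data
#'   (write) or [crop_schema()] (read).
#'
#' @return `write_yield_csv()` returns `path` invisibly; `read_yield_csv()`
#'   returns the dataset tibble with the schema attached.
#' @export
write_yield_csv <- function(data, path, schema = NULL) {
  schema <- schema %||% data_schema(data)
  validate_dataset(data, schema)
  out <- data[, c(schema$name, "treatment", "location", "yield")]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_yield_csv
#' @export
read_yield_csv <- function(path, schema = crop_schema()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c(schema$name, "treatment", "location", "yield"), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing column: %s", missing_cols[1]))
  }
  num_cols <- c(schema$name, "yield")
  parsed <- purrr::map(num_cols, function(nm) {
    x <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(x) & !is.na(raw[[nm]]))
    if (length(bad) || anyNA(raw[[nm]])) {
      row <- c(bad, which(is.na(raw[[nm]])))[1]
      abort(sprintf("non-numeric value in column '%s' at row %d", nm, row))
    }
    x
  })
  names(parsed) <- num_cols
  out <- tibble::as_tibble(parsed[schema$name])
  out$treatment <- raw$treatment
  out$location <- raw$location
  out$yield <- parsed$yield
  validate_dataset(out, schema)
  out$treatment <- factor(out$treatment, levels = TREATMENTS)
  out$location <- factor(out$location, levels = LOCATIONS)
  attr(out, "schema") <- schema
  out
}

#' Seed-deterministic k-fold split
#'
#' Shuffles the row indices with the given seed and deals them into `k`
#' folds whose sizes differ by at most one.
#'
#' @param data A data frame (only its row count is used) or an integer row count.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed.
#'
#' @return A list of `k` elements, each `list(train = ..., test = ...)` of
#'   integer row indices; the test sets partition `1:n`.
#' @export
#' @examples
#' kfold_split(10, k = 5, seed = 1)
kfold_split <- function(data, k = 5, seed = 1) {
  n <- if (is.data.frame(data)) nrow(data) else as.integer(data)
  if (k < 2) abort("kfold_split: k must be >= 2")
  if (k > n) abort(sprintf("kfold_split: k (%d) exceeds number of records (%d)", k, n))
  idx <- with_seed(seed, sample.int(n))
  # deal shuffled indices round-robin so fold sizes differ by <= 1
  fold_of <- rep(seq_len(k), length.out = n)
  purrr::map(seq_len(k), function(f) {
    test <- sort(idx[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
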