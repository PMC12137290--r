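#' Define a single feature of the crop-record schema
#'
#' A feature spec describes one numeric column of a plot-season record:
#' its agronomic group, the expert-defined range it is drawn from, and the
#' signed linear contribution of the (range-standardized) feature to yield
#' used by the synthetic generator. Features flagged `noise_only` carry no
#' yield signal and exist so that feature-selection runs have a planted
#' negative answer.
#'
#' @param name Feature name (a syntactic identifier).
#' @param group One of `"soil"`, `"crop"`, `"management"`.
#' @param low,high Range of the feature (in its native unit); `low < high`.
#' @param effect Signed contribution (t/ha per standardized unit) of the
#'   feature to yield. Must be 0 when `noise_only` is `TRUE`.
#' @param noise_only If `TRUE`, the feature carries no yield signal.
#'
#' @return A one-row tibble with columns `name`, `group`, `low`, `high`,
#'   `effect`, `noise_only`.
#' @export
#' @examples
#' feature_spec("soil_pH", "soil", 6.5, 8.5, effect = 0.2)
feature_spec <- function(name, group, low, high, effect = 0, noise_only = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("feature_spec: `name` must be a non-empty string")
  }
  group <- match.arg(group, c("soil", "crop", "management"))
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    abort(sprintf("feature_spec: invalid range [%s, %s] for feature '%s' (need low < high)",
                  low, high, name))
  }
  if (noise_only && effect != 0) {
    abort(sprintf("feature_spec: feature '%s' is noise_only but has effect %g != 0",
                  name, effect))
  }
  tibble::tibble(name = name, group = group, low = low, high = high,
                 effect = effect, noise_only = noise_only)
}

#' Default crop-record schema
#'
#' The 26 numeric features used by the default synthetic generator, spanning
#' soil, crop, and management variables of a maize-soybean intercropping
#' trial. Together with the categorical `treatment` and `location` columns
#' this gives 28 input parameters per record. Effect signs encode the
#' agronomic ground truth planted in the generator: total biomass, maize
#' residue biomass, plant-available moisture (PMC) and soil pH push yield
#' up; excess iron and high clay content push it down. Eight features are
#' pure noise so selection procedures can be scored against a known answer.
#'
#' @return A tibble of [feature_spec()] rows.
#' @export
#' @examples
#' crop_schema()
crop_schema <- function() {
  dplyr::bind_rows(
    # soil
    feature_spec("soil_organic_carbon", "soil", 0.2, 1.5, effect = 0.25),
    feature_spec("soil_pct_N",          "soil", 0.02, 0.15, noise_only = TRUE),
    feature_spec("soil_pct_C",          "soil", 0.2, 1.6,  noise_only = TRUE),
    feature_spec("CN_ratio",            "soil", 8, 15,     noise_only = TRUE),
    feature_spec("bulk_density",        "soil", 1.1, 1.7,  effect = -0.15),
    feature_spec("Mn",                  "soil", 1, 15,     noise_only = TRUE),
    feature_spec("P",                   "soil", 4, 20,     effect = 0.15),
    feature_spec("K",                   "soil", 80, 280,   effect = 0.15),
    feature_spec("soil_pH",             "soil", 6.5, 8.5,  effect = 0.2),
    feature_spec("water_pH",            "soil", 6.5, 8.5,  effect = 0.15),
    feature_spec("iron",                "soil", 2, 60,     effect = -0.4),
    feature_spec("clay_content",        "soil", 5, 45,     effect = -0.3),
    feature_spec("PMC",                 "soil", 5, 25,     effect = 0.3),
    feature_spec("sand_content",        "soil", 20, 70,    noise_only = TRUE),
    feature_spec("EC",                  "soil", 0.2, 4,    noise_only = TRUE),
    feature_spec("Zn",                  "soil", 0.5, 5,    noise_only = TRUE),
    feature_spec("soil_temp",           "soil", 15, 35,    noise_only = TRUE),
    # crop
    feature_spec("total_biomass",       "crop", 0, 20,     effect = 0.8),
    feature_spec("transpiration",       "crop", 1, 8,      effect = 0.25),
    feature_spec("crop_N_uptake",       "crop", 50, 250,   effect = 0.2),
    feature_spec("yield_per_plant",     "crop", 20, 300,   effect = 0.2),
    feature_spec("crop_biomass",        "crop", 2, 18,     effect = 0.3),
    feature_spec("LAI",                 "crop", 0, 8,      effect = 0.3),
    # management
    feature_spec("M_residue_biomass",   "management", 0, 10000, effect = 0.5),
    feature_spec("nutrient_mgmt_score", "management", 0, 10, effect = 0.2),
    feature_spec("pest_mgmt_score",     "management", 0, 10, effect = 0.15)
  )
}

validate_schema <- function(schema) {
  required <- c("name", "group", "low", "high", "effect", "noise_only")
  if (!is.data.frame(schema) || !all(required %in% names(schema))) {
    abort(paste("schema must be a data frame with columns:",
                paste(required, collapse = ", ")))
  }
  if (anyDuplicated(schema$name)) {
    abort(sprintf("schema error: duplicated feature name '%s'",
                  schema$name[duplicated(schema$name)][1]))
  }
  bad <- which(!(schema$low < schema$high))
  if (length(bad)) {
    abort(sprintf("schema error in feature '%s': low (%g) must be < high (%g)",
                  schema$name[bad[1]], schema$low[bad[1]], schema$high[bad[1]]))
  }
  bad <- which(schema$noise_only & schema$effect != 0)
  if (length(bad)) {
    abort(sprintf("schema error in feature '%s': noise_only features must have effect 0",
                  schema$name[bad[1]]))
  }
  reserved <- intersect(schema$name, c("treatment", "location", "yield"))
  if (length(reserved)) {
    abort(sprintf("schema error: feature name '%s' is reserved", reserved[1]))
  }
  invisible(schema)
}

#' Generator configuration for synthetic intercropping records
#'
#' Bundles everything the synthetic generator needs: the feature schema,
#' additive treatment and location effects on yield (t/ha), the residual
#' noise level, and the seed. Defaults emulate a 225-record maize-soybean
#' intercropping trial at two sites: maize-dominant treatments out-yield
#' sole soybean, and Khairpur out-yields Bahawalpur.
#'
#' @param n_records Number of plot-season records (default 225).
#' @param schema Feature schema, a tibble of [feature_spec()] rows.
#' @param base_yield Baseline yield in t/ha before group and feature effects.
#' @param treatment_effects Named numeric vector over `SS, SM, 2M2S, 2M3S`.
#' @param location_effects Named numeric vector over `Bahawalpur, Khairpur`.
#' @param noise_sd Gaussian residual standard deviation, t/ha.
#' @param seed Integer seed; identical seeds give identical datasets.
#'
#' @return A list of class `fohem_generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_records = 40, seed = 1)
#' d <- simulate_yield_data(cfg)
generator_config <- function(n_records = 225,
                             schema = crop_schema(),
                             base_yield = 6,
                             treatment_effects = c(SS = -2.2, SM = 1.2,
                                                   `2M2S` = 0.8, `2M3S` = 0.4),
                             location_effects = c(Bahawalpur = -0.5,
                                                  Khairpur = 0.5),
                             noise_sd = 0.3,
                             seed = 42) {
  validate_schema(schema)
  if (!is.numeric(n_records) || n_records < 8) {
    abort("generator_config: n_records must be >= 8 (one record per treatment x location)")
  }
  if (!setequal(names(treatment_effects), TREATMENTS)) {
    abort(sprintf("generator_config: treatment_effects must be named exactly {%s}",
                  paste(TREATMENTS, collapse = ", ")))
  }
  if (!setequal(names(location_effects), LOCATIONS)) {
    abort(sprintf("generator_config: location_effects must be named exactly {%s}",
                  paste(LOCATIONS, collapse = ", ")))
  }
  if (noise_sd < 0) abort("generator_config: noise_sd must be >= 0")
  structure(
    list(n_records = as.integer(n_records), schema = schema,
         base_yield = base_yield,
         treatment_effects = treatment_effects[TREATMENTS],
         location_effects = location_effects[LOCATIONS],
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "fohem_generator_config"
  )
}
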