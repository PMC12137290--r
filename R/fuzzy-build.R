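#' Build the default yield-prediction rule base
#'
#' Constructs a Mamdani rule base over 2-4 selected input features.
#' Each input gets low / medium / high sets. For `total_biomass` and
#' `M_residue_biomass` the breakpoints follow the expert ranges of the
#' intercropping study design (total biomass: low 0-10 t, medium 5-20 t,
#' high 15-20 t; maize residue biomass: low 0-4000 kg/ha, high
#' 6000-10000 kg/ha); other features get an overlapping tertile partition
#' of their `[low, high]` range. The overlapping printed ranges are realised
#' as peak-at-midpoint triangles, with the boundary sets shouldered so
#' extreme inputs keep full membership.
#'
#' The output variable `yield` spans 0-10 t/ha with low yield below
#' 7.5 t/ha (left-shouldered, peak at 0), medium between 7.5 and 9 t/ha
#' (peak 8.25), and high from 9 t/ha up to 10 (right-shouldered).
#'
#' The rule grid enumerates every combination of input categories and maps
#' it monotonically: scoring low = 0, medium = 1, high = 2, the consequent
#' is low when the mean score is <= 0.5, high when >= 1.5, else medium —
#' so all-low maps to low, all-high to high, and balanced mixtures to medium.
#'
#' @param features A tibble of [feature_spec()] rows (2-4 of them) naming
#'   the selected input features and their ranges.
#' @param resolution Defuzzification grid size, default 1000.
#' @param and_operator `"min"` (default) or `"product"`.
#'
#' @return A [fuzzy_rulebase()] with `3^k` rules for `k` input features.
#' @export
#' @examples
#' sc <- crop_schema()
#' fis <- build_yield_fis(sc[sc$name %in% c("total_biomass", "M_residue_biomass"), ])
#' length(fis$rules)  # 9
build_yield_fis <- function(features, resolution = 1000L,
                            and_operator = c("min", "product")) {
  and_operator <- match.arg(and_operator)
  if (!is.data.frame(features) || nrow(features) == 0) {
    abort("build_yield_fis: empty feature list")
  }
  if (nrow(features) < 2 || nrow(features) > 4) {
    abort(sprintf("build_yield_fis: need 2-4 input features, got %d", nrow(features)))
  }
  input_vars <- purrr::map(seq_len(nrow(features)), function(i) {
    yield_input_variable(features$name[i], features$low[i], features$high[i])
  })

  output_var <- fuzzy_variable("yield", c(0, 10), list(
    low    = tri_mf(0, 0, 7.5, left_shoulder = TRUE),
    medium = tri_mf(7.5, 8.25, 9),
    high   = tri_mf(9, 10, 10, right_shoulder = TRUE)
  ))

  labels <- c("low", "medium", "high")
  combos <- expand.grid(rep(list(labels), nrow(features)),
                        stringsAsFactors = FALSE)
  names(combos) <- features$name
  rules <- purrr::map(seq_len(nrow(combos)), function(i) {
    ante <- unlist(combos[i, , drop = FALSE])
    score <- mean(match(ante, labels) - 1)
    cons <- if (score <= 0.5) "low" else if (score >= 1.5) "high" else "medium"
    fuzzy_rule(ante, cons)
  })
  fuzzy_rulebase(input_vars, output_var, rules,
                 and_operator = and_operator, resolution = resolution)
}

# low/medium/high partition of one input feature
yield_input_variable <- function(name, low, high) {
  if (name == "total_biomass") {
    # expert ranges (tons): low 0-10, medium 5-20, high 15-20
    sets <- list(
      low    = tri_mf(0, 5, 10, left_shoulder = TRUE),
      medium = tri_mf(5, 12.5, 20),
      high   = tri_mf(15, 17.5, 20, right_shoulder = TRUE)
    )
    return(fuzzy_variable(name, c(0, 20), sets))
  }
  if (name == "M_residue_biomass") {
    # expert ranges (kg/ha): low 0-4000, high 6000-10000; medium bridges them
    sets <- list(
      low    = tri_mf(0, 2000, 4000, left_shoulder = TRUE),
      medium = tri_mf(3000, 5000, 7000),
      high   = tri_mf(6000, 8000, 10000, right_shoulder = TRUE)
    )
    return(fuzzy_variable(name, c(0, 10000), sets))
  }
  span <- high - low
  centers <- low + span * c(1 / 6, 1 / 2, 5 / 6)
  sets <- list(
    low    = tri_mf(low, centers[1], centers[2], left_shoulder = TRUE),
    medium = tri_mf(centers[1], centers[2], centers[3]),
    high   = tri_mf(centers[2], centers[3], high, right_shoulder = TRUE)
  )
  fuzzy_variable(name, c(low, high), sets)
}

#' Classify a crisp yield value into its fuzzy category
#'
#' Returns the label of the output set with the highest membership at `x`
#' (argmax; ties broken by set order low, medium, high).
#'
#' @param base A rule base from [build_yield_fis()].
#' @param x Crisp yield value(s), t/ha.
#' @return Character vector of set labels.
#' @export
#' @examples
#' sc <- crop_schema()
#' fis <- build_yield_fis(sc[sc$name %in% c("total_biomass", "M_residue_biomass"), ])
#' classify_yield(fis, 8.3)  # "medium"
classify_yield <- function(base, x) {
  mus <- vapply(base$output_var$sets, mf_eval, numeric(length(x)), x = x)
  if (length(x) == 1L) mus <- matrix(mus, nrow = 1,
                                     dimnames = list(NULL, names(base$output_var$sets)))
  colnames(mus) <- names(base$output_var$sets)
  colnames(mus)[max.col(mus, ties.method = "first")]
}
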