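#' Fuzzy rule and rule base
#'
#' A rule maps AND-combined antecedents ("input variable is set-label") to a
#' consequent set of the output variable. A rule base bundles input
#' variables, the output variable, the rules, the AND operator (`min`, the
#' Mamdani default, or `product`), and the grid resolution used for
#' centroid defuzzification.
#'
#' @param antecedents Named character vector: `c(variable = "set label", ...)`.
#' @param consequent Set label of the output variable.
#'
#' @return `fuzzy_rule()` an object of class `fohem_rule`; `fuzzy_rulebase()`
#'   an object of class `fohem_fis`.
#' @export
fuzzy_rule <- function(antecedents, consequent) {
  if (!length(antecedents) || is.null(names(antecedents))) {
    abort("fuzzy_rule: antecedents must be a named character vector")
  }
  structure(list(antecedents = antecedents, consequent = consequent),
            class = "fohem_rule")
}

#' @rdname fuzzy_rule
#' @param input_vars List of [fuzzy_variable()] objects.
#' @param output_var The output [fuzzy_variable()].
#' @param rules List of [fuzzy_rule()] objects.
#' @param and_operator `"min"` (default) or `"product"`.
#' @param resolution Number of grid points for defuzzification (>= 100).
#' @export
fuzzy_rulebase <- function(input_vars, output_var, rules,
                           and_operator = c("min", "product"),
                           resolution = 1000L) {
  and_operator <- match.arg(and_operator)
  if (resolution < 100) abort("fuzzy_rulebase: resolution must be >= 100")
  names(input_vars) <- vapply(input_vars, `[[`, character(1), "name")
  for (r in rules) {
    for (vn in names(r$antecedents)) {
      if (!vn %in% names(input_vars)) {
        abort(sprintf("fuzzy_rulebase: rule references unknown variable '%s'", vn))
      }
      if (!r$antecedents[[vn]] %in% names(input_vars[[vn]]$sets)) {
        abort(sprintf("fuzzy_rulebase: variable '%s' has no set '%s'",
                      vn, r$antecedents[[vn]]))
      }
    }
    if (!r$consequent %in% names(output_var$sets)) {
      abort(sprintf("fuzzy_rulebase: output variable has no set '%s'", r$consequent))
    }
  }
  structure(list(input_vars = input_vars, output_var = output_var,
                 rules = rules, and_operator = and_operator,
                 resolution = as.integer(resolution)),
            class = "fohem_fis")
}

#' Firing strength of one rule
#'
#' AND-combines the membership degrees of the rule's antecedents at the
#' given crisp inputs, with `min` (default) or `product`.
#'
#' @param rule A [fuzzy_rule()].
#' @param inputs Named numeric vector (or single-row data frame) of crisp values.
#' @param base The [fuzzy_rulebase()] supplying variable definitions and the
#'   AND operator.
#' @return A single number in `[0, 1]`.
#' @export
rule_strength <- function(rule, inputs, base) {
  inputs <- unlist(inputs)
  mus <- vapply(names(rule$antecedents), function(vn) {
    if (!vn %in% names(inputs)) {
      abort(sprintf("rule_strength: missing input variable '%s'", vn))
    }
    mf_eval(base$input_vars[[vn]]$sets[[rule$antecedents[[vn]]]], inputs[[vn]])
  }, numeric(1))
  if (base$and_operator == "min") min(mus) else prod(mus)
}

#' Mamdani inference for one input vector
#'
#' Clips each rule's consequent set at the rule's firing strength (Mamdani
#' implication), aggregates the clipped shapes by pointwise maximum over the
#' output universe discretized at `resolution` points, and defuzzifies by
#' centroid.
#'
#' @inheritParams rule_strength
#' @param base A [fuzzy_rulebase()].
#' @return A list with `crisp` (the defuzzified output, always inside the
#'   output universe), `grid`, and `mu` (the aggregated membership curve).
#' @export
#' @examples
#' v_in <- fuzzy_variable("x", c(0, 1), list(lo = tri_mf(0, 0, 1), hi = tri_mf(0, 1, 1)))
#' v_out <- fuzzy_variable("y", c(0, 10), list(
#'   low = tri_mf(0, 2, 4), high = tri_mf(6, 8, 10)))
#' fis <- fuzzy_rulebase(list(v_in), v_out, list(
#'   fuzzy_rule(c(x = "lo"), "low"), fuzzy_rule(c(x = "hi"), "high")))
#' fis_infer(fis, c(x = 0.9))$crisp
fis_infer <- function(base, inputs) {
  stopifnot(inherits(base, "fohem_fis"))
  if (!length(base$rules)) abort("fis_infer: rule base has no rules")
  strengths <- vapply(base$rules, rule_strength, numeric(1),
                      inputs = inputs, base = base)
  if (all(strengths == 0)) {
    abort("no rule fired", class = "fohem_no_rule_fired")
  }
  uni <- base$output_var$universe
  grid <- seq(uni[1], uni[2], length.out = base$resolution)
  agg <- numeric(base$resolution)
  for (i in seq_along(base$rules)) {
    if (strengths[i] == 0) next
    mu <- mf_eval(base$output_var$sets[[base$rules[[i]]$consequent]], grid)
    agg <- pmax(agg, pmin(mu, strengths[i]))
  }
  crisp <- sum(grid * agg) / sum(agg)
  list(crisp = crisp, grid = grid, mu = agg, strengths = strengths)
}

#' Batch FIS prediction over a dataset
#'
#' Runs [fis_infer()] on every record. Records for which no rule fires
#' receive the midpoint of the output universe, with one warning summarising
#' how many records fell back.
#'
#' @param base A [fuzzy_rulebase()].
#' @param data Data frame containing every input variable as a column.
#' @return Numeric vector of crisp predictions, one per row.
#' @export
fis_predict <- function(base, data) {
  vars <- names(base$input_vars)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(sprintf("fis_predict: missing feature column '%s'", missing_cols[1]))
  }
  mid <- mean(base$output_var$universe)
  n_fallback <- 0L
  out <- vapply(seq_len(nrow(data)), function(i) {
    inputs <- vapply(vars, function(v) as.numeric(data[[v]][i]), numeric(1))
    tryCatch(fis_infer(base, inputs)$crisp,
             fohem_no_rule_fired = function(e) {
               n_fallback <<- n_fallback + 1L
               mid
             })
  }, numeric(1))
  if (n_fallback > 0L) {
    warn(sprintf("fis_predict: no rule fired for %d record(s); used output midpoint %g",
                 n_fallback, mid))
  }
  out
}

#' Serialize / restore a fuzzy rule base
#'
#' Writes the complete FIS definition (variables, set parameters, rules,
#' operator, resolution) as pretty-printed JSON so rule bases are
#' versionable and diffable.
#'
#' @param base A [fuzzy_rulebase()].
#' @param path File path.
#' @return `read_fis()` returns the restored `fohem_fis`.
#' @export
write_fis <- function(base, path) {
  ser_var <- function(v) {
    list(name = v$name, universe = v$universe,
         sets = purrr::map(v$sets, function(m) {
           list(a = m$a, b = m$b, c = m$c,
                left_shoulder = m$left_shoulder, right_shoulder = m$right_shoulder)
         }))
  }
  doc <- list(
    input_vars = purrr::map(unname(base$input_vars), ser_var),
    output_var = ser_var(base$output_var),
    rules = purrr::map(base$rules, function(r) {
      list(antecedents = as.list(r$antecedents), consequent = r$consequent)
    }),
    and_operator = base$and_operator,
    resolution = base$resolution
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fis
#' @export
read_fis <- function(path) {
  doc <- jsonlite::read_json(path)
  de_var <- function(v) {
    sets <- purrr::map(v$sets, function(m) {
      tri_mf(m$a, m$b, m$c, isTRUE(m$left_shoulder), isTRUE(m$right_shoulder))
    })
    fuzzy_variable(v$name, unlist(v$universe), sets)
  }
  fuzzy_rulebase(
    input_vars = purrr::map(doc$input_vars, de_var),
    output_var = de_var(doc$output_var),
    rules = purrr::map(doc$rules, function(r) {
      fuzzy_rule(unlist(r$antecedents), r$consequent)
    }),
    and_operator = doc$and_operator,
    resolution = doc$resolution
  )
}
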