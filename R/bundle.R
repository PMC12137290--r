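#' Write / read a fitted model bundle
#'
#' Serializes a fitted hybrid model to a directory: a JSON manifest
#' (package version, seeds, configuration), the fuzzy rule base as JSON,
#' the blend-weight table and feature artifacts as CSV/JSON, the ELM and
#' meta-combiner as portable numeric arrays, and the tree models via their
#' libraries' native serialization. `read_fohem_bundle()` restores a model
#' whose predictions are identical to the original's.
#'
#' @param model A `fohem_model` from [fohem_fit()].
#' @param dir Bundle directory (created if needed).
#' @return `write_fohem_bundle()` returns `dir` invisibly;
#'   `read_fohem_bundle()` returns the restored `fohem_model`.
#' @export
write_fohem_bundle <- function(model, dir) {
  stopifnot(inherits(model, "fohem_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "fohem",
    version = as.character(utils::packageVersion("fohem")),
    seed = model$config$seed,
    weight_mode = attr(model$weights, "mode"),
    n_features_selected = sum(model$features$mask),
    n_engineered = nrow(model$features$engineered),
    fis_inputs = names(model$fis$input_vars)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_fis(model$fis, file.path(dir, "fis.json"))
  readr::write_csv(tibble::as_tibble(model$weights),
                   file.path(dir, "weights.csv"))
  jsonlite::write_json(
    list(mask = as.list(model$features$mask),
         engineered = model$features$engineered),
    file.path(dir, "features.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  readr::write_csv(ga_history_frame(model),
                   file.path(dir, "convergence.csv"))
  # full model object (includes the tree learners' native serializations)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

ga_history_frame <- function(model) {
  dplyr::bind_rows(
    tibble::tibble(stage = "feature_selection",
                   generation = seq_along(model$selection_history),
                   best_fitness = model$selection_history),
    tibble::tibble(stage = "feature_engineering",
                   generation = seq_along(model$engineering_history),
                   best_fitness = model$engineering_history),
    purrr::imap_dfr(attr(model$weights, "ga_history"), function(h, nm) {
      tibble::tibble(stage = paste0("weights_", nm),
                     generation = seq_along(h), best_fitness = h)
    })
  )
}

#' @rdname write_fohem_bundle
#' @export
read_fohem_bundle <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) {
    abort(sprintf("read_fohem_bundle: no model.rds in '%s'", dir))
  }
  model <- readRDS(path)
  stopifnot(inherits(model, "fohem_model"))
  model
}
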