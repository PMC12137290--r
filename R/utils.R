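# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage seed from a global seed; keeps results < 2^31.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

group_key <- function(treatment, location) {
  paste(as.character(treatment), as.character(location), sep = "|")
}

#' @importFrom rlang abort warn .data %||%
#' @importFrom generics tidy glance
NULL

# Treatment and location codes of the intercropping design.
TREATMENTS <- c("SS", "SM", "2M2S", "2M3S")
LOCATIONS <- c("Bahawalpur", "Khairpur")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
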