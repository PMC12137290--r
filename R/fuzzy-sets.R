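#' Triangular membership function
#'
#' A triangular membership function with left foot `a`, peak `b`, right foot
#' `c` (`a <= b <= c`). Shouldered variants saturate at 1 beyond the peak:
#' a left-shouldered set has `mu(x) = 1` for all `x <= b`, a right-shouldered
#' set has `mu(x) = 1` for all `x >= b`. Degenerate segments (`a == b` or
#' `b == c`) evaluate to 1 at the shared point.
#'
#' @param a,b,c Feet and peak, `a <= b <= c`.
#' @param left_shoulder,right_shoulder Saturate membership beyond the peak.
#'
#' @return An object of class `fohem_mf`.
#' @export
#' @examples
#' mf_eval(tri_mf(0, 5, 10), c(0, 2.5, 5, 10, 12))
tri_mf <- function(a, b, c, left_shoulder = FALSE, right_shoulder = FALSE) {
  stopifnot_scalar_number(a, "a")
  stopifnot_scalar_number(b, "b")
  stopifnot_scalar_number(c, "c")
  if (!(a <= b && b <= c)) {
    abort(sprintf("tri_mf: need a <= b <= c, got (%g, %g, %g)", a, b, c))
  }
  structure(list(a = a, b = b, c = c,
                 left_shoulder = isTRUE(left_shoulder),
                 right_shoulder = isTRUE(right_shoulder)),
            class = "fohem_mf")
}

#' Evaluate a membership function
#'
#' Vectorized over `x`; always returns values in `[0, 1]`.
#'
#' @param mf A [tri_mf()].
#' @param x Numeric vector of crisp values.
#' @return Numeric vector of membership degrees.
#' @export
mf_eval <- function(mf, x) {
  stopifnot(inherits(mf, "fohem_mf"))
  a <- mf$a; b <- mf$b; cc <- mf$c
  mu <- numeric(length(x))
  up <- x >= a & x < b
  if (b > a) mu[up] <- (x[up] - a) / (b - a)
  down <- x >= b & x <= cc
  if (cc > b) mu[down] <- (cc - x[down]) / (cc - b)
  mu[x == b] <- 1
  if (mf$left_shoulder) mu[x <= b] <- 1
  if (mf$right_shoulder) mu[x >= b] <- 1
  pmin(pmax(mu, 0), 1)
}

#' Fuzzy linguistic variable
#'
#' A named variable over a numeric universe, carrying labelled fuzzy sets
#' (e.g. low / medium / high yield).
#'
#' @param name Variable name.
#' @param universe Length-2 numeric `c(min, max)`.
#' @param sets Named list of [tri_mf()] objects; names are the set labels.
#'
#' @return An object of class `fohem_variable`.
#' @export
#' @examples
#' v <- fuzzy_variable("yield", c(0, 10), list(
#'   low = tri_mf(0, 0, 7.5, left_shoulder = TRUE),
#'   medium = tri_mf(7.5, 8.25, 9),
#'   high = tri_mf(9, 10, 10, right_shoulder = TRUE)
#' ))
fuzzy_variable <- function(name, universe, sets) {
  if (!is.character(name) || length(name) != 1L) abort("fuzzy_variable: bad name")
  if (length(universe) != 2L || universe[1] >= universe[2]) {
    abort("fuzzy_variable: universe must be c(min, max) with min < max")
  }
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("fuzzy_variable: sets must be a uniquely named non-empty list")
  }
  for (lab in names(sets)) {
    mf <- sets[[lab]]
    if (!inherits(mf, "fohem_mf")) {
      abort(sprintf("fuzzy_variable '%s': set '%s' is not a tri_mf", name, lab))
    }
    if (mf$a < universe[1] - 1e-9 || mf$c > universe[2] + 1e-9) {
      abort(sprintf("fuzzy_variable '%s': support of set '%s' exceeds the universe",
                    name, lab))
    }
  }
  structure(list(name = name, universe = as.numeric(universe), sets = sets),
            class = "fohem_variable")
}

# membership of x in every set of a variable -> named numeric vector
variable_memberships <- function(var, x) {
  vapply(var$sets, mf_eval, numeric(length(x)), x = x)
}
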