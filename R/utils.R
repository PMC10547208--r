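# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default numerical tolerances
#'
#' Single source for the feasibility / integrality / zero tolerances used
#' throughout the package. All three are tied together: the MILP solver's
#' feasibility tolerance, the threshold below which a usage slack
#' \eqn{\alpha_j} counts as zero, and the tolerance used when a target flux
#' is fixed at its optimum.
#'
#' @param zero threshold (mmol/gDCW/h) below which a slack or flux is
#'   treated as zero.
#' @param feasibility constraint feasibility tolerance passed to the solver.
#' @param integrality integrality tolerance for binary variables.
#' @return A named list with components `zero`, `feasibility`, `integrality`.
#' @export
mri_tolerances <- function(zero = 1e-6, feasibility = 1e-6,
                           integrality = 1e-6) {
  stopifnot(zero > 0, feasibility > 0, integrality > 0)
  list(zero = zero, feasibility = feasibility, integrality = integrality)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_mri <- function(...) stop(..., call. = FALSE)

warn_mri <- function(...) warning(..., call. = FALSE)
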