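# Calibration of the expression-to-flux conversion constant C by
# sensitivity analysis of the growth-prediction error: growth is predicted
# by FBA with the expression-usage caps active, the mean relative error
# against measured growth rates is evaluated over a grid of C values, and
# the minimizing C is chosen.

build_growth_problem <- function(model, profile, C, tol = mri_tolerances(),
                                 exclusivity_big_m = 1000) {
  if (is.na(model$biomass))
    stop_mri("model has no biomass reaction; growth cannot be predicted")
  # reuse the scoring assembly, then strip the usage objective: maximize
  # net biomass flux with z relaxed (the indicator rows become inactive)
  prob <- build_mri_problem(model, profile, C, tol = tol,
                            exclusivity_big_m = exclusivity_big_m)
  p <- prob$milp
  p$obj <- numeric(length(p$obj))
  cols <- which(prob$model$origin$source == prob$model$biomass)
  sgn <- ifelse(prob$model$origin$direction[cols] == "fwd", 1, -1)
  p$obj[cols] <- sgn
  p$maximize <- TRUE
  p$integer[prob$z_idx] <- FALSE
  prob$milp <- p
  prob
}

#' Predict the growth rate from expression levels
#'
#' Maximizes biomass flux subject to steady state, the medium bounds, the
#' expression-usage caps (each gene's total supported flux at most
#' `E_j * C`), and direction exclusivity on reversible reactions.
#'
#' @param model an `irreversible_model` with a biomass reaction.
#' @param profile an `expression_profile`.
#' @param medium optional [medium_spec()] applied first.
#' @param C conversion constant.
#' @param tol tolerances.
#' @return Predicted growth rate (1/h).
#' @export
predict_growth_rate <- function(model, profile, medium = NULL, C,
                                tol = mri_tolerances()) {
  model <- convert_model(model)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  res <- solve_milp(build_growth_problem(model, profile, C, tol)$milp)
  if (res$status != "optimal")
    stop_mri("growth prediction failed with status '", res$status, "'")
  res$objective
}

#' Default calibration grid
#'
#' 30 logarithmically spaced C values spanning four decades centred on
#' (maximum flux bound) / (median total expression), a scale-free window
#' that brackets the C at which expression caps start to bind.
#'
#' @param model an `irreversible_model` (or `stoich_model`).
#' @param profiles list of `expression_profile`s.
#' @param n grid size.
#' @param decades total width in decades.
#' @return Increasing numeric vector of candidate C values.
#' @export
default_C_grid <- function(model, profiles, n = 30L, decades = 4) {
  tot <- stats::median(vapply(profiles, function(p) sum(p$values), 0))
  centre <- max(model$ub) / max(tot, .Machine$double.eps)
  10^seq(log10(centre) - decades / 2, log10(centre) + decades / 2,
         length.out = n)
}

#' Calibrate the conversion constant C
#'
#' For each candidate C, growth is predicted for every strain with a
#' measured growth rate and the error against the measurement is
#' averaged; the C minimizing the error is the optimum. Growth prediction
#' uses the same direction-exclusivity constraints as scoring, so the
#' flux space is identical across the package.
#'
#' @param model `stoich_model` or `irreversible_model` with a biomass
#'   reaction.
#' @param profiles named list of `expression_profile`s.
#' @param phenotypes `phenotype_table` with a `growth_rate` column; only
#'   strains present in both inputs with a measured growth rate are used.
#' @param medium a [medium_spec()].
#' @param C_grid increasing vector of candidate C values; defaults to
#'   [default_C_grid()].
#' @param error `"relative"` (|pred - obs| / obs, the default) or
#'   `"absolute"`.
#' @param tol tolerances.
#' @return A `calibration_curve` list: `C_grid`, per-C mean `errors`,
#'   `optimum`, and the per-strain prediction matrix.
#' @export
calibrate_C <- function(model, profiles, phenotypes, medium,
                        C_grid = NULL, error = c("relative", "absolute"),
                        tol = mri_tolerances()) {
  error <- match.arg(error)
  model <- convert_model(model)
  model <- apply_medium(model, medium)
  strains <- intersect(names(profiles),
                       phenotypes$strain[!is.na(phenotypes$growth_rate)])
  if (length(strains) == 0)
    stop_mri("no strains with measured growth rate")
  if (is.null(C_grid)) C_grid <- default_C_grid(model, profiles[strains])
  C_grid <- sort(as.numeric(C_grid))
  if (length(C_grid) == 0) stop_mri("empty C grid")
  mu_exp <- phenotypes$growth_rate[match(strains, phenotypes$strain)]

  probs <- list()
  for (C in C_grid)
    for (s in strains)
      probs[[length(probs) + 1L]] <-
        build_growth_problem(model, profiles[[s]], C, tol)$milp
  res <- solve_milp_batch(probs)
  mu_pred <- matrix(vapply(res, function(r) {
    if (r$status != "optimal")
      stop_mri("growth prediction failed with status '", r$status, "'")
    r$objective
  }, 0), nrow = length(strains),
    dimnames = list(strains, signif(C_grid, 6)))

  errs <- apply(mu_pred, 2, function(mp)
    if (error == "relative") mean(abs(mp - mu_exp) / mu_exp)
    else mean(abs(mp - mu_exp)))
  structure(list(C_grid = C_grid, errors = unname(errs),
                 optimum = C_grid[which.min(errs)],
                 predictions = mu_pred, strains = strains,
                 error_type = error),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("calibration_curve: ", length(x$C_grid), " C values, optimum C = ",
      signif(x$optimum, 6), " (mean ", x$error_type, " error ",
      signif(min(x$errors), 4), ")\n", sep = "")
  invisible(x)
}
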