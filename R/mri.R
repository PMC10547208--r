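# Assembly and solution of the adaptation-score MILP.
#
# For each measured gene j mapped to converted reactions K_j the
# expression-usage constraint
#     sum_{i in K_j} v_i + alpha_j = E_j * C
# holds, with usage slack alpha_j >= 0. A binary z_j with the big-M row
# alpha_j - U_j z_j <= 0 (U_j = E_j * C, the tightest valid constant)
# indicates whether gene j's expression is fully converted to flux
# (z_j = 0). Minimizing sum(z) and subtracting from P, the number of
# mapped measured genes, gives the adaptation score. Per reversible source
# reaction, binaries w_f, w_b with w_f + w_b = 1 and v <= 1000 w forbid
# simultaneous forward/backward flux, which would otherwise inflate the
# score through futile cycles.

#' Define a growth medium
#'
#' The unlimited-condition medium: the listed exchange reactions may be
#' consumed at up to 1000 mmol/gDCW/h, every other exchange is closed for
#' uptake, and all exchanges may secrete at up to 1000 mmol/gDCW/h.
#'
#' @param unlimited character vector of exchange reaction identifiers open
#'   for uptake (carbon source plus minimal-medium components such as
#'   ammonium, water, oxygen, phosphate, sulfur and proton exchanges).
#' @param carbon_source the carbon source exchange; must be listed in
#'   `unlimited`.
#' @param max_rate universal exchange flux cap (mmol/gDCW/h).
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(unlimited, carbon_source = unlimited[1],
                        max_rate = 1000) {
  unlimited <- unique(as.character(unlimited))
  if (!carbon_source %in% unlimited)
    stop_mri("carbon_source '", carbon_source, "' must be in `unlimited`")
  structure(list(unlimited = unlimited, carbon_source = carbon_source,
                 max_rate = max_rate), class = "medium_spec")
}

#' Apply a medium to a converted model
#'
#' Sets exchange bounds on the irreversible model: converted exchange
#' copies that import their metabolite get upper bound `max_rate` if their
#' source exchange is in the medium's unlimited set and 0 otherwise;
#' exporting copies get upper bound `max_rate`.
#'
#' @param model an `irreversible_model`.
#' @param medium a [medium_spec()].
#' @return The model with medium bounds applied.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "irreversible_model"),
            inherits(medium, "medium_spec"))
  exch <- which(model$exchange)
  exch_src <- unique(model$origin$source[exch])
  missing <- setdiff(medium$unlimited, exch_src)
  if (length(missing)) {
    near <- unlist(lapply(missing, function(x)
      utils::head(agrep(x, exch_src, max.distance = 0.3, value = TRUE), 3)))
    stop_mri("exchange(s) not in model: ",
             paste(missing, collapse = ", "),
             if (length(near)) paste0(" (near matches: ",
                                      paste(unique(near), collapse = ", "),
                                      ")") else "")
  }
  for (k in exch) {
    coef <- model$S[, k]
    nz <- which(coef != 0)
    importing <- length(nz) == 0 || coef[nz[1]] > 0
    src <- model$origin$source[k]
    model$ub[k] <- if (!importing) medium$max_rate
      else if (src %in% medium$unlimited) medium$max_rate else 0
    model$lb[k] <- min(model$lb[k], model$ub[k])
  }
  model
}

# ---- problem assembly ------------------------------------------------------

#' Assemble the adaptation-score MILP
#'
#' Builds the full mixed-integer program for one strain: steady-state rows
#' `S v = 0`, one expression-usage equality and one big-M indicator row
#' per mapped measured gene, and direction-exclusivity rows per reversible
#' source reaction. The objective is `min sum(z)`.
#'
#' @param model an `irreversible_model`, medium already applied.
#' @param profile an `expression_profile` for the strain.
#' @param C expression-to-flux conversion constant (mmol/gDCW/h per
#'   expression unit).
#' @param tol tolerances from [mri_tolerances()].
#' @param exclusivity_big_m big-M for the direction rows; fluxes are capped
#'   at 1000 by the model bounds, so 1000 is valid and tight.
#' @return An object of class `mri_problem`.
#' @export
build_mri_problem <- function(model, profile, C, tol = mri_tolerances(),
                              exclusivity_big_m = 1000) {
  stopifnot(inherits(model, "irreversible_model"), C >= 0)
  if (is.null(model$mapped_genes) ||
      !setequal(model$mapped_genes,
                intersect(model$genes, names(profile$values))))
    model <- build_gene_map(model, profile)
  genes <- model$mapped_genes
  P <- model$P
  E <- unname(profile$values[genes])
  U <- E * C
  if (any(U < tol$feasibility) && C > 0)
    warn_mri(sum(U < tol$feasibility), " gene(s) have expression capacity ",
             "E_j*C below the feasibility tolerance; their usage ",
             "constraints are still built")
  nv <- length(model$rxn_ids)
  R <- length(model$opposite_pairs)
  v_idx <- seq_len(nv)
  a_idx <- nv + seq_len(P)
  z_idx <- nv + P + seq_len(P)
  wf_idx <- nv + 2L * P + 2L * seq_len(R) - 1L
  wb_idx <- wf_idx + 1L
  ntot <- nv + 2L * P + 2L * R

  St <- methods::as(methods::as(model$S, "generalMatrix"), "TsparseMatrix")
  m <- length(model$met_ids)
  ti <- St@i; tj <- St@j; tx <- St@x           # S v = b rows (0-based later)
  rlb <- model$b; rub <- model$b
  row <- m

  # Eq (2): sum_{K_j} v + alpha_j = E_j * C
  for (j in seq_len(P)) {
    K <- model$gene_map[[genes[j]]]
    ti <- c(ti, rep(row, length(K) + 1L))
    tj <- c(tj, K - 1L, a_idx[j] - 1L)
    tx <- c(tx, rep(1, length(K) + 1L))
    rlb <- c(rlb, U[j]); rub <- c(rub, U[j])
    row <- row + 1L
  }
  # Eq (3): alpha_j - U_j z_j <= 0
  for (j in seq_len(P)) {
    ti <- c(ti, row, row)
    tj <- c(tj, a_idx[j] - 1L, z_idx[j] - 1L)
    tx <- c(tx, 1, -U[j])
    rlb <- c(rlb, -Inf); rub <- c(rub, 0)
    row <- row + 1L
  }
  # Eqs (5)-(7) per reversible source reaction
  for (r in seq_len(R)) {
    pr <- model$opposite_pairs[[r]]
    for (i in pr$fwd) {
      ti <- c(ti, row, row); tj <- c(tj, i - 1L, wf_idx[r] - 1L)
      tx <- c(tx, 1, -exclusivity_big_m)
      rlb <- c(rlb, -Inf); rub <- c(rub, 0); row <- row + 1L
    }
    for (i in pr$bwd) {
      ti <- c(ti, row, row); tj <- c(tj, i - 1L, wb_idx[r] - 1L)
      tx <- c(tx, 1, -exclusivity_big_m)
      rlb <- c(rlb, -Inf); rub <- c(rub, 0); row <- row + 1L
    }
    ti <- c(ti, row, row); tj <- c(tj, wf_idx[r] - 1L, wb_idx[r] - 1L)
    tx <- c(tx, 1, 1)
    rlb <- c(rlb, 1); rub <- c(rub, 1); row <- row + 1L
  }

  A <- Matrix::sparseMatrix(i = ti + 1L, j = tj + 1L, x = tx,
                            dims = c(row, ntot))
  lb <- c(model$lb, rep(0, P), rep(0, P), rep(0, 2L * R))
  ub <- c(model$ub, U, rep(1, P), rep(1, 2L * R))
  integer <- c(rep(FALSE, nv + P), rep(TRUE, P + 2L * R))
  obj <- c(rep(0, nv + P), rep(1, P), rep(0, 2L * R))
  milp <- milp_problem(obj, A, rlb, rub, lb, ub, integer, maximize = FALSE)

  structure(list(model = model, strain = profile$strain, C = C,
                 genes = genes, E = stats::setNames(E, genes), P = P,
                 tol = tol, exclusivity_big_m = exclusivity_big_m,
                 n_flux = nv, n_pairs = R,
                 v_idx = v_idx, alpha_idx = a_idx, z_idx = z_idx,
                 wf_idx = wf_idx, wb_idx = wb_idx, milp = milp),
            class = "mri_problem")
}

#' @export
print.mri_problem <- function(x, ...) {
  cat("mri_problem (strain ", x$strain, ", C = ", x$C, "): ",
      x$n_flux, " fluxes, ", x$P, " alpha, ", x$P, " z binaries, ",
      2L * x$n_pairs, " w binaries\n", sep = "")
  invisible(x)
}

result_from_solution <- function(problem, res, target = NULL,
                                 target_optimum = NULL) {
  if (res$status == "limit")
    stop_mri("MILP solver hit its time limit; best bound ", res$bound)
  if (res$status != "optimal")
    stop_mri("MILP solver returned status '", res$status,
             "' (an assembled problem with b = 0 is always feasible)")
  z <- res$x[problem$z_idx]
  score <- problem$P - as.integer(round(res$objective))
  structure(list(strain = problem$strain, C = problem$C, P = problem$P,
                 score = score,
                 fully_used_genes = problem$genes[z < 0.5],
                 alpha_values = stats::setNames(res$x[problem$alpha_idx],
                                                problem$genes),
                 witness_flux = stats::setNames(res$x[problem$v_idx],
                                                problem$model$rxn_ids),
                 witness_z = stats::setNames(z, problem$genes),
                 solver_status = res$status,
                 objective_bound = res$bound,
                 target = target, target_optimum = target_optimum),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat("adaptation_result: strain ", x$strain, ", score ", x$score, " / P = ",
      x$P, if (!is.null(x$target))
        paste0(" (conditional on ", x$target, " at ",
               signif(x$target_optimum, 6), ")"), "\n", sep = "")
  invisible(x)
}

#' Solve for the adaptation score
#'
#' Minimizes the number of genes whose expression is not fully converted
#' to flux and returns the score `P - min sum(z)` together with one
#' optimal witness (usage flags, slacks, flux vector).
#'
#' @param problem an [build_mri_problem()] object.
#' @return An `adaptation_result`.
#' @export
solve_adaptation_score <- function(problem) {
  stopifnot(inherits(problem, "mri_problem"))
  result_from_solution(problem, solve_milp(problem$milp))
}

target_columns <- function(problem, target) {
  model <- problem$model
  if (target %in% problem$genes || target %in% model$genes) {
    if (!target %in% names(model$gene_map))
      stop_mri("gene '", target, "' not mapped to any reaction")
    return(model$gene_map[[target]])
  }
  cols <- which(model$origin$source == target)
  if (length(cols) == 0) cols <- which(model$rxn_ids == target)
  if (length(cols) == 0)
    stop_mri("target '", target, "' is neither a gene nor a reaction of ",
             "the model")
  cols
}

# stage 1 of conditional scoring: maximize the target's usage over the
# continuous relaxation with direction exclusivity still binary
conditional_stage1_milp <- function(problem, cols) {
  p <- problem$milp
  p$obj <- numeric(length(p$obj))
  p$obj[cols] <- 1
  p$maximize <- TRUE
  p$integer[problem$z_idx] <- FALSE   # relax z; keep w binary
  p
}

conditional_stage2_milp <- function(problem, cols, opt) {
  base <- problem$milp
  d <- problem$tol$zero * max(1, abs(opt))
  extra <- Matrix::sparseMatrix(i = rep(1L, length(cols)), j = cols, x = 1,
                                dims = c(1L, length(base$obj)))
  base$A <- rbind(base$A, extra)
  base$rlb <- c(base$rlb, opt - d)
  base$rub <- c(base$rub, opt + d)
  base
}

#' Conditional adaptation score
#'
#' Two-stage computation of the score under maximal use of a target: first
#' the target usage (total flux through the target reaction's converted
#' copies, or through K_j for a gene target) is maximized over the
#' continuous relaxation with direction exclusivity enforced; then the
#' usage is fixed at that optimum (equality within tolerance) and
#' `min sum(z)` is re-solved.
#'
#' @param problem an `mri_problem`.
#' @param target a reaction identifier (source reaction of the unconverted
#'   model) or gene identifier.
#' @return An `adaptation_result` with `target` and `target_optimum` set;
#'   its score never exceeds the unconditional score.
#' @export
conditional_adaptation_score <- function(problem, target) {
  stopifnot(inherits(problem, "mri_problem"))
  cols <- target_columns(problem, target)
  r1 <- solve_milp(conditional_stage1_milp(problem, cols))
  if (r1$status != "optimal")
    stop_mri("stage-1 maximization failed with status '", r1$status, "'")
  opt <- r1$objective
  if (opt < problem$tol$zero)
    warn_mri("maximum usage of target '", target, "' is 0; the ",
             "conditional score equals a vacuous condition")
  result_from_solution(problem,
                       solve_milp(conditional_stage2_milp(problem, cols, opt)),
                       target = target, target_optimum = opt)
}

#' Optimality-preserving fully-used gene set
#'
#' The set of genes j for which some optimal solution uses j fully: gene j
#' belongs to the set iff forcing `z_j = 0` preserves the optimal score.
#' This is a superset of any single witness's `fully_used_genes` and is
#' reproducible across solvers, unlike the witness, which is one optimum
#' among possibly many.
#'
#' @param problem an `mri_problem`.
#' @param result the corresponding `adaptation_result`; computed if `NULL`.
#' @return Character vector of gene identifiers.
#' @export
full_usage_gene_set <- function(problem, result = NULL) {
  stopifnot(inherits(problem, "mri_problem"))
  if (is.null(result)) result <- solve_adaptation_score(problem)
  candidates <- setdiff(problem$genes, result$fully_used_genes)
  if (length(candidates) == 0) return(sort(result$fully_used_genes))
  probs <- lapply(candidates, function(g) {
    p <- problem$milp
    p$ub[problem$z_idx[match(g, problem$genes)]] <- 0
    p
  })
  res <- solve_milp_batch(probs)
  keep <- vapply(seq_along(candidates), function(k) {
    r <- res[[k]]
    r$status == "optimal" &&
      as.integer(round(r$objective)) == problem$P - result$score
  }, TRUE)
  sort(union(result$fully_used_genes, candidates[keep]))
}

#' Check an adaptation witness against the problem invariants
#'
#' Verifies, within tolerance: the expression-usage equalities, the bounds
#' `0 <= alpha_j <= E_j C`, that no opposite-direction pair carries flux on
#' both sides, that fully used genes have zero slack, and
#' `0 <= score <= P`.
#'
#' @param problem an `mri_problem`.
#' @param result an `adaptation_result` for it.
#' @param tol tolerance multiplier on the problem's zero tolerance.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
check_adaptation_witness <- function(problem, result, tol = 10) {
  eps <- tol * problem$tol$zero
  v <- result$witness_flux; a <- result$alpha_values
  for (j in seq_len(problem$P)) {
    K <- problem$model$gene_map[[problem$genes[j]]]
    lhs <- sum(v[K]) + a[j]
    if (abs(lhs - problem$E[j] * problem$C) > eps * max(1, problem$E[j] * problem$C))
      stop_mri("usage constraint violated for gene ", problem$genes[j])
  }
  if (any(a < -eps) || any(a > problem$E * problem$C + eps *
                           pmax(1, problem$E * problem$C)))
    stop_mri("alpha out of [0, E_j*C]")
  for (pr in problem$model$opposite_pairs) {
    if (min(sum(v[pr$fwd]), sum(v[pr$bwd])) > eps * problem$exclusivity_big_m)
      stop_mri("opposite-direction pair '", pr$source,
               "' active in both directions")
  }
  au <- a[match(result$fully_used_genes, problem$genes)]
  if (length(au) && any(au > eps * pmax(1, problem$E[result$fully_used_genes] *
                                          problem$C)))
    stop_mri("fully-used gene with nonzero alpha")
  if (result$score < 0 || result$score > problem$P)
    stop_mri("score out of [0, P]")
  invisible(TRUE)
}
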