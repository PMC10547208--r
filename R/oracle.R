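# Exhaustive-enumeration oracle for the adaptation score. For every
# subset G of mapped measured genes it asks, by LP feasibility, whether
# all genes in G can simultaneously have zero usage slack; the score is
# the size of the largest feasible subset. Direction exclusivity is
# handled by enumerating the orientation of every reversible source
# reaction. Feasibility is decided with quadprog (min ||v||^2 subject to
# the constraint system; the Goldfarb-Idnani method reports inconsistent
# constraints), a route fully independent of the MILP solver it is used
# to validate.

ORACLE_MAX_GENES <- 12L

# Feasibility of: S v = 0, lb <= v <= ub (with `off` columns closed),
# sum_{K_j} v = E_j C for j in G, <= for the other mapped genes, plus an
# optional linear row  sum(v[target]) >= target_min.
oracle_feasible <- function(model, E, C, G, closed, target_cols = NULL,
                            target_min = NULL, tol = 1e-6) {
  ub <- model$ub
  ub[closed] <- 0
  keep <- which(ub > 0 | model$lb > 0)
  if (length(keep) == 0) {
    # only the all-zero flux remains: feasible iff G demands nothing
    need <- vapply(G, function(g) E[[g]] * C, 0)
    return(all(need <= tol) &&
             (is.null(target_min) || target_min <= tol))
  }
  nk <- length(keep)
  Sk <- as.matrix(model$S[, keep, drop = FALSE])
  kmap <- function(idx) match(intersect(idx, keep), keep)

  Aeq <- Sk; beq <- model$b
  for (g in G) {
    row <- numeric(nk)
    row[kmap(model$gene_map[[g]])] <- 1
    Aeq <- rbind(Aeq, row); beq <- c(beq, E[[g]] * C)
  }
  Ain <- rbind(diag(nk), -diag(nk))        # v >= lb, -v >= -ub
  bin <- c(model$lb[keep], -ub[keep])
  for (g in setdiff(names(E), G)) {
    row <- numeric(nk)
    cols <- kmap(model$gene_map[[g]])
    if (length(cols) == 0) next
    row[cols] <- -1
    Ain <- rbind(Ain, row); bin <- c(bin, -E[[g]] * C)
  }
  if (!is.null(target_cols)) {
    row <- numeric(nk)
    row[kmap(target_cols)] <- 1
    Ain <- rbind(Ain, row); bin <- c(bin, target_min)
  }
  ok <- tryCatch({
    quadprog::solve.QP(Dmat = diag(nk), dvec = numeric(nk),
                       Amat = t(rbind(Aeq, Ain)), bvec = c(beq, bin),
                       meq = nrow(Aeq))
    TRUE
  }, error = function(e) FALSE)
  ok
}

# All orientation assignments of the reversible source reactions, as a
# list of "closed column" index vectors.
orientation_closures <- function(model) {
  pairs <- model$opposite_pairs
  if (length(pairs) == 0) return(list(integer(0)))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(pairs)))
  lapply(seq_len(nrow(grid)), function(r) {
    unlist(lapply(seq_along(pairs), function(k)
      if (grid[r, k]) pairs[[k]]$bwd else pairs[[k]]$fwd))
  })
}

oracle_subset_feasible <- function(model, E, C, G, closures,
                                   target_cols = NULL, target_min = NULL,
                                   tol = 1e-6) {
  for (cl in closures)
    if (oracle_feasible(model, E, C, G, cl, target_cols, target_min, tol))
      return(TRUE)
  FALSE
}

# Maximum attainable value of sum(v[target_cols]) under the relaxed usage
# constraints (all slacks free), found by bisection on feasibility. The
# attainable set is a union of intervals all containing zero, hence an
# interval, so bisection is exact up to `prec`.
oracle_max_target <- function(model, E, C, target_cols, closures,
                              prec = 1e-7) {
  hi <- sum(model$ub[target_cols])
  if (!oracle_subset_feasible(model, E, C, character(0), closures,
                              target_cols, 0))
    stop_mri("oracle: even zero target flux infeasible")
  lo <- 0
  while (hi - lo > prec * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (oracle_subset_feasible(model, E, C, character(0), closures,
                               target_cols, mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Brute-force adaptation score by subset enumeration
#'
#' Independent oracle for validating the MILP: enumerates gene subsets in
#' decreasing size, testing by LP feasibility whether every gene of the
#' subset can have zero usage slack simultaneously (enumerating reversible
#' reaction orientations for direction exclusivity). Returns the score,
#' all optimal usage patterns, and the full antichain of maximal feasible
#' subsets. Only practical for small instances.
#'
#' @param model a `stoich_model` or converted `irreversible_model`.
#' @param profile an `expression_profile`.
#' @param C conversion constant.
#' @param medium optional [medium_spec()] applied before scoring.
#' @param fixed_target optional gene or reaction identifier whose usage is
#'   fixed at its maximum attainable value before scoring.
#' @param tol feasibility tolerance.
#' @return A list with `score`, `P`, `optimal_patterns` (list of character
#'   vectors), `maximal_patterns`, and for a fixed target `target_max`.
#' @export
brute_force_adaptation_score <- function(model, profile, C, medium = NULL,
                                         fixed_target = NULL, tol = 1e-6) {
  model <- convert_model(model)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  model <- build_gene_map(model, profile)
  genes <- model$mapped_genes
  P <- length(genes)
  if (P > ORACLE_MAX_GENES)
    stop_mri("oracle limited to ", ORACLE_MAX_GENES,
             " genes (2^P enumeration); use the MILP")
  E <- as.list(profile$values[genes])
  closures <- orientation_closures(model)

  target_cols <- NULL; target_min <- NULL; target_max <- NULL
  if (!is.null(fixed_target)) {
    target_cols <- if (fixed_target %in% genes)
      model$gene_map[[fixed_target]]
    else which(model$origin$source == fixed_target |
                 model$rxn_ids == fixed_target)
    if (length(target_cols) == 0)
      stop_mri("fixed target '", fixed_target, "' not in model")
    target_max <- oracle_max_target(model, E, C, target_cols, closures)
    target_min <- target_max - tol * max(1, target_max)
  }

  maximal <- list()
  best <- -1L
  for (k in P:0) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(genes, k, simplify = FALSE)
    for (G in subsets) {
      dominated <- any(vapply(maximal, function(M) all(G %in% M), TRUE))
      if (dominated) next
      if (oracle_subset_feasible(model, E, C, G, closures,
                                 target_cols, target_min, tol)) {
        maximal[[length(maximal) + 1L]] <- G
        if (best < 0L) best <- k
      }
    }
    if (k == 0 && best < 0L) best <- 0L
  }
  sizes <- vapply(maximal, length, 0L)
  list(score = best, P = P,
       optimal_patterns = maximal[sizes == best],
       maximal_patterns = maximal,
       target_max = target_max)
}

#' Agreement study: MILP score versus brute-force oracle
#'
#' Generates one random fixture per seed ([random_toy_spec()]), scores its
#' wild-type profile at each C value with the MILP (solved in one batch),
#' re-scores with the enumeration oracle, and tabulates both. Used to
#' validate the solver route on many instances at once.
#'
#' @param seeds integer vector of fixture seeds.
#' @param C_values conversion constants swept per fixture.
#' @return A data frame with one row per (seed, C): `P`, `n_converted`,
#'   `score_milp`, `score_oracle`. The assembled problems and MILP results
#'   are attached as attributes `problems` and `results` for further
#'   invariant checking.
#' @export
oracle_milp_agreement <- function(seeds, C_values = c(0.5, 1, 5)) {
  problems <- list(); meta <- list()
  for (s in seeds) {
    spec <- random_toy_spec(s)
    model <- make_toy_model(spec)
    conv <- apply_medium(convert_model(model), medium_spec(spec$medium))
    wt <- expression_profile("WT", spec$wt_expr)
    for (C in C_values) {
      problems[[length(problems) + 1L]] <-
        suppressWarnings(build_mri_problem(conv, wt, C))
      meta[[length(meta) + 1L]] <-
        list(seed = s, C = C, model = model, profile = wt,
             medium = medium_spec(spec$medium))
    }
  }
  res <- solve_milp_batch(lapply(problems, `[[`, "milp"))
  rows <- lapply(seq_along(problems), function(k) {
    pr <- problems[[k]]; mt <- meta[[k]]
    milp_score <- pr$P - as.integer(round(res[[k]]$objective))
    orc <- brute_force_adaptation_score(mt$model, mt$profile, mt$C,
                                        medium = mt$medium)
    data.frame(seed = mt$seed, C = mt$C, P = pr$P,
               n_converted = pr$n_flux,
               score_milp = milp_score, score_oracle = orc$score)
  })
  out <- do.call(rbind, rows)
  attr(out, "problems") <- problems
  attr(out, "results") <- res
  out
}
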