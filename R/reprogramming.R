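# Key-gene identification and downstream analyses for wild-type vs
# evolved strain comparisons: expression-difference ranking of the
# wild-type's fully used genes, Pearson correlation of conditional scores
# with measured phenotypes, usage-set comparison, and score ratios.

#' Identify candidate key genes of a reprogramming event
#'
#' Two-factor selection: restrict to genes whose expression the wild type
#' converts fully into flux under the unlimited condition, then rank by
#' the absolute difference between wild-type expression and the mean
#' expression of the evolved strains (on the input scale). Genes at the
#' top of the ranking are the candidates for having changed their role in
#' metabolism during adaptive evolution.
#'
#' @param wt_fully_used either an `adaptation_result` for the wild type
#'   under the unlimited condition (its witness `fully_used_genes` is
#'   used) or a character vector of gene identifiers — e.g. the
#'   solver-independent set from [full_usage_gene_set()], which is the
#'   recommended, reproducible choice.
#' @param wt_profile wild-type `expression_profile`.
#' @param evolved_profiles list of evolved `expression_profile`s.
#' @param top_k number of top-ranked genes to flag as selected.
#' @param min_delta selection additionally requires an expression
#'   difference strictly greater than this (default 0, so unchanged genes
#'   are never selected).
#' @return A `key_gene_table` data frame sorted by rank, with columns
#'   `gene`, `e_wt`, `e_evolved_mean`, `delta_expression`, `rank`,
#'   `selected`, and the diagnostic `wt_extreme` (is the wild-type level
#'   the minimum or maximum across all strains, as expected for a genuine
#'   reprogramming candidate).
#' @export
identify_key_genes <- function(wt_fully_used, wt_profile, evolved_profiles,
                               top_k = 2L, min_delta = 0) {
  genes <- if (inherits(wt_fully_used, "adaptation_result"))
    wt_fully_used$fully_used_genes else as.character(wt_fully_used)
  stopifnot(inherits(wt_profile, "expression_profile"),
            length(evolved_profiles) >= 1)
  evo_mat <- NULL
  keep <- genes
  for (p in evolved_profiles) {
    absent <- setdiff(keep, names(p$values))
    if (length(absent)) {
      warn_mri("gene(s) missing from evolved profile '", p$strain,
               "' excluded: ", paste(absent, collapse = ", "))
      keep <- setdiff(keep, absent)
    }
  }
  keep <- intersect(keep, names(wt_profile$values))
  if (length(keep) == 0)
    return(structure(data.frame(gene = character(0)),
                     class = c("key_gene_table", "data.frame")))
  evo_mat <- vapply(evolved_profiles, function(p) p$values[keep],
                    numeric(length(keep)))
  evo_mat <- matrix(evo_mat, nrow = length(keep))
  e_wt <- unname(wt_profile$values[keep])
  e_evo <- rowMeans(evo_mat)
  delta <- abs(e_wt - e_evo)
  ord <- order(-delta, keep)    # descending delta, ties lexicographic
  tab <- data.frame(gene = keep[ord], e_wt = e_wt[ord],
                    e_evolved_mean = e_evo[ord],
                    delta_expression = delta[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  tab$selected <- tab$rank <= top_k & tab$delta_expression > min_delta
  lo <- pmin(e_wt, apply(evo_mat, 1, min))[ord]
  hi <- pmax(e_wt, apply(evo_mat, 1, max))[ord]
  tab$wt_extreme <- tab$e_wt <= lo | tab$e_wt >= hi
  class(tab) <- c("key_gene_table", "data.frame")
  tab
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r between paired observations, with the two-sided
#' p-value from the t distribution on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param quantity label for the phenotype being correlated.
#' @return A `correlation_report` list: `quantity`, `n`, `pearson_r`,
#'   `p_value`, and the paired values.
#' @export
pearson_correlation <- function(x, y, quantity = "phenotype") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_mri("x and y must have equal length")
  if (length(x) < 3) stop_mri("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_mri("zero variance in input vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(quantity = quantity, n = length(x),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, x = x, y = y),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("correlation_report (", x$quantity, "): r = ",
      signif(x$pearson_r, 4), ", p = ", signif(x$p_value, 4),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Compare fully-used gene sets across strains
#'
#' Counts every region of the Venn partition of 2-4 gene sets (which
#' strains share which fully used genes). Region names list the member
#' strains joined by `&`.
#'
#' @param sets named list (2-4 entries) of character vectors.
#' @return Named integer vector of region counts; the counts sum to the
#'   size of the union.
#' @export
compare_usage_sets <- function(sets) {
  k <- length(sets)
  if (k < 2) stop_mri("need at least 2 sets")
  if (k > 4) stop_mri("more than 4 sets: compute a pairwise intersection ",
                      "matrix instead")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- table(key)
  out <- stats::setNames(as.integer(regions), names(regions))
  out
}

#' Ratio of two adaptation scores
#'
#' E.g. the carbon-source conditional score divided by a key gene's
#' conditional score; a drop in this ratio after evolution indicates more
#' efficient substrate use per unit of the key gene's activity.
#'
#' @param numerator,denominator `adaptation_result` objects.
#' @return `numerator$score / denominator$score`.
#' @export
adaptation_score_ratio <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "adaptation_result"),
            inherits(denominator, "adaptation_result"))
  if (denominator$score <= 0)
    stop_mri("denominator adaptation score is 0")
  numerator$score / denominator$score
}

#' Run the full reprogramming analysis
#'
#' End-to-end pipeline: per-strain unconditional adaptation scores under
#' the unlimited condition; wild-type full-usage set; key-gene table;
#' conditional scores per key gene per strain; Pearson correlations of
#' each key gene's conditional scores against each supplied phenotype;
#' usage-set comparison under the top key gene's condition; and the
#' carbon-source / key-gene score ratio per strain.
#'
#' @param model a `stoich_model` or converted `irreversible_model`.
#' @param profiles named list of `expression_profile`s; the entry named by
#'   `wt_strain` is the wild type, all others are evolved strains.
#' @param phenotypes optional `phenotype_table`; if `NULL` the correlation
#'   stage is flagged "not computed".
#' @param medium a [medium_spec()].
#' @param C conversion constant (see [calibrate_C()]).
#' @param wt_strain name of the wild-type profile.
#' @param top_k number of key genes to carry into conditional scoring.
#' @param use_witness_sets if `TRUE`, mimic single-witness key-gene
#'   selection instead of the optimality-preserving set.
#' @param tol tolerances from [mri_tolerances()].
#' @return An `mri_report` list bundling every stage's output.
#' @export
run_full_analysis <- function(model, profiles, phenotypes = NULL, medium,
                              C, wt_strain = "WT", top_k = 2L,
                              use_witness_sets = FALSE,
                              tol = mri_tolerances()) {
  stopifnot(wt_strain %in% names(profiles))
  model <- convert_model(model)
  model <- apply_medium(model, medium)

  problems <- lapply(profiles, function(p)
    build_mri_problem(model, p, C, tol = tol))
  unconditional <- lapply(problems, solve_adaptation_score)

  wt_set <- if (use_witness_sets)
    unconditional[[wt_strain]]$fully_used_genes
  else full_usage_gene_set(problems[[wt_strain]], unconditional[[wt_strain]])

  evolved <- profiles[setdiff(names(profiles), wt_strain)]
  key_genes <- identify_key_genes(wt_set, profiles[[wt_strain]], evolved,
                                  top_k = top_k)
  selected <- key_genes$gene[key_genes$selected]

  conditional <- list()
  for (g in selected)
    conditional[[g]] <- lapply(problems, conditional_adaptation_score,
                               target = g)

  correlations <- NULL
  if (!is.null(phenotypes) && length(selected)) {
    correlations <- list()
    for (g in selected) {
      scores <- vapply(conditional[[g]], `[[`, 0, "score")
      idx <- match(names(scores), phenotypes$strain)
      for (q in intersect(colnames(phenotypes), phenotype_columns)) {
        vals <- phenotypes[[q]][idx]
        ok <- !is.na(vals)
        if (sum(ok) >= 3 && stats::sd(scores[ok]) > 0 &&
            stats::sd(vals[ok]) > 0)
          correlations[[paste(g, q, sep = ".")]] <-
            pearson_correlation(scores[ok], vals[ok], quantity = q)
      }
    }
  }

  usage_comparison <- NULL
  if (length(selected)) {
    cond_sets <- lapply(conditional[[selected[1]]], `[[`, "fully_used_genes")
    usage_comparison <- if (length(cond_sets) <= 4)
      compare_usage_sets(cond_sets)
    else {
      nm <- names(cond_sets)
      outer(nm, nm, Vectorize(function(a, b)
        length(intersect(cond_sets[[a]], cond_sets[[b]]))))
    }
  }

  ratios <- NULL
  if (length(selected)) {
    carbon_cond <- lapply(problems, conditional_adaptation_score,
                          target = medium$carbon_source)
    ratios <- vapply(names(problems), function(s)
      adaptation_score_ratio(carbon_cond[[s]], conditional[[selected[1]]][[s]]),
      0)
  }

  structure(list(C = C, medium = medium, wt_strain = wt_strain,
                 unconditional = unconditional,
                 wt_full_usage_set = wt_set,
                 key_genes = key_genes,
                 conditional = conditional,
                 correlations = correlations %||% "not computed",
                 usage_comparison = usage_comparison,
                 score_ratios = ratios),
            class = "mri_report")
}
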