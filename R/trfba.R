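# Conversion of a stoichiometric model to the irreversible, without-OR form
# required for expression-usage constraints: every reversible reaction is
# split into forward/backward columns, every OR rule is expanded into
# isozyme copies carrying a single AND conjunct, and the gene -> reaction
# index map K_j is built. Opposite-direction copies of the same source
# reaction are registered so direction-exclusivity constraints can forbid
# futile forward+backward cycles.

new_irreversible_model <- function(base, origin, opposite_pairs,
                                   rule_conjuncts, gene_map = NULL) {
  structure(list(met_ids = base$met_ids, rxn_ids = base$rxn_ids, S = base$S,
                 lb = base$lb, ub = base$ub, obj = base$obj, b = base$b,
                 rule_conjuncts = rule_conjuncts,
                 genes = sort(unique(unlist(rule_conjuncts))),
                 exchange = base$exchange, biomass = base$biomass,
                 origin = origin, opposite_pairs = opposite_pairs,
                 gene_map = gene_map),
            class = "irreversible_model")
}

#' @export
print.irreversible_model <- function(x, ...) {
  cat("irreversible_model:", length(x$met_ids), "metabolites,",
      length(x$rxn_ids), "converted reactions,",
      length(x$opposite_pairs), "opposite-direction pair group(s),",
      length(x$genes), "genes\n")
  invisible(x)
}

#' Split reversible reactions
#'
#' Each reaction with a negative lower bound becomes a forward copy (the
#' original column, bounds `[0, ub]`) and a backward copy (the negated
#' column, bounds `[0, -lb]`); irreversible reactions pass through. A
#' reaction with `lb < 0` and `ub <= 0` is first normalized by flipping its
#' direction. Each reversible source reaction is registered as an
#' opposite-direction pair.
#'
#' @param model a [stoich_model()].
#' @return An `irreversible_model` whose gene rules are still unparsed OR
#'   trees; see [expand_gpr_without_or()].
#' @export
split_reversible <- function(model) {
  if (inherits(model, "irreversible_model")) return(model)
  stopifnot(inherits(model, "stoich_model"))
  S <- model$S
  cols <- list(); ids <- character(0); lb <- ub <- obj <- numeric(0)
  rules <- character(0); src <- character(0); dir <- character(0)
  pairs <- list()
  for (k in seq_along(model$rxn_ids)) {
    l <- model$lb[k]; u <- model$ub[k]; colk <- S[, k, drop = FALSE]
    rid <- model$rxn_ids[k]
    if (l < 0 && u <= 0) {      # backward-only: flip direction
      colk <- -colk; tmp <- l; l <- -u; u <- -tmp
      dir_fwd <- "bwd"
    } else dir_fwd <- "fwd"
    if (l < 0) {                # genuinely reversible: split
      cols <- c(cols, list(colk, -colk))
      ids <- c(ids, paste0(rid, "_f"), paste0(rid, "_b"))
      lb <- c(lb, 0, 0); ub <- c(ub, u, -l)
      obj <- c(obj, model$obj[k], -model$obj[k])
      rules <- c(rules, model$gene_rules[k], model$gene_rules[k])
      src <- c(src, rid, rid); dir <- c(dir, "fwd", "bwd")
      pairs[[length(pairs) + 1L]] <-
        list(source = rid, fwd = length(ids) - 1L, bwd = length(ids))
    } else {
      cols <- c(cols, list(colk))
      ids <- c(ids, rid)
      lb <- c(lb, l); ub <- c(ub, u)
      obj <- c(obj, if (dir_fwd == "bwd") -model$obj[k] else model$obj[k])
      rules <- c(rules, model$gene_rules[k])
      src <- c(src, rid); dir <- c(dir, dir_fwd)
    }
  }
  S2 <- do.call(cbind, cols)
  base <- list(met_ids = model$met_ids, rxn_ids = ids, S = S2,
               lb = lb, ub = ub, obj = obj, b = model$b,
               exchange = as.logical(Matrix::colSums(S2 != 0) <= 1),
               biomass = model$biomass)
  origin <- data.frame(source = src, direction = dir,
                       isozyme = 1L, stringsAsFactors = FALSE)
  m <- new_irreversible_model(base, origin, pairs,
                              rule_conjuncts = lapply(rules, gpr_genes))
  m$gene_rules <- rules   # raw rule text, consumed by expand_gpr_without_or
  m
}

#' Expand OR rules into isozyme reaction copies
#'
#' Rewrites every gene rule in disjunctive normal form; a reaction whose
#' rule has k disjuncts becomes k identical columns, each carrying one AND
#' conjunct. Opposite-direction registrations are regrouped per source
#' reaction so that every forward copy opposes all backward copies.
#'
#' @param model output of [split_reversible()].
#' @param dnf_cap maximum number of disjuncts per reaction; deeper rules
#'   abort with an error rather than silently truncating.
#' @return An `irreversible_model` in without-OR form: every converted
#'   reaction carries a single conjunct (possibly empty) of genes.
#' @export
expand_gpr_without_or <- function(model, dnf_cap = 32L) {
  stopifnot(inherits(model, "irreversible_model"))
  rules <- model$gene_rules
  if (is.null(rules)) return(model)   # already expanded
  cols <- list(); ids <- character(0); lb <- ub <- obj <- numeric(0)
  conj <- list(); src <- character(0); dir <- character(0); iso <- integer(0)
  for (k in seq_along(model$rxn_ids)) {
    tree <- gpr_parse(rules[k])
    disj <- gpr_dnf(tree, cap = dnf_cap, rule_text = rules[k])
    if (length(disj) == 0) disj <- list(character(0))
    for (d in seq_along(disj)) {
      cols <- c(cols, list(model$S[, k, drop = FALSE]))
      ids <- c(ids, if (length(disj) == 1) model$rxn_ids[k] else
        paste0(model$rxn_ids[k], "_iso", d))
      lb <- c(lb, model$lb[k]); ub <- c(ub, model$ub[k])
      obj <- c(obj, model$obj[k])
      conj <- c(conj, list(disj[[d]]))
      src <- c(src, model$origin$source[k])
      dir <- c(dir, model$origin$direction[k])
      iso <- c(iso, d)
    }
  }
  S2 <- do.call(cbind, cols)
  # regroup opposite pairs: all fwd copies vs all bwd copies per source
  rev_sources <- unique(vapply(model$opposite_pairs, `[[`, "", "source"))
  pairs <- lapply(rev_sources, function(s) {
    list(source = s,
         fwd = which(src == s & dir == "fwd"),
         bwd = which(src == s & dir == "bwd"))
  })
  base <- list(met_ids = model$met_ids, rxn_ids = ids, S = S2,
               lb = lb, ub = ub, obj = obj, b = model$b,
               exchange = as.logical(Matrix::colSums(S2 != 0) <= 1),
               biomass = model$biomass)
  origin <- data.frame(source = src, direction = dir, isozyme = iso,
                       stringsAsFactors = FALSE)
  out <- new_irreversible_model(base, origin, pairs, conj)
  out$gene_map <- gene_reaction_map(out)
  out
}

# K_j over all genes appearing in any conjunct.
gene_reaction_map <- function(model) {
  genes <- model$genes
  km <- lapply(genes, function(g)
    which(vapply(model$rule_conjuncts, function(cj) g %in% cj, TRUE)))
  stats::setNames(km, genes)
}

#' Build the gene-to-reaction map against an expression profile
#'
#' Restricts the converted model's map \eqn{K_j} to genes measured in the
#' profile. Measured genes absent from every rule are dropped with a
#' warning; P, the number of mapped measured genes, is the ceiling of the
#' adaptation score.
#'
#' @param model an `irreversible_model` in without-OR form.
#' @param profile an `expression_profile`.
#' @return `model` with `mapped_genes` (character) and `P` fields set.
#' @export
build_gene_map <- function(model, profile) {
  stopifnot(inherits(model, "irreversible_model"),
            inherits(profile, "expression_profile"))
  if (is.null(model$gene_map)) model$gene_map <- gene_reaction_map(model)
  measured <- trimws(names(profile$values))
  alien <- setdiff(measured, model$genes)
  if (length(alien))
    warn_mri(length(alien), " measured gene(s) absent from every model ",
             "rule are ignored: ",
             paste(utils::head(alien, 5), collapse = ", "),
             if (length(alien) > 5) ", ..." else "")
  model$mapped_genes <- intersect(model$genes, measured)
  model$P <- length(model$mapped_genes)
  model
}

#' Convert a model to irreversible, without-OR form
#'
#' Convenience wrapper: [split_reversible()] then
#' [expand_gpr_without_or()]. Idempotent: an already converted model is
#' returned unchanged.
#'
#' @param model a `stoich_model` or `irreversible_model`.
#' @param dnf_cap passed to [expand_gpr_without_or()].
#' @return An `irreversible_model`.
#' @export
convert_model <- function(model, dnf_cap = 32L) {
  if (inherits(model, "irreversible_model") && is.null(model$gene_rules))
    return(model)
  expand_gpr_without_or(split_reversible(model), dnf_cap = dnf_cap)
}
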