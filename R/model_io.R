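#' Construct a stoichiometric model
#'
#' The raw genome-scale model container: stoichiometric matrix, flux bounds,
#' objective coefficients, Boolean gene rules and exchange flags. Exchange
#' reactions are those with at most one nonzero stoichiometric coefficient;
#' their bounds define the growth medium.
#'
#' @param met_ids character vector of metabolite identifiers (length m).
#' @param rxn_ids character vector of reaction identifiers (length n).
#' @param S m x n stoichiometric matrix (coerced to sparse).
#' @param lb,ub per-reaction flux bounds (mmol/gDCW/h).
#' @param obj per-reaction objective coefficients; defaults to all zero.
#' @param b per-metabolite right-hand side (mmol/gDCW/h); defaults to zero
#'   (pure steady state).
#' @param gene_rules per-reaction Boolean gene association text (`""` for
#'   reactions with no gene); AND joins complex members, OR joins isozymes.
#' @param biomass identifier of the biomass reaction, or `NA`.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(met_ids, rxn_ids, S, lb, ub, obj = NULL, b = NULL,
                         gene_rules = NULL, biomass = NA_character_) {
  m <- length(met_ids); n <- length(rxn_ids)
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(S) != m || ncol(S) != n)
    stop_mri("S must be ", m, " x ", n, ", got ", nrow(S), " x ", ncol(S))
  if (anyDuplicated(met_ids)) stop_mri("duplicated metabolite identifiers")
  if (anyDuplicated(rxn_ids)) stop_mri("duplicated reaction identifiers")
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (length(lb) != n || length(ub) != n)
    stop_mri("bounds must have one entry per reaction")
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop_mri("non-finite flux bound")
  if (any(lb > ub))
    stop_mri("lower bound exceeds upper bound for reaction(s): ",
             paste(rxn_ids[lb > ub], collapse = ", "))
  obj <- if (is.null(obj)) numeric(n) else as.numeric(obj)
  b <- if (is.null(b)) numeric(m) else as.numeric(b)
  gene_rules <- if (is.null(gene_rules)) rep("", n) else as.character(gene_rules)
  stopifnot(length(obj) == n, length(b) == m, length(gene_rules) == n)
  genes <- sort(unique(unlist(lapply(gene_rules, gpr_genes))))
  exchange <- Matrix::colSums(S != 0) <= 1
  if (!is.na(biomass) && !biomass %in% rxn_ids)
    stop_mri("biomass reaction '", biomass, "' not in model")
  structure(list(met_ids = met_ids, rxn_ids = rxn_ids, S = S,
                 lb = lb, ub = ub, obj = obj, b = b,
                 gene_rules = gene_rules, genes = genes,
                 exchange = as.logical(exchange), biomass = biomass),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("stoich_model:", length(x$met_ids), "metabolites,",
      length(x$rxn_ids), "reactions,", length(x$genes), "genes,",
      sum(x$exchange), "exchanges\n")
  invisible(x)
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("expression_profile '", x$strain, "': ", length(x$values),
      " genes\n", sep = "")
  invisible(x)
}

#' Construct an expression profile
#'
#' Per-strain gene expression levels on whatever scale the platform
#' provides (log-scale microarray intensities in the motivating use
#' case). Values must be finite, non-negative and uniquely named by gene.
#'
#' @param strain strain label.
#' @param values named numeric vector, gene identifier -> expression
#'   level.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(strain, values) {
  values <- unlist(values)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop_mri("expression values must be uniquely named by gene")
  if (any(!is.finite(values)) || any(values < 0))
    stop_mri("expression values must be finite and >= 0")
  structure(list(strain = strain, values = values),
            class = "expression_profile")
}

#' Read a gene expression table
#'
#' Tab-separated, UTF-8, '.' decimal separator: first column gene
#' identifiers, one column per strain, header row of strain labels.
#' Expression values are consumed on whatever scale the table provides
#' (typically log-scale microarray intensities); the conversion constant C
#' absorbs the scale downstream.
#'
#' @param path file path.
#' @return A named list of `expression_profile` objects, one per strain.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_mri("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(tab) < 2) stop_mri("expression table needs a gene column and at ",
                              "least one strain column")
  genes <- trimws(tab[[1]])
  if (anyDuplicated(genes))
    stop_mri("duplicated gene identifier(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "),
             " (duplicates are an error, not averaged)")
  strains <- colnames(tab)[-1]
  profiles <- lapply(seq_along(strains), function(k) {
    raw <- trimws(tab[[k + 1]])
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & !(raw %in% c("", "NA")))
    if (length(bad))
      stop_mri("non-numeric expression value '", raw[bad[1]], "' at row ",
               bad[1], ", column '", strains[k], "'")
    if (anyNA(vals))
      stop_mri("missing expression value at row ", which(is.na(vals))[1],
               ", column '", strains[k], "'")
    expression_profile(strains[k], stats::setNames(vals, genes))
  })
  stats::setNames(profiles, strains)
}

#' Write a gene expression table
#'
#' Inverse of [read_expression_table()]; all profiles must cover the same
#' genes.
#'
#' @param profiles named list of `expression_profile` objects.
#' @param path output file path.
#' @export
write_expression_table <- function(profiles, path) {
  genes <- names(profiles[[1]]$values)
  df <- data.frame(gene = genes, check.names = FALSE)
  for (p in profiles) df[[p$strain]] <- unname(p$values[genes])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rename profile genes through an identifier mapping
#'
#' Expression platforms often report gene symbols (e.g. `cyoC`) while
#' models use locus tags (e.g. `b0430`). This applies a two-column
#' mapping to a profile's gene names; matching elsewhere in the package
#' is by exact (whitespace-trimmed, case-sensitive) identifier.
#'
#' @param profile an `expression_profile`.
#' @param mapping data frame (or two-column matrix) whose first column
#'   holds the profile's current identifiers and second column the model
#'   identifiers; genes absent from the mapping keep their names.
#' @return The renamed `expression_profile`.
#' @export
map_gene_identifiers <- function(profile, mapping) {
  stopifnot(inherits(profile, "expression_profile"))
  mapping <- as.data.frame(mapping)
  if (ncol(mapping) < 2) stop_mri("mapping needs two columns")
  from <- trimws(as.character(mapping[[1]]))
  to <- trimws(as.character(mapping[[2]]))
  if (anyDuplicated(from))
    stop_mri("duplicated source identifier(s) in mapping")
  nm <- names(profile$values)
  hit <- match(nm, from)
  nm[!is.na(hit)] <- to[hit[!is.na(hit)]]
  if (anyDuplicated(nm))
    stop_mri("mapping makes gene identifiers collide: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
  expression_profile(profile$strain, stats::setNames(profile$values, nm))
}

phenotype_columns <- c("growth_rate", "growth_yield", "oxygen_uptake",
                       "substrate_uptake")

#' Read a phenotype table
#'
#' Tab-separated: strains as rows (first column `strain`), measured
#' quantities as columns. Accepted quantities: `growth_rate` (1/h),
#' `growth_yield` (gDCW/mmol substrate), `oxygen_uptake` and
#' `substrate_uptake` (mmol/gDCW/h). Missing cells become `NA`, never zero.
#'
#' @param path file path.
#' @return A data frame of class `phenotype_table`, one row per strain.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop_mri("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(tab) == 0) stop_mri("no strains in phenotype table")
  cols <- colnames(tab)
  if (cols[1] != "strain")
    stop_mri("first column must be 'strain', got '", cols[1], "'")
  unknown <- setdiff(cols[-1], phenotype_columns)
  if (length(unknown))
    stop_mri("unknown phenotype column(s) ",
             paste(sQuote(unknown), collapse = ", "), "; accepted: ",
             paste(phenotype_columns, collapse = ", "))
  out <- data.frame(strain = trimws(tab[[1]]), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (cn in cols[-1]) {
    raw <- trimws(tab[[cn]])
    vals <- suppressWarnings(as.numeric(raw))
    vals[raw %in% c("", "NA")] <- NA_real_
    bad <- which(is.na(vals) & !(raw %in% c("", "NA")))
    if (length(bad))
      stop_mri("non-numeric value '", raw[bad[1]], "' in column '", cn, "'")
    if (cn %in% c("growth_rate", "growth_yield") && any(vals < 0, na.rm = TRUE))
      stop_mri("negative ", cn, " in phenotype table")
    out[[cn]] <- vals
  }
  class(out) <- c("phenotype_table", "data.frame")
  out
}
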