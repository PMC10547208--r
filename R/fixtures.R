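# Deterministic toy-model and expression-profile generators. These small
# networks exercise every structural feature the scoring MILP must handle:
# exchange reactions, a reversible step, parallel pathways, isozyme (OR)
# and complex (AND) gene rules, and wild-type vs "evolved" expression
# profiles that differ in a known subset of genes.

#' Toy model specifications
#'
#' `toy_spec("toy1")` is the canonical worked instance: uptake `EX_A` of
#' metabolite A, two parallel conversions `R1` (gene g1) and `R2` (gene
#' g2) from A to B, a reversible step `R3` (gene g3) between B and C, and
#' secretion `EX_C`. With wild-type expression g1=2, g2=4, g3=5 and C=1
#' the reversible step caps total throughput at 5 while the parallel
#' branches supply up to 6, so at most two of the three genes can be fully
#' used. `toy_spec("toy1_growth")` is the same network with `EX_C`
#' declared as the biomass reaction (growth = export of C at yield 1).
#' `random_toy_spec()` draws a randomized chain/branch network.
#'
#' @param name `"toy1"` or `"toy1_growth"`.
#' @return A `toy_spec` list: metabolites, reaction templates, wild-type
#'   expression assignment and medium.
#' @export
toy_spec <- function(name = "toy1") {
  name <- match.arg(name, c("toy1", "toy1_growth"))
  spec <- list(
    name = name,
    mets = c("A", "B", "C"),
    reactions = list(
      list(id = "EX_A", from = character(0), to = "A",
           lb = 0, ub = 1000, rule = ""),
      list(id = "R1", from = "A", to = "B", lb = 0, ub = 1000, rule = "g1"),
      list(id = "R2", from = "A", to = "B", lb = 0, ub = 1000, rule = "g2"),
      list(id = "R3", from = "B", to = "C", lb = -1000, ub = 1000,
           rule = "g3"),
      list(id = "EX_C", from = "C", to = character(0),
           lb = 0, ub = 1000, rule = "")),
    biomass = if (name == "toy1_growth") "EX_C" else NA_character_,
    wt_expr = c(g1 = 2, g2 = 4, g3 = 5),
    medium = c("EX_A"),
    seed = NA_integer_)
  class(spec) <- "toy_spec"
  spec
}

#' Random toy model specification
#'
#' Draws a small metabolic network deterministically from a seed: an
#' uptake exchange feeding a chain of 2-4 internal metabolites, a terminal
#' secretion exchange, one gene per chain step with 3-6 genes total, and
#' randomly sampled structural templates: a parallel branch, a reversible
#' step (always at least one), an isozyme (OR) rule and a complex (AND)
#' rule. Wild-type expression levels are drawn uniformly between 1 and
#' 10. Every
#' generated model admits the all-zero flux solution and maps every gene
#' to at least one reaction.
#'
#' @param seed integer seed; the spec is a pure function of it.
#' @return A `toy_spec`.
#' @export
random_toy_spec <- function(seed) {
  pick1 <- function(x) if (length(x) <= 1) x[1] else sample(x, 1)
  with_seed(seed, {
    n_int <- pick1(2:4)
    mets <- paste0("M", seq_len(n_int))
    gene_ct <- 0L
    next_gene <- function() {
      gene_ct <<- gene_ct + 1L
      paste0("g", gene_ct)
    }
    rxns <- list(list(id = "EX_in", from = character(0), to = mets[1],
                      lb = 0, ub = 1000, rule = ""))
    rev_step <- pick1(seq_len(n_int - 1L) + 1L)  # reaction index of one
    use_iso <- stats::runif(1) < 0.5
    use_and <- stats::runif(1) < 0.5
    iso_step <- (if (use_iso) pick1(2:n_int) else -1L) %||% -1L
    and_step <- (if (use_and) pick1(setdiff(2:n_int, iso_step)) else
      -1L) %||% -1L
    if (is.na(and_step)) and_step <- -1L
    for (k in seq_len(n_int - 1L)) {
      idx <- k + 1L
      rule <- if (idx == iso_step) paste(next_gene(), "or", next_gene())
        else if (idx == and_step) paste(next_gene(), "and", next_gene())
        else next_gene()
      rev <- idx == rev_step || stats::runif(1) < 0.2
      rxns[[length(rxns) + 1L]] <-
        list(id = paste0("S", k), from = mets[k], to = mets[k + 1L],
             lb = if (rev) -1000 else 0, ub = 1000, rule = rule)
    }
    if (n_int >= 3 && stats::runif(1) < 0.6)   # parallel branch
      rxns[[length(rxns) + 1L]] <-
        list(id = "BR", from = mets[1], to = mets[n_int],
             lb = 0, ub = 1000, rule = next_gene())
    rxns[[length(rxns) + 1L]] <-
      list(id = "EX_out", from = mets[n_int], to = character(0),
           lb = 0, ub = 1000, rule = "")
    wt <- round(stats::runif(gene_ct, 1, 10), 2)
    spec <- list(name = paste0("random", seed), mets = mets,
                 reactions = rxns, biomass = NA_character_,
                 wt_expr = stats::setNames(wt, paste0("g", seq_len(gene_ct))),
                 medium = c("EX_in"), seed = seed)
    class(spec) <- "toy_spec"
    spec
  })
}

#' Build a stoichiometric model from a toy specification
#'
#' Deterministic: the same spec always yields the same model (and
#' byte-identical SBML when written).
#'
#' @param spec a [toy_spec()] or [random_toy_spec()] object, or a name
#'   accepted by `toy_spec()`.
#' @return A [stoich_model()].
#' @export
make_toy_model <- function(spec = "toy1") {
  if (is.character(spec)) spec <- toy_spec(spec)
  stopifnot(inherits(spec, "toy_spec"))
  mets <- spec$mets
  n <- length(spec$reactions)
  S <- matrix(0, length(mets), n, dimnames = list(mets, NULL))
  for (k in seq_len(n)) {
    r <- spec$reactions[[k]]
    bad <- setdiff(c(r$from, r$to), mets)
    if (length(bad))
      stop_mri("toy spec references unknown metabolite(s): ",
               paste(bad, collapse = ", "))
    for (mm in r$from) S[mm, k] <- S[mm, k] - 1
    for (mm in r$to) S[mm, k] <- S[mm, k] + 1
  }
  stoich_model(mets,
               vapply(spec$reactions, `[[`, "", "id"), S,
               lb = vapply(spec$reactions, `[[`, 0, "lb"),
               ub = vapply(spec$reactions, `[[`, 0, "ub"),
               gene_rules = vapply(spec$reactions, `[[`, "", "rule"),
               biomass = spec$biomass)
}

#' Simulate wild-type and evolved expression profiles
#'
#' The wild-type profile comes from the spec (or an explicit named
#' vector); each evolved profile equals the wild type plus `shift` on the
#' designated genes plus seeded Gaussian noise of spread `noise` (default
#' 0, i.e. exact). Values are clamped at zero. The shifted genes are the
#' ground-truth key genes and are recorded in the `shifted_genes`
#' attribute.
#'
#' @param spec a `toy_spec`, or a named numeric vector of wild-type
#'   expression levels.
#' @param shifted_genes genes whose expression changes during "evolution".
#' @param shift additive expression change (on the input scale).
#' @param n_evolved number of evolved strains.
#' @param noise standard deviation of per-gene, per-strain noise.
#' @param seed RNG seed for the noise.
#' @return Named list of `expression_profile` objects (`WT`, `Ev1`, ...).
#' @export
simulate_expression_profiles <- function(spec, shifted_genes, shift,
                                         n_evolved = 3L, noise = 0,
                                         seed = 1L) {
  wt <- if (inherits(spec, "toy_spec")) spec$wt_expr else unlist(spec)
  stopifnot(is.finite(shift), n_evolved >= 1)
  missing <- setdiff(shifted_genes, names(wt))
  if (length(missing))
    stop_mri("shifted gene(s) not in the wild-type profile: ",
             paste(missing, collapse = ", "))
  profs <- list(WT = expression_profile("WT", wt))
  with_seed(seed, {
    for (k in seq_len(n_evolved)) {
      v <- wt
      v[shifted_genes] <- v[shifted_genes] + shift
      if (noise > 0) v <- v + stats::rnorm(length(v), 0, noise)
      v <- pmax(v, 0)
      profs[[paste0("Ev", k)]] <-
        expression_profile(paste0("Ev", k), v)
    }
  })
  attr(profs, "shifted_genes") <- shifted_genes
  profs
}

#' Medium for a toy model
#'
#' @param spec a `toy_spec` or name.
#' @return A [medium_spec()] opening the spec's uptake exchange(s).
#' @export
toy_medium <- function(spec = "toy1") {
  if (is.character(spec)) spec <- toy_spec(spec)
  medium_spec(spec$medium, carbon_source = spec$medium[1])
}
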