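# SBML import/export. Writing targets Level 3 Version 1 with the
# flux-balance (fbc v2) extension; reading additionally accepts Level 2
# files that carry bounds in kineticLaw parameters (LOWER_BOUND /
# UPPER_BOUND) and GPRs in GENE_ASSOCIATION notes. Only the subset of SBML
# needed for constraint-based modelling is covered: species, reactions,
# stoichiometry, flux bounds, gene associations and the active objective.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sanitize_sid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("x", x), x)
}

xml_local <- function(node, name) {
  xml2::xml_find_all(node, paste0("./*[local-name()='", name, "']"))
}

attr_by_localname <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(at)) == local)
  if (length(hit)) unname(at[hit[1]]) else NA_character_
}

# ---- writing ---------------------------------------------------------------

gpr_assoc_xml <- function(node, gene_sid) {
  if (!is.null(node$gene))
    return(paste0('<fbc:geneProductRef fbc:geneProduct="',
                  gene_sid[[node$gene]], '"/>'))
  inner <- paste(vapply(node$args, gpr_assoc_xml, "", gene_sid = gene_sid),
                 collapse = "")
  paste0("<fbc:", node$op, ">", inner, "</fbc:", node$op, ">")
}

num_attr <- function(x) format(x, digits = 17, scientific = FALSE,
                               trim = TRUE)

#' Write a model to SBML
#'
#' Serializes a [stoich_model()] as SBML Level 3 Version 1 with the fbc v2
#' extension (parameter-based flux bounds, `geneProductAssociation` GPRs,
#' an active objective when a biomass reaction is set). Original
#' identifiers are preserved in `name` attributes so that round-tripping
#' recovers them exactly even when they are not valid SBML SIds.
#'
#' @param model a `stoich_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  if (inherits(model, "irreversible_model")) {
    notes <- sprintf("SOURCE:%s DIRECTION:%s ISOZYME:%d",
                     model$origin$source, model$origin$direction,
                     model$origin$isozyme)
    model <- stoich_model(
      model$met_ids, model$rxn_ids, model$S, model$lb, model$ub,
      obj = model$obj, b = model$b,
      gene_rules = vapply(model$rule_conjuncts, conjunct_text, ""),
      biomass = model$biomass)
    model$rxn_notes <- notes    # conversion provenance, written as notes
  }
  stopifnot(inherits(model, "stoich_model"))
  rxn_sid <- stats::setNames(paste0("R_", sanitize_sid(model$rxn_ids)),
                             model$rxn_ids)
  met_sid <- stats::setNames(paste0("M_", sanitize_sid(model$met_ids)),
                             model$met_ids)
  gene_sid <- stats::setNames(paste0("G_", sanitize_sid(model$genes)),
                              model$genes)
  bounds <- sort(unique(c(model$lb, model$ub)))
  bnd_id <- stats::setNames(paste0("bnd_", seq_along(bounds)),
                            num_attr(bounds))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_CORE_NS, '" xmlns:fbc="', SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    '<model id="model" fbc:strict="false">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "<listOfSpecies>",
    paste0('<species id="', met_sid, '" name="', esc(model$met_ids),
           '" compartment="c" hasOnlySubstanceUnits="false"',
           ' boundaryCondition="false" constant="false"/>'),
    "</listOfSpecies>",
    "<listOfParameters>",
    paste0('<parameter id="', bnd_id, '" value="', names(bnd_id),
           '" constant="true"/>'),
    "</listOfParameters>",
    "<listOfReactions>")

  for (k in seq_along(model$rxn_ids)) {
    col <- model$S[, k]
    nz <- which(col != 0)
    lines <- c(lines, paste0(
      '<reaction id="', rxn_sid[k], '" name="', esc(model$rxn_ids[k]),
      '" reversible="', tolower(model$lb[k] < 0), '" fast="false"',
      ' fbc:lowerFluxBound="', bnd_id[[num_attr(model$lb[k])]],
      '" fbc:upperFluxBound="', bnd_id[[num_attr(model$ub[k])]], '">'))
    react <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(react))
      lines <- c(lines, "<listOfReactants>",
                 paste0('<speciesReference species="', met_sid[react],
                        '" stoichiometry="', num_attr(-col[react]),
                        '" constant="true"/>'),
                 "</listOfReactants>")
    if (length(prod))
      lines <- c(lines, "<listOfProducts>",
                 paste0('<speciesReference species="', met_sid[prod],
                        '" stoichiometry="', num_attr(col[prod]),
                        '" constant="true"/>'),
                 "</listOfProducts>")
    if (!is.null(model$rxn_notes))
      lines <- c(lines, paste0(
        '<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>',
        esc(model$rxn_notes[k]), "</p></body></notes>"))
    tree <- gpr_parse(model$gene_rules[k])
    if (!is.null(tree))
      lines <- c(lines, "<fbc:geneProductAssociation>",
                 gpr_assoc_xml(tree, gene_sid),
                 "</fbc:geneProductAssociation>")
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>")

  if (!is.na(model$biomass)) {
    lines <- c(lines,
      '<fbc:listOfObjectives fbc:activeObjective="obj">',
      '<fbc:objective fbc:id="obj" fbc:type="maximize">',
      "<fbc:listOfFluxObjectives>",
      paste0('<fbc:fluxObjective fbc:reaction="', rxn_sid[[model$biomass]],
             '" fbc:coefficient="1"/>'),
      "</fbc:listOfFluxObjectives>", "</fbc:objective>",
      "</fbc:listOfObjectives>")
  }
  if (length(model$genes))
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               paste0('<fbc:geneProduct fbc:id="', gene_sid, '" fbc:label="',
                      esc(model$genes), '"/>'),
               "</fbc:listOfGeneProducts>")
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

assoc_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- attr_by_localname(node, "geneProduct")
    if (is.na(g)) stop_mri("SBML parse error: geneProductRef without ",
                           "fbc:geneProduct attribute")
    return(g)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, assoc_to_rule, "")
  op <- if (nm == "and") " and " else if (nm == "or") " or " else
    stop_mri("SBML parse error: unexpected element '", nm,
             "' in geneProductAssociation")
  paste0("(", paste(parts, collapse = op), ")")
}

#' Read an SBML model
#'
#' Parses SBML into a [stoich_model()]. Flux bounds are taken from fbc
#' bound parameters (Level 3) or kineticLaw `LOWER_BOUND`/`UPPER_BOUND`
#' parameters (Level 2); a reaction without bounds is an error, never
#' silently defaulted. Gene associations come from fbc
#' `geneProductAssociation` elements or `GENE_ASSOCIATION` notes and are
#' preserved as Boolean rule text. Species flagged `boundaryCondition` are
#' dropped from the stoichiometry, so their reactions become exchanges.
#'
#' @param path SBML file path.
#' @return A `stoich_model`.
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) stop_mri("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_mri("invalid SBML: ",
                                               conditionMessage(e)))
  model_node <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(model_node, "xml_missing"))
    stop_mri("SBML parse error: no <model> element")

  # species
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp_nodes) == 0) stop_mri("SBML parse error: no species")
  sp_id <- vapply(sp_nodes, function(n) attr_by_localname(n, "id"), "")
  if (anyNA(sp_id) || any(!nzchar(sp_id)))
    stop_mri("SBML parse error: species without id")
  sp_name <- vapply(sp_nodes, function(n) attr_by_localname(n, "name"), "")
  sp_bdry <- vapply(sp_nodes, function(n)
    identical(attr_by_localname(n, "boundaryCondition"), "true"), TRUE)
  met_orig <- ifelse(is.na(sp_name) | !nzchar(sp_name),
                     sub("^M_", "", sp_id), sp_name)
  keep <- !sp_bdry
  met_ids <- met_orig[keep]
  met_row <- stats::setNames(match(sp_id[keep], sp_id[keep]), sp_id[keep])

  # fbc bound parameters
  par_nodes <- xml2::xml_find_all(doc, "//*[local-name()='model']/*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(attr_by_localname(n, "value")), 0),
    vapply(par_nodes, function(n) attr_by_localname(n, "id"), ""))

  # gene products: SId -> label
  gp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lbl <- attr_by_localname(n, "label")
      if (is.na(lbl) || !nzchar(lbl))
        lbl <- sub("^G_", "", attr_by_localname(n, "id"))
      lbl
    }, ""),
    vapply(gp_nodes, function(n) attr_by_localname(n, "id"), ""))

  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop_mri("SBML parse error: no reactions")
  n <- length(rx_nodes)
  rxn_ids <- character(n); lb <- numeric(n); ub <- numeric(n)
  rules <- character(n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)

  for (k in seq_len(n)) {
    node <- rx_nodes[[k]]
    rid <- attr_by_localname(node, "id")
    if (is.na(rid)) stop_mri("SBML parse error: reaction without id")
    rname <- attr_by_localname(node, "name")
    rxn_ids[k] <- if (!is.na(rname) && nzchar(rname)) rname else
      sub("^R_", "", rid)

    add_side <- function(list_name, sign) {
      for (sr in xml_local(node, list_name) |> xml2::xml_children()) {
        sp <- attr_by_localname(sr, "species")
        st <- attr_by_localname(sr, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (is.na(sp) || !sp %in% sp_id)
          stop_mri("SBML parse error: reaction '", rid,
                   "' references unknown species '", sp, "'")
        if (sp %in% names(met_row)) {   # boundary species are dropped
          trip_i <<- c(trip_i, met_row[[sp]])
          trip_j <<- c(trip_j, k)
          trip_x <<- c(trip_x, sign * st)
        }
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", +1)

    # bounds: fbc attributes first, then kineticLaw parameters (L2)
    lo_ref <- attr_by_localname(node, "lowerFluxBound")
    up_ref <- attr_by_localname(node, "upperFluxBound")
    if (!is.na(lo_ref) && !is.na(up_ref)) {
      if (!lo_ref %in% names(par_val) || !up_ref %in% names(par_val))
        stop_mri("SBML parse error: reaction '", rid,
                 "' references undefined bound parameter")
      lb[k] <- par_val[[lo_ref]]; ub[k] <- par_val[[up_ref]]
    } else {
      klaw <- xml2::xml_find_all(node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      kl_id <- vapply(klaw, function(p) attr_by_localname(p, "id"), "")
      kl_v <- vapply(klaw, function(p) as.numeric(attr_by_localname(p, "value")), 0)
      ilo <- which(kl_id == "LOWER_BOUND"); iup <- which(kl_id == "UPPER_BOUND")
      if (length(ilo) == 0 || length(iup) == 0)
        stop_mri("reaction '", rid, "' has no flux bounds (fbc attributes ",
                 "or kineticLaw LOWER_BOUND/UPPER_BOUND required)")
      lb[k] <- kl_v[ilo[1]]; ub[k] <- kl_v[iup[1]]
    }

    # gene association
    assoc <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids) != 1)
        stop_mri("SBML parse error: malformed geneProductAssociation in '",
                 rid, "'")
      rule_sid <- assoc_to_rule(kids[[1]])
      # map gene product SIds to labels, longest-first to avoid prefix hits
      for (sid in names(gp_label)[order(-nchar(names(gp_label)))])
        rule_sid <- gsub(paste0("\\b", sid, "\\b"), gp_label[[sid]],
                         rule_sid)
      rules[k] <- gpr_text(gpr_parse(rule_sid))
    } else {
      notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        mt <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
        if (length(mt))
          rules[k] <- trimws(sub("GENE_ASSOCIATION:", "", mt))
      }
    }
  }

  # objective / biomass
  biomass <- NA_character_
  fo <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    bref <- attr_by_localname(fo, "reaction")
    k <- match(bref, vapply(rx_nodes, function(nd) attr_by_localname(nd, "id"), ""))
    if (!is.na(k)) biomass <- rxn_ids[k]
  }

  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(met_ids), n))
  stoich_model(met_ids, rxn_ids, S, lb, ub, gene_rules = rules,
               biomass = biomass)
}
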