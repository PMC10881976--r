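#' Read an SBML Level 3 + FBC model
#'
#' Reads the constructs needed for flux balance analysis -- compartments,
#' species (with FBC charge/formula), reactions with FBC flux bounds, and the
#' active objective -- from an SBML Level 3 file using the `fbc` extension
#' (the distribution format of genome-scale models such as Yeast8). Any other
#' construct in the file is ignored with one logged message per construct
#' type. Support is read-only.
#'
#' Species marked `boundaryCondition="true"` are dropped from stoichiometries
#' (they are outside the balanced system), which leaves boundary reactions
#' touching a single species; such reactions are flagged as exchanges.
#'
#' @param path Path to the SBML file.
#' @param role_patterns Named list used to resolve semantic roles. Each entry
#'   is a list with any of `id` (exact reaction id), `annotation` (fixed
#'   string searched in the reaction annotation block) and `name_regex`
#'   (regular expression on the reaction name), tried in that order. Roles
#'   that match nothing are left unset rather than guessed.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path, role_patterns = list()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  doc <- xml2::read_xml(path)  # malformed XML -> parse error naming the line

  find_all <- function(node, tag) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", tag, "']"))
  }
  attr1 <- function(node, name) {
    # namespace-agnostic attribute lookup: match on the local attribute name
    at <- xml2::xml_attrs(node)
    hit <- which(sub("^.*:", "", names(at)) == name)
    if (length(hit)) at[[hit[1]]] else NA_character_
  }

  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) abort("SBML file has no <model>")

  handled <- c("listOfCompartments", "listOfSpecies", "listOfParameters",
               "listOfReactions", "listOfObjectives", "listOfUnitDefinitions",
               "annotation", "notes", "listOfGeneProducts")
  for (child in xml2::xml_children(model_node)) {
    tag <- sub("^.*:", "", xml2::xml_name(child))
    if (!tag %in% handled) {
      inform(paste0("read_sbml: ignoring SBML construct <", tag, ">"))
    }
  }

  # parameters hold the shared flux-bound values
  pars <- find_all(model_node, "parameter")
  par_val <- stats::setNames(
    as.numeric(vapply(pars, function(p) attr1(p, "value"), "")),
    vapply(pars, function(p) attr1(p, "id"), "")
  )

  sp_nodes <- find_all(model_node, "species")
  if (!length(sp_nodes)) abort("SBML file declares no species")
  boundary <- logical(length(sp_nodes))
  # collect every element symbol present so unusual ones (R groups, metals)
  # are accepted as a declared extension set
  raw_formulas <- vapply(sp_nodes, function(s) attr1(s, "chemicalFormula"), "")
  all_elements <- unique(unlist(regmatches(
    raw_formulas, gregexpr("[A-Z][a-z]?", raw_formulas[!is.na(raw_formulas)])
  )))
  extra <- setdiff(all_elements, names(.ATOMIC_MASS))
  if (length(extra)) {
    inform(paste0("read_sbml: formulas use extension elements: ",
                  paste(extra, collapse = ", ")))
  }
  mets <- vector("list", length(sp_nodes))
  for (i in seq_along(sp_nodes)) {
    s <- sp_nodes[[i]]
    boundary[i] <- identical(attr1(s, "boundaryCondition"), "true")
    f <- raw_formulas[i]
    fml <- if (is.na(f) || !nzchar(f)) NULL else
      tryCatch(parse_formula(f, extra_elements = extra),
               error = function(e) NULL)
    ch <- attr1(s, "charge")
    mets[[i]] <- metabolite(
      id = attr1(s, "id"),
      name = attr1(s, "name") %||% attr1(s, "id"),
      formula = fml,
      charge = if (is.na(ch)) 0L else as.integer(ch),
      compartment = attr1(s, "compartment")
    )
  }
  met_tbl <- dplyr::bind_rows(mets)
  boundary_ids <- met_tbl$id[boundary]
  met_tbl <- met_tbl[!boundary, ]

  rx_nodes <- xml2::xml_find_all(
    model_node,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']"
  )
  if (!length(rx_nodes)) abort("SBML file declares no reactions")
  rxns <- vector("list", length(rx_nodes))
  annos <- character(length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    r <- rx_nodes[[i]]
    rid <- attr1(r, "id")
    lb_ref <- attr1(r, "lowerFluxBound")
    ub_ref <- attr1(r, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref) ||
        is.na(par_val[lb_ref]) || is.na(par_val[ub_ref])) {
      abort(paste0("reaction '", rid, "': flux bounds missing or unresolvable"))
    }
    sto <- c()
    for (ref in find_all(r, "speciesReference")) {
      sp <- attr1(ref, "species")
      if (sp %in% boundary_ids) next
      coef <- as.numeric(attr1(ref, "stoichiometry") %||% "1")
      if (is.na(coef)) coef <- 1
      parent_tag <- sub("^.*:", "", xml2::xml_name(xml2::xml_parent(ref)))
      sgn <- if (parent_tag == "listOfReactants") -1 else 1
      sto[sp] <- (if (!is.null(sto[sp]) && !is.na(sto[sp])) sto[sp] else 0) +
        sgn * coef
    }
    if (!length(sto)) {
      inform(paste0("read_sbml: reaction '", rid,
                    "' touches only boundary species; skipped"))
      rxns[i] <- list(NULL)
      next
    }
    an <- xml2::xml_find_first(r, "./*[local-name()='annotation']")
    annos[i] <- if (inherits(an, "xml_missing")) "" else as.character(an)
    rxns[[i]] <- reaction(
      id = rid, name = attr1(r, "name") %||% rid,
      stoichiometry = sto,
      lower_bound = unname(par_val[lb_ref]),
      upper_bound = unname(par_val[ub_ref]),
      is_exchange = length(sto) == 1L
    )
  }
  keep <- !vapply(rxns, is.null, TRUE)
  rxn_tbl <- dplyr::bind_rows(rxns[keep])
  annos <- annos[keep]

  roles <- list()
  for (role in names(role_patterns)) {
    pat <- role_patterns[[role]]
    hit <- NA_character_
    if (!is.null(pat$id) && pat$id %in% rxn_tbl$id) {
      hit <- pat$id
    } else if (!is.null(pat$annotation)) {
      k <- grep(pat$annotation, annos, fixed = TRUE)
      if (length(k)) hit <- rxn_tbl$id[k[1]]
    }
    if (is.na(hit) && !is.null(pat$name_regex)) {
      k <- grep(pat$name_regex, rxn_tbl$name)
      if (length(k)) hit <- rxn_tbl$id[k[1]]
    }
    if (!is.na(hit)) roles[[role]] <- hit
  }

  metabolic_model(met_tbl, rxn_tbl, roles = roles,
                  provenance = paste0("sbml:", basename(path)))
}

#' Default role-matching patterns for the Yeast8 consensus model
#'
#' Id patterns follow the yeast-GEM naming scheme; they are configuration,
#' not assertions about any particular release, and can be overridden.
#'
#' @return Named list suitable for the `role_patterns` argument of
#'   [read_sbml()].
#' @export
yeast8_role_patterns <- function() {
  list(
    glucose_exchange = list(id = "r_1714",
                            name_regex = "D-glucose exchange"),
    biomass = list(id = "r_2111", name_regex = "growth|biomass"),
    bicarbonate_formation = list(name_regex = "carbonic anhydrase"),
    bicarbonate_exchange = list(name_regex = "bicarbonate exchange"),
    atp_dissipation = list(id = "r_4046",
                           name_regex = "non-growth associated maintenance")
  )
}
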