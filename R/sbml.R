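# SBML Level 3 + FBC v2 import/export for stoichiometric models, built on
# xml2 and restricted to the constraint-based subset: compartments, species
# (with fbc chemical formula and charge), reactions with fbc flux bounds,
# and the active fbc objective. Gene-product associations, annotations and
# units are ignored on read and not written.

RF_SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
RF_SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

rf_sbml_compartment <- function(x) {
  # map arbitrary SBML compartment ids onto c/p/e; unknown ids become "c"
  switch(tolower(x),
         "c" = "c", "cytosol" = "c", "cytoplasm" = "c",
         "p" = "p", "periplasm" = "p",
         "e" = "e", "extracellular" = "e", "extracellular space" = "e",
         "c")
}

#' Read an SBML Level 3 FBC model
#'
#' Parses species, reactions, flux bounds and the active objective from an
#' SBML Level 3 document with the FBC package and returns a
#' [stoich_model()]. Bounds may be given as parameter references (the FBC
#' convention) or as literal numbers. Boundary-condition species are
#' dropped from reaction stoichiometries (their exchange reactions then
#' touch a single species). Reactions touching exactly one species are
#' flagged as exchanges; reactions whose id contains "biomass" or "ATPM"
#' (case-insensitive) are flagged as pseudo-reactions.
#'
#' @param path Path to an SBML file.
#' @return A `stoich_model` (validated for structure; elemental balance is
#'   not enforced on import since genome-scale models may omit formulas).
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("cannot read SBML file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = RF_SBML_CORE_NS, fbc = RF_SBML_FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) {
    stop("no <model> element found (is this SBML Level 3?)")
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "sbml_model"

  ## parameters (bound values)
  pars <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter",
                             ns)
  par_val <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id"))

  resolve_bound <- function(ref, rxn_id, which) {
    if (is.na(ref)) {
      stop("reaction '", rxn_id, "' has no FBC ", which, " flux bound")
    }
    if (ref %in% names(par_val)) return(par_val[[ref]])
    v <- suppressWarnings(as.numeric(ref))
    if (is.na(v)) {
      stop("reaction '", rxn_id, "': ", which, " bound '", ref,
           "' is neither a parameter id nor a number")
    }
    v
  }

  ## species
  sp <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0) stop("SBML model contains no species")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_name <- xml2::xml_attr(sp, "name")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_form <- xml2::xml_attr(sp, "fbc:chemicalFormula",
                            ns = c(fbc = RF_SBML_FBC_NS))
  sp_chg <- xml2::xml_attr(sp, "fbc:charge", ns = c(fbc = RF_SBML_FBC_NS))
  sp_bdry <- xml2::xml_attr(sp, "boundaryCondition")
  boundary <- !is.na(sp_bdry) & tolower(sp_bdry) == "true"
  mets <- vector("list", sum(!boundary)); k <- 0
  for (i in seq_along(sp)) {
    if (boundary[i]) next
    k <- k + 1
    form <- if (is.na(sp_form[i])) "" else sp_form[i]
    counts <- tryCatch(parse_formula(form),
                       error = function(e) parse_formula(""))
    mets[[k]] <- metabolite(
      id = sp_id[i],
      name = if (is.na(sp_name[i])) sp_id[i] else sp_name[i],
      formula = counts,
      charge = if (is.na(sp_chg[i])) 0L else as.integer(sp_chg[i]),
      compartment = rf_sbml_compartment(sp_comp[i]))
  }
  met_ids <- vapply(mets, function(m) m$id, character(1))
  boundary_ids <- sp_id[boundary]

  ## reactions
  rx <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0) stop("SBML model contains no reactions")
  rxns <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    rid <- xml2::xml_attr(node, "id")
    rname <- xml2::xml_attr(node, "name")
    lbref <- xml2::xml_attr(node, "fbc:lowerFluxBound",
                            ns = c(fbc = RF_SBML_FBC_NS))
    ubref <- xml2::xml_attr(node, "fbc:upperFluxBound",
                            ns = c(fbc = RF_SBML_FBC_NS))
    lb <- resolve_bound(lbref, rid, "lower")
    ub <- resolve_bound(ubref, rid, "upper")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node,
                                 paste0("./s:", side, "/s:speciesReference"),
                                 ns)
      if (length(refs) == 0) next
      ids <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      keep <- !ids %in% boundary_ids
      ids <- ids[keep]; coef <- coef[keep]
      dangling <- setdiff(ids, met_ids)
      if (length(dangling) > 0) {
        stop("reaction '", rid, "' references undeclared species: ",
             paste(dangling, collapse = ", "))
      }
      for (j in seq_along(ids)) {
        st[ids[j]] <- (if (ids[j] %in% names(st)) st[[ids[j]]] else 0) +
          coef[j]
      }
    }
    rxns[[i]] <- reaction(
      rid, st, lower_bound = lb, upper_bound = ub,
      name = if (is.na(rname)) rid else rname,
      is_exchange = length(st[st != 0]) == 1,
      is_pseudo = grepl("biomass|atpm|maintenance", rid,
                        ignore.case = TRUE))
  }

  ## objective
  objective <- numeric(0)
  act <- xml2::xml_attr(
    xml2::xml_find_first(model_node, ".//fbc:listOfObjectives", ns),
    "fbc:activeObjective", ns = c(fbc = RF_SBML_FBC_NS))
  obj_nodes <- xml2::xml_find_all(
    model_node,
    if (!is.na(act))
      sprintf(".//fbc:objective[@fbc:id='%s']/fbc:listOfFluxObjectives/fbc:fluxObjective", act)
    else ".//fbc:fluxObjective",
    ns)
  if (length(obj_nodes) > 0) {
    oid <- xml2::xml_attr(obj_nodes, "fbc:reaction",
                          ns = c(fbc = RF_SBML_FBC_NS))
    ocf <- as.numeric(xml2::xml_attr(obj_nodes, "fbc:coefficient",
                                     ns = c(fbc = RF_SBML_FBC_NS)))
    ocf[is.na(ocf)] <- 1
    objective <- stats::setNames(ocf, oid)
  }
  stoich_model(mets, rxns, objective, id = model_id)
}

#' Write a model as SBML Level 3 + FBC v2
#'
#' Serialises a [stoich_model()] to the same SBML dialect [read_sbml()]
#' consumes (flux bounds as parameters, formulas and charges as FBC
#' attributes, active maximisation objective), so that write/read
#' round-trips preserve stoichiometry, bounds and the objective.
#'
#' @param model A `stoich_model`.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "stoich_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', RF_SBML_CORE_NS, '" xmlns:fbc="', RF_SBML_FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="true">')
  comps <- unique(vapply(model$metabolites, function(m) m$compartment,
                         character(1)))
  w('    <listOfCompartments>')
  for (cp in comps) {
    w('      <compartment id="', cp, '" constant="true"/>')
  }
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (m in model$metabolites) {
    form <- formula_string(m$formula)
    w('      <species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', m$compartment,
      '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
      ' constant="false"',
      if (nzchar(form)) paste0(' fbc:chemicalFormula="', form, '"') else "",
      ' fbc:charge="', m$charge, '"/>')
  }
  w('    </listOfSpecies>')
  ## one shared parameter per distinct bound value
  bounds <- unique(unlist(lapply(model$reactions,
                                 function(r) c(r$lower_bound,
                                               r$upper_bound))))
  par_id <- stats::setNames(
    sprintf("bnd_%d", seq_along(bounds)),
    vapply(bounds, num, character(1)))
  w('    <listOfParameters>')
  for (i in seq_along(bounds)) {
    w('      <parameter id="', par_id[[num(bounds[i])]], '" value="',
      num(bounds[i]), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (r in model$reactions) {
    w('      <reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', if (r$lower_bound < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', par_id[[num(r$lower_bound)]],
      '" fbc:upperFluxBound="', par_id[[num(r$upper_bound)]], '">')
    st <- r$stoichiometry
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac) > 0) {
      w('        <listOfReactants>')
      for (mid in names(reac)) {
        w('          <speciesReference species="', esc(mid),
          '" stoichiometry="', num(-reac[[mid]]), '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(prod) > 0) {
      w('        <listOfProducts>')
      for (mid in names(prod)) {
        w('          <speciesReference species="', esc(mid),
          '" stoichiometry="', num(prod[[mid]]), '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  if (length(model$objective) > 0) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    for (rid in names(model$objective)) {
      w('          <fbc:fluxObjective fbc:reaction="', esc(rid),
        '" fbc:coefficient="', num(model$objective[[rid]]), '"/>')
    }
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
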