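# Standard-format model I/O.
#
# SBML: Level 3 Version 1 core with the fbc v2 extension for flux bounds
# and the active objective -- the interchange subset that constraint-based
# tools exchange. Written and parsed with xml2 (no libsbml binding exists
# in this R stack). Unrecognised SBML content is ignored on read.
#
# JSON: a dialect mirroring the GEM type one-to-one (id, metabolites,
# reactions with stoichiometry/bounds/flags, objective_id); schema
# documented in inst/extdata/gem-schema.json.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a metabolic model from SBML or JSON
#'
#' @param path File path.
#' @param format `"sbml"` or `"json"`; default guessed from the extension.
#' @return A validated [gem()]. Models without a declared active objective
#'   raise a "no biomass objective" error.
#' @export
read_gem <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  assert_(file.exists(path), paste0("no such file: ", path))
  switch(format, sbml = read_gem_sbml_(path), json = read_gem_json_(path))
}

#' Write a metabolic model to SBML or JSON
#'
#' `read_gem(write_gem(m, p), p)` is structurally identical to `m`
#' (ids, names, stoichiometry, bounds, flags, objective).
#'
#' @param model A valid [gem()].
#' @inheritParams read_gem
#' @return `path`, invisibly.
#' @export
write_gem <- function(model, path, format = c("auto", "sbml", "json")) {
  validate_gem(model)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  switch(format, sbml = write_gem_sbml_(model, path), json = write_gem_json_(model, path))
  invisible(path)
}

write_gem_json_ <- function(model, path) {
  rx <- purrr::map(unname(model$reactions), function(r) {
    list(id = r$id, stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         is_exchange = r$is_exchange, is_biomass = r$is_biomass)
  })
  obj <- list(id = model$id,
              metabolites = purrr::pmap(model$metabolites, function(id, name, compartment) {
                list(id = id, name = name, compartment = compartment)
              }),
              reactions = rx,
              objective_id = model$objective_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_gem_json_ <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) abort_(paste0("JSON parse failure in ", path, ": ", conditionMessage(e))))
  for (f in c("id", "metabolites", "reactions")) {
    assert_(!is.null(obj[[f]]), paste0("JSON model missing field '", f, "'"))
  }
  if (is.null(obj$objective_id)) abort_(paste0("JSON model '", obj$id, "': no biomass objective"))
  mets <- dplyr::bind_rows(purrr::map(obj$metabolites, function(m) {
    tibble::tibble(id = m$id, name = m$name %||% m$id, compartment = m$compartment)
  }))
  rxns <- purrr::map(obj$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(r$id, st, r$lower_bound %||% -1000, r$upper_bound %||% 1000,
             is_exchange = r$is_exchange, is_biomass = isTRUE(r$is_biomass))
  })
  gem(obj$id, mets, rxns, obj$objective_id)
}

write_gem_sbml_ <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, `xmlns:fbc` = FBC_NS,
    level = "3", version = "1", `fbc:required` = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$id, `fbc:strict` = "true")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  }

  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(sp, "species", id = m$id, name = m$name,
                        compartment = m$compartment, hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }

  # one shared parameter per distinct bound value, fbc-style
  bvals <- sort(unique(c(
    vapply(model$reactions, `[[`, 0, "lower_bound"),
    vapply(model$reactions, `[[`, 0, "upper_bound")
  )))
  pid <- stats::setNames(paste0("fb_", seq_along(bvals)), fmt_num_(bvals))
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bvals)) {
    xml2::xml_add_child(pars, "parameter", id = pid[[i]],
                        value = fmt_num_(bvals[i]), constant = "true")
  }

  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    attrs <- c(id = r$id, reversible = tolower(r$lower_bound < 0), fast = "false")
    rn <- xml2::xml_add_child(rl, "reaction")
    xml2::xml_set_attrs(rn, c(attrs,
      `fbc:lowerFluxBound` = pid[[fmt_num_(r$lower_bound)]],
      `fbc:upperFluxBound` = pid[[fmt_num_(r$upper_bound)]]))
    if (r$is_biomass) xml2::xml_set_attr(rn, "sboTerm", "SBO:0000629")
    neg <- r$stoichiometry[r$stoichiometry < 0]
    pos <- r$stoichiometry[r$stoichiometry > 0]
    if (length(neg)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(neg)) {
        xml2::xml_add_child(lr, "speciesReference", species = m,
                            stoichiometry = fmt_num_(-neg[[m]]), constant = "true")
      }
    }
    if (length(pos)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(pos)) {
        xml2::xml_add_child(lp, "speciesReference", species = m,
                            stoichiometry = fmt_num_(pos[[m]]), constant = "true")
      }
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", `fbc:activeObjective` = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", `fbc:id` = "obj", `fbc:type` = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective", `fbc:reaction` = model$objective_id,
                      `fbc:coefficient` = "1")

  xml2::write_xml(doc, path)
}

read_gem_sbml_ <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_(paste0("SBML parse failure in ", path, ": ", conditionMessage(e))))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  assert_(!inherits(mdl, "xml_missing"), "SBML parse failure: no <model> element")
  mid <- xml2::xml_attr(mdl, "id") %||% "model"

  species <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  assert_(length(species) > 0, "SBML parse failure: no species declared")
  mets <- tibble::tibble(
    id = xml2::xml_attr(species, "id"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"), xml2::xml_attr(species, "id")),
    compartment = xml2::xml_attr(species, "compartment")
  )

  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")), xml2::xml_attr(pars, "id"))

  obj_rxn <- xml2::xml_attr(
    xml2::xml_find_first(mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns),
    "fbc:reaction", ns = ns
  )
  if (is.na(obj_rxn) || is.null(obj_rxn)) {
    abort_(paste0("SBML model '", mid, "': no biomass objective declared"))
  }

  rnodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  assert_(length(rnodes) > 0, "SBML parse failure: no reactions declared")
  rxns <- purrr::map(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    assert_(!is.na(rid) && nzchar(rid), "SBML parse failure: reaction without id")
    reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")), xml2::xml_attr(reac, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")), xml2::xml_attr(prod, "species"))
    )
    assert_(length(st) > 0, paste0("SBML parse failure: reaction '", rid, "' has empty stoichiometry"))
    lbid <- xml2::xml_attr(rn, "fbc:lowerFluxBound", ns = ns)
    ubid <- xml2::xml_attr(rn, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else
      if (identical(xml2::xml_attr(rn, "reversible"), "true")) -1000 else 0
    ub <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else 1000
    reaction(rid, st, lb, ub, is_biomass = rid == obj_rxn)
  })
  gem(mid, mets, rxns, obj_rxn)
}
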