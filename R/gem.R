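#' Construct a reaction record
#'
#' A reaction maps metabolite ids to signed stoichiometric coefficients
#' (negative = consumed) with flux bounds in mmol/gDW/h by convention.
#' Exchange reactions follow the dominant community-modelling convention:
#' a single metabolite with coefficient -1, negative flux meaning uptake
#' and positive flux meaning secretion.
#'
#' @param id Reaction identifier (non-empty string).
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds; must satisfy
#'   `lower_bound <= upper_bound` and be finite.
#' @param is_exchange Logical; defaults to the single-metabolite
#'   coefficient -1 convention.
#' @param is_biomass Logical; flags the growth pseudo-reaction whose
#'   coefficients are averaged when models are merged.
#' @return A list of class `gem_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000, upper_bound = 1000,
                     is_exchange = NULL, is_biomass = FALSE) {
  assert_(is.character(id) && length(id) == 1 && nzchar(id), "reaction id must be a non-empty string")
  assert_(is.numeric(stoichiometry) && length(stoichiometry) > 0 &&
            !is.null(names(stoichiometry)) && all(nzchar(names(stoichiometry))),
          paste0("reaction '", id, "': stoichiometry must be a non-empty named numeric vector"))
  assert_(!anyDuplicated(names(stoichiometry)),
          paste0("reaction '", id, "': duplicated metabolite in stoichiometry"))
  assert_(is.finite(lower_bound) && is.finite(upper_bound) && lower_bound <= upper_bound,
          paste0("reaction '", id, "': requires finite lower_bound <= upper_bound"))
  if (is.null(is_exchange)) {
    is_exchange <- !isTRUE(is_biomass) &&
      length(stoichiometry) == 1L && unname(stoichiometry) == -1
  }
  structure(
    list(id = id, stoichiometry = stoichiometry,
         lower_bound = as.numeric(lower_bound), upper_bound = as.numeric(upper_bound),
         is_exchange = isTRUE(is_exchange), is_biomass = isTRUE(is_biomass)),
    class = "gem_reaction"
  )
}

#' Construct a genome-scale metabolic model (GEM)
#'
#' @param id Taxon/model identifier.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`
#'   (compartment tags such as `"c"` cytosol, `"e"` extracellular).
#' @param reactions List of [reaction()] records.
#' @param objective_id Id of the biomass reaction; exactly this reaction
#'   must carry `is_biomass = TRUE`.
#' @return An object of class `gem`.
#' @export
gem <- function(id, metabolites, reactions, objective_id) {
  metabolites <- tibble::as_tibble(metabolites)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  metabolites <- metabolites[, c("id", "name", "compartment")]
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  out <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective_id = objective_id),
    class = "gem"
  )
  validate_gem(out)
  out
}

#' Validate GEM invariants
#'
#' Checks id uniqueness, bound ordering, stoichiometry referencing only
#' declared metabolites, and that the declared objective is the unique
#' biomass-flagged reaction.
#'
#' @param model A `gem`.
#' @return The model, invisibly, if valid; otherwise an error.
#' @export
validate_gem <- function(model) {
  assert_(inherits(model, "gem"), "not a gem object")
  assert_(is.character(model$id) && nzchar(model$id), "gem id must be non-empty")
  mets <- model$metabolites
  assert_(nrow(mets) > 0 && all(nzchar(mets$id)), "gem must declare metabolites with non-empty ids")
  assert_(!anyDuplicated(mets$id), paste0("gem '", model$id, "': duplicated metabolite ids"))
  assert_(all(nzchar(mets$compartment)), paste0("gem '", model$id, "': empty compartment tag"))
  rxns <- model$reactions
  assert_(length(rxns) > 0, paste0("gem '", model$id, "': no reactions"))
  ids <- vapply(rxns, `[[`, "", "id")
  assert_(!anyDuplicated(ids), paste0("gem '", model$id, "': duplicated reaction ids"))
  for (r in rxns) {
    missing <- setdiff(names(r$stoichiometry), mets$id)
    assert_(length(missing) == 0,
            paste0("gem '", model$id, "': reaction '", r$id,
                   "' references unknown metabolites: ", paste(missing, collapse = ", ")))
  }
  assert_(is.character(model$objective_id) && model$objective_id %in% ids,
          paste0("gem '", model$id, "': no biomass objective (objective_id missing)"))
  bio <- unname(ids[vapply(rxns, `[[`, TRUE, "is_biomass")])
  assert_(identical(bio, model$objective_id),
          paste0("gem '", model$id, "': exactly the objective reaction must have is_biomass = TRUE"))
  invisible(model)
}

#' @export
print.gem <- function(x, ...) {
  nex <- sum(vapply(x$reactions, `[[`, TRUE, "is_exchange"))
  cat("<gem> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", length(x$reactions),
      " (", nex, " exchanges)\n",
      "  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

rxn_ids_ <- function(model) names(model$reactions)

exchange_ids_ <- function(model) {
  names(model$reactions)[vapply(model$reactions, `[[`, TRUE, "is_exchange")]
}

# single metabolite carried by an exchange reaction
exchange_met_ <- function(rxn) names(rxn$stoichiometry)[1]

# metabolite x reaction stoichiometric matrix (dense; toy scale)
stoich_matrix_ <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids), dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

bounds_ <- function(model) {
  list(lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
       ub = vapply(model$reactions, `[[`, 0, "upper_bound"))
}

#' Reaction identifiers of a model as a set
#'
#' Utility used by the redundancy metrics: reaction ids with biomass
#' pseudo-reactions excluded (their ids are artifacts of merging) and,
#' optionally, community member suffixes stripped.
#'
#' @param model A `gem`.
#' @param exclude_biomass Drop biomass-flagged reactions (default TRUE).
#' @param strip_suffix Remove a trailing `"__<tag>"` community suffix.
#' @return Character vector of reaction ids.
#' @export
reaction_set <- function(model, exclude_biomass = TRUE, strip_suffix = FALSE) {
  keep <- if (exclude_biomass) {
    !vapply(model$reactions, `[[`, TRUE, "is_biomass")
  } else rep(TRUE, length(model$reactions))
  ids <- names(model$reactions)[keep]
  if (strip_suffix) ids <- sub("__.*$", "", ids)
  unique(ids)
}
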