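#' Merge related GEMs into one pooled model
#'
#' Implements the model-joining step of phylogenetically informed
#' community modelling: the merged model contains the union of the input
#' models' reactions (deduplicated by reaction id, first occurrence
#' winning for bounds and stoichiometry) and a single new biomass reaction
#' whose coefficient for each metabolite is the arithmetic mean of the
#' input biomass coefficients,
#' \deqn{c_{merged}(m) = \frac{1}{N}\sum_{i=1}^{N} c_i(m),}
#' with \eqn{c_i(m) = 0} when metabolite \eqn{m} is absent from model
#' \eqn{i}'s biomass. All input biomass reactions are removed; the new
#' biomass (bounds `[0, 1000]`) becomes the sole objective.
#'
#' When two inputs share a reaction id but disagree on stoichiometry or
#' bounds, the first occurrence is kept and the conflict is counted in a
#' single warning (id-keyed deduplication assumes a shared reaction
#' namespace, as in curated model collections).
#'
#' @param models List of valid [gem()]s (at least one).
#' @param merged_id Id for the merged model; also stems the new biomass id
#'   `biomass_<merged_id>` (deterministically renamed with a warning on
#'   collision).
#' @return A validated merged [gem()].
#' @examples
#' fam <- make_related_family(2, core_size = 4, variant_size = 2, seed = 1)
#' merged <- merge_models(fam, "fam")
#' length(merged$reactions)  # 4 + 2*2 unique + 1 new biomass
#' @export
merge_models <- function(models, merged_id) {
  assert_(is.list(models) && length(models) >= 1, "merge_models needs at least one model")
  purrr::walk(models, validate_gem)
  n <- length(models)

  mets <- dplyr::distinct(dplyr::bind_rows(purrr::map(models, "metabolites")),
                          .data$id, .keep_all = TRUE)

  rxns <- list()
  conflicts <- 0L
  for (mod in models) {
    for (r in mod$reactions) {
      if (r$is_biomass) next
      if (is.null(rxns[[r$id]])) {
        rxns[[r$id]] <- r
      } else {
        prev <- rxns[[r$id]]
        same <- isTRUE(all.equal(prev$stoichiometry[order(names(prev$stoichiometry))],
                                 r$stoichiometry[order(names(r$stoichiometry))])) &&
          prev$lower_bound == r$lower_bound && prev$upper_bound == r$upper_bound
        if (!same) conflicts <- conflicts + 1L
      }
    }
  }
  if (conflicts > 0) {
    rlang::warn(paste0("merge_models('", merged_id, "'): ", conflicts,
                       " reaction id collisions with differing definitions; first occurrence kept"))
  }

  # mean biomass coefficient vector over a common metabolite basis
  coef <- numeric(0)
  for (mod in models) {
    st <- mod$reactions[[mod$objective_id]]$stoichiometry
    for (m in names(st)) coef[m] <- (coef[m] %|na|% 0) + st[[m]]
  }
  coef <- coef / n

  bio_id <- paste0("biomass_", merged_id)
  if (!is.null(rxns[[bio_id]])) {
    new_id <- paste0(bio_id, "_merged")
    rlang::warn(paste0("merge_models: biomass id '", bio_id, "' collides with a reaction; using '",
                       new_id, "'"))
    bio_id <- new_id
  }
  rxns[[bio_id]] <- reaction(bio_id, coef, 0, 1000, is_exchange = FALSE, is_biomass = TRUE)
  gem(merged_id, mets, rxns, bio_id)
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Build pooled models for every group of a grouping scheme
#'
#' The pooled-model counterpart of [aggregate_abundances()]: one merged
#' model per group via [merge_models()], plus the group-level abundance
#' table. Together these are the inputs of a pooled ("pre" strategy)
#' community simulation.
#'
#' @param models Named list taxon_id -> [gem()].
#' @param table Abundance table (`sample_id`, `taxon_id`, `abundance`).
#' @param scheme A `grouping_scheme` over the table's taxa.
#' @return List with `models` (named list group_id -> merged gem) and
#'   `abundances` (group-level abundance table).
#' @export
build_phylogems <- function(models, table, scheme) {
  table <- as_abundance_table_(table)
  present <- unique(table$taxon_id[table$abundance > 0])
  missing <- setdiff(present, names(models))
  assert_(length(missing) == 0,
          paste0("no model available for taxa: ", paste(missing, collapse = ", ")))
  groups <- groups_as_list_(scheme)
  groups <- purrr::keep(groups, ~ length(intersect(.x, names(models))) > 0)
  merged <- purrr::imap(groups, function(members, gid) {
    merge_models(models[intersect(members, names(models))], gid)
  })
  list(models = merged, abundances = aggregate_abundances(table, scheme))
}
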