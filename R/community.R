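#' Build a compartmentalised community model
#'
#' Each member GEM is embedded with its metabolite and reaction ids
#' suffixed `"__<taxon>"`, its exchange reactions rewired into transfer
#' reactions against a shared extracellular pool, and the pool opened to
#' the environment through pool exchange reactions governed by the
#' medium. Member fluxes are per gram of member biomass; the pool side of
#' each transfer is scaled by the member's relative abundance `a_i`
#' (mass-weighted coupling), so pool balances are per gram of community
#' and the natural community objective is the abundance-weighted growth
#' `sum(a_i * mu_i)`.
#'
#' Pool metabolite ids are `<met>_m`; pool exchanges are `EX_<met>_m`. A
#' medium may address pool exchanges either by their pool id or by the
#' member-level exchange id they descend from (e.g. `EX_glc`). With
#' `medium = NULL` every pool exchange takes the widest member bound
#' (permissive default).
#'
#' @param models Named list taxon_id -> [gem()].
#' @param abundances Named numeric of relative abundances (any positive
#'   scale; renormalised), or a tibble with `taxon_id`, `abundance`.
#' @param medium Optional [medium()] for the pool exchanges.
#' @param abundance_cutoff Members below this relative abundance are
#'   dropped before renormalisation (default 1e-4).
#' @return A `community_model`: `members` (tibble taxon_id, abundance,
#'   biomass_id, model), `metabolites`, `reactions`, `medium`.
#' @export
build_community <- function(models, abundances, medium = NULL, abundance_cutoff = 1e-4) {
  if (is.data.frame(abundances)) {
    abundances <- stats::setNames(abundances$abundance, abundances$taxon_id)
  }
  assert_(is.numeric(abundances) && !is.null(names(abundances)),
          "abundances must be named (taxon_id -> fraction)")
  abundances <- abundances[abundances > 0]
  missing <- setdiff(names(abundances), names(models))
  assert_(length(missing) == 0,
          paste0("no model for community members: ", paste(missing, collapse = ", ")))
  a <- abundances / sum(abundances)
  a <- a[a >= abundance_cutoff]
  assert_(length(a) > 0, "empty community: all members below the abundance cutoff")
  a <- a / sum(a)

  mets <- list()
  rxns <- list()
  members <- tibble::tibble(taxon_id = names(a), abundance = as.numeric(a),
                            biomass_id = NA_character_,
                            model = unname(models[names(a)]))
  pool_seen <- character(0)
  alias <- character(0)   # pool exchange id -> member-level exchange id

  for (k in seq_len(nrow(members))) {
    taxon <- members$taxon_id[k]
    ai <- members$abundance[k]
    mod <- members$model[[k]]
    validate_gem(mod)
    sfx <- function(x) paste0(x, "__", taxon)
    mm <- mod$metabolites
    mm$id <- sfx(mm$id)
    mets[[taxon]] <- mm
    for (r in mod$reactions) {
      st <- stats::setNames(as.numeric(r$stoichiometry), sfx(names(r$stoichiometry)))
      if (r$is_exchange) {
        met <- exchange_met_(r)
        pool <- paste0(met, "_m")
        if (!pool %in% pool_seen) {
          pool_seen <- c(pool_seen, pool)
          mets[[pool]] <- tibble::tibble(id = pool, name = pool, compartment = "m")
          # pool exchange bound: widest member uptake unless a medium says otherwise
          plb <- if (is.null(medium)) r$lower_bound else 0
          rxns[[paste0("EX_", pool)]] <- reaction(paste0("EX_", pool),
                                                  stats::setNames(-1, pool),
                                                  plb, 1000, is_exchange = TRUE)
          alias[[paste0("EX_", pool)]] <- r$id
        } else if (is.null(medium)) {
          ex_id <- paste0("EX_", pool)
          rxns[[ex_id]]$lower_bound <- min(rxns[[ex_id]]$lower_bound, r$lower_bound)
        }
        # member transfer: member compartment <-> shared pool, a_i-scaled
        st[pool] <- ai
        rxns[[sfx(r$id)]] <- reaction(sfx(r$id), st, r$lower_bound, r$upper_bound,
                                      is_exchange = FALSE)
      } else {
        rxns[[sfx(r$id)]] <- reaction(sfx(r$id), st, r$lower_bound, r$upper_bound,
                                      is_exchange = FALSE, is_biomass = r$is_biomass)
      }
    }
    members$biomass_id[k] <- sfx(mod$objective_id)
  }

  cm <- structure(
    list(members = members,
         metabolites = dplyr::bind_rows(mets),
         reactions = rxns,
         exchange_alias = alias,
         medium = if (is.null(medium)) NULL else medium(medium)),
    class = "community_model"
  )
  cm
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", nrow(x$members), " members, ",
      length(x$reactions), " reactions, ",
      sum(x$metabolites$compartment == "m"), " pool metabolites\n", sep = "")
  print(tibble::as_tibble(x$members[, c("taxon_id", "abundance")]))
  invisible(x)
}

# assemble the LP pieces of a community model, applying its medium to the
# pool exchanges (member-level exchange ids are accepted as aliases)
community_lp_parts_ <- function(cm) {
  rxn_ids <- names(cm$reactions)
  met_ids <- cm$metabolites$id
  S <- matrix(0, length(met_ids), length(rxn_ids), dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(cm$reactions)) {
    st <- cm$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  lb <- vapply(cm$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(cm$reactions, `[[`, 0, "upper_bound")
  if (!is.null(cm$medium)) {
    med <- cm$medium
    for (id in names(cm$reactions)) {
      r <- cm$reactions[[id]]
      if (!r$is_exchange) next
      al <- cm$exchange_alias[[id]] %||% id          # member-level exchange id
      up <- if (id %in% names(med)) med[[id]] else if (al %in% names(med)) med[[al]] else 0
      lb[[id]] <- -up
      ub[[id]] <- max(ub[[id]], 0)
    }
  }
  bio_idx <- match(cm$members$biomass_id, rxn_ids)
  list(S = S, lb = lb, ub = ub, rxn_ids = rxn_ids, bio_idx = bio_idx)
}

growth_result_ <- function(cm, status, mu = NULL, method = NA_character_) {
  if (is.null(mu)) {
    return(structure(list(community_growth = NA_real_, member_growth = NULL,
                          status = status, method = method), class = "growth_result"))
  }
  mg <- tibble::tibble(taxon_id = cm$members$taxon_id,
                       abundance = cm$members$abundance,
                       growth_rate = as.numeric(mu))
  structure(list(community_growth = sum(mg$abundance * mg$growth_rate),
                 member_growth = mg, status = status, method = method),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat("<growth_result> status:", x$status, " method:", x$method, "\n")
  if (x$status == "optimal") {
    cat("  community growth:", signif(x$community_growth, 6), "\n")
    print(x$member_growth)
  }
  invisible(x)
}

#' Cooperative-tradeoff community growth
#'
#' Two-stage optimisation in the spirit of regularised community FBA:
#' stage 1 maximises the abundance-weighted community growth
#' `G = sum(a_i mu_i)`; stage 2 fixes `G >= tradeoff_fraction * G*` and
#' minimises `sum(mu_i^2)`, which distributes growth across members (the
#' unique L2 point on the optimal face, so results are deterministic).
#'
#' @param cm A `community_model`.
#' @param tradeoff_fraction Fraction of the stage-1 optimum the community
#'   must retain, in `(0, 1]`; default 1.
#' @return A `growth_result` with per-member growth rates `mu_i` and
#'   `community_growth = sum(a_i mu_i)`.
#' @export
cooperative_tradeoff <- function(cm, tradeoff_fraction = 1.0) {
  assert_(inherits(cm, "community_model"), "cm must be a community_model")
  assert_(tradeoff_fraction > 0 && tradeoff_fraction <= 1,
          "tradeoff_fraction must lie in (0, 1]")
  p <- community_lp_parts_(cm)
  w <- numeric(length(p$rxn_ids))
  w[p$bio_idx] <- cm$members$abundance
  s1 <- lp_solve_(w, p$S, rep(0, nrow(p$S)), p$lb, p$ub, maximize = TRUE)
  if (s1$status != "optimal") return(growth_result_(cm, s1$status, method = "cooperative_tradeoff"))
  gstar <- s1$objective

  s2 <- qp_l2_solve_(p$S, rep(0, nrow(p$S)), p$lb, p$ub, quad_idx = p$bio_idx,
                     extra = matrix(w, nrow = 1),
                     extra_rhs = tradeoff_fraction * gstar)
  if (s2$status != "optimal") {
    # fall back on the stage-1 vertex (still optimal, merely not L2-centred)
    return(growth_result_(cm, "optimal", s1$solution[p$bio_idx], "cooperative_tradeoff"))
  }
  growth_result_(cm, "optimal", s2$solution[p$bio_idx], "cooperative_tradeoff")
}

#' Summed-growth community optimisation
#'
#' Single-level surrogate for multi-objective community frameworks:
#' maximises the unweighted sum of member growth rates subject to
#' community stoichiometry, then resolves ties with a secondary L2
#' minimisation at the achieved sum so alternate optima cannot make
#' results run-dependent. `community_growth` is still reported as
#' `sum(a_i mu_i)`.
#'
#' @param cm A `community_model`.
#' @return A `growth_result`.
#' @export
community_fba_sum <- function(cm) {
  assert_(inherits(cm, "community_model"), "cm must be a community_model")
  p <- community_lp_parts_(cm)
  w <- numeric(length(p$rxn_ids))
  w[p$bio_idx] <- 1
  s1 <- lp_solve_(w, p$S, rep(0, nrow(p$S)), p$lb, p$ub, maximize = TRUE)
  if (s1$status != "optimal") return(growth_result_(cm, s1$status, method = "sum"))
  s2 <- qp_l2_solve_(p$S, rep(0, nrow(p$S)), p$lb, p$ub, quad_idx = p$bio_idx,
                     extra = matrix(w, nrow = 1), extra_rhs = s1$objective)
  mu <- if (s2$status == "optimal") s2$solution[p$bio_idx] else s1$solution[p$bio_idx]
  growth_result_(cm, "optimal", mu, "sum")
}

#' Simulate community growth
#'
#' @param cm A `community_model`.
#' @param method `"cooperative_tradeoff"` (default) or `"sum"`.
#' @param tradeoff_fraction Passed to [cooperative_tradeoff()].
#' @return A `growth_result`.
#' @export
community_growth <- function(cm, method = c("cooperative_tradeoff", "sum"),
                             tradeoff_fraction = 1.0) {
  method <- match.arg(method)
  switch(method,
         cooperative_tradeoff = cooperative_tradeoff(cm, tradeoff_fraction),
         sum = community_fba_sum(cm))
}

#' Remove one member and re-simulate
#'
#' The member is removed, remaining abundances are renormalised (set
#' `renormalize = FALSE` to keep the absolute abundances of the
#' survivors), and the chosen simulation is re-run on the reduced
#' community.
#'
#' @param cm A `community_model`.
#' @param taxon Member to knock out.
#' @param method,tradeoff_fraction As in [community_growth()].
#' @param renormalize Renormalise remaining abundances (default TRUE).
#' @return A `growth_result` covering the remaining members.
#' @export
knockout_taxon <- function(cm, taxon, method = c("cooperative_tradeoff", "sum"),
                           tradeoff_fraction = 1.0, renormalize = TRUE) {
  method <- match.arg(method)
  assert_(taxon %in% cm$members$taxon_id, paste0("'", taxon, "' is not a community member"))
  assert_(nrow(cm$members) > 1, "cannot knock out the last remaining member")
  keep <- cm$members[cm$members$taxon_id != taxon, ]
  ab <- stats::setNames(keep$abundance, keep$taxon_id)
  models <- stats::setNames(keep$model, keep$taxon_id)
  cm2 <- build_community(models, ab, medium = cm$medium, abundance_cutoff = 0)
  if (!renormalize) {
    # keep the survivors' original a_i both as weights and pool coupling
    cm2$members$abundance <- keep$abundance[match(cm2$members$taxon_id, keep$taxon_id)]
    cm2 <- rescale_coupling_(cm2)
  }
  community_growth(cm2, method, tradeoff_fraction)
}

# rewrite the pool-side coupling coefficients after a manual abundance edit
rescale_coupling_ <- function(cm) {
  for (k in seq_len(nrow(cm$members))) {
    taxon <- cm$members$taxon_id[k]
    ai <- cm$members$abundance[k]
    mod <- cm$members$model[[k]]
    for (r in mod$reactions) {
      if (!r$is_exchange) next
      id <- paste0(r$id, "__", taxon)
      pool <- paste0(exchange_met_(r), "_m")
      cm$reactions[[id]]$stoichiometry[[pool]] <- ai
    }
  }
  cm
}
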