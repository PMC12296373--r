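# Seeded generators for toy models, related-model families and
# multi-sample cohorts. These stand in for curated model databases and
# real metagenome cohorts: every generator is a pure function of its
# arguments and seed, and every generated model has a closed-form FBA
# optimum so solver output can be checked exactly.

#' Generate a linear-pathway toy GEM
#'
#' Builds a minimal growth model: each substrate `s` gets an exchange
#' `EX_<s>` (uptake bounded), a transport `T_<s>` into the cytosol and a
#' conversion `CV_<s>` producing biomass precursor at the stated yield.
#' The FBA optimum is therefore exactly `sum(uptake * yield)`. Declared
#' byproducts are coupled to the biomass reaction (one unit secreted per
#' unit growth), which makes cross-feeding fixtures deterministic.
#'
#' @param substrates Named list; each element `c(uptake = , yield = )`.
#'   Names become metabolite stems, so a byproduct named `"P"` in one
#'   model feeds a substrate named `"P"` in another.
#' @param byproducts Character vector of forced secretion products.
#' @param id Model id.
#' @param seed Unused source of randomness (the construction is fully
#'   deterministic); accepted for generator API symmetry.
#' @return A validated [gem()].
#' @examples
#' m <- make_toy_gem(substrates = list(S = c(uptake = 10, yield = 0.5)))
#' fba(m)$objective_value  # 5
#' @export
make_toy_gem <- function(substrates, byproducts = character(0), id = "toy", seed = NULL) {
  assert_(length(substrates) >= 1, "need at least one substrate")
  if (is.null(names(substrates)) || any(!nzchar(names(substrates)))) {
    names(substrates) <- paste0("S", seq_along(substrates))
  }
  mets <- list()
  rxns <- list()
  bio_met <- paste0("bio_", id, "_c")
  mets[[bio_met]] <- tibble::tibble(id = bio_met, compartment = "c")
  bio_st <- stats::setNames(-1, bio_met)

  for (s in names(substrates)) {
    sp <- substrates[[s]]
    up <- as.numeric(sp[["uptake"]]); yd <- as.numeric(sp[["yield"]])
    assert_(up >= 0 && yd > 0, paste0("substrate '", s, "': uptake >= 0 and yield > 0 required"))
    e <- paste0(s, "_e"); cc <- paste0(s, "_c")
    mets[[e]] <- tibble::tibble(id = e, compartment = "e")
    mets[[cc]] <- tibble::tibble(id = cc, compartment = "c")
    rxns <- c(rxns, list(
      reaction(paste0("EX_", s), stats::setNames(-1, e), -up, 1000),
      reaction(paste0("T_", s), stats::setNames(c(-1, 1), c(e, cc)), 0, 1000),
      reaction(paste0("CV_", s), stats::setNames(c(-1, yd), c(cc, bio_met)), 0, 1000)
    ))
  }
  for (p in byproducts) {
    e <- paste0(p, "_e"); cc <- paste0(p, "_c")
    mets[[e]] <- tibble::tibble(id = e, compartment = "e")
    mets[[cc]] <- tibble::tibble(id = cc, compartment = "c")
    bio_st[cc] <- 1
    rxns <- c(rxns, list(
      reaction(paste0("T_", p), stats::setNames(c(-1, 1), c(cc, e)), 0, 1000),
      reaction(paste0("EX_", p), stats::setNames(-1, e), 0, 1000)  # secretion only
    ))
  }
  rxns <- c(rxns, list(
    reaction(paste0("biomass_", id), bio_st, 0, 1000, is_biomass = TRUE)
  ))
  gem(id, dplyr::bind_rows(mets), rxns, paste0("biomass_", id))
}

# inert, mass-balanced filler reactions used to pad reaction sets without
# touching the growth pathway (their substrates have no source, so they
# are blocked and carry zero flux)
filler_rxns_ <- function(prefix, k, mets_acc) {
  out <- list(rxns = list(), mets = mets_acc)
  for (i in seq_len(k)) {
    a <- paste0(prefix, "_fa", i, "_c"); b <- paste0(prefix, "_fb", i, "_c")
    out$mets[[a]] <- tibble::tibble(id = a, compartment = "c")
    out$mets[[b]] <- tibble::tibble(id = b, compartment = "c")
    out$rxns <- c(out$rxns, list(
      reaction(paste0(prefix, "_f", i), stats::setNames(c(-1, 1), c(a, b)), 0, 1000)
    ))
  }
  out
}

#' Generate a family of structurally related GEMs
#'
#' Members share an identical core reaction set (an uptake/transport chain
#' for the family substrate plus inert core filler reactions) and each
#' carries its own variant set: a member-specific biomass-precursor
#' conversion whose yield is drawn from `yield_range`, plus inert variant
#' fillers. Consequences, exactly:
#' * pairwise Jaccard distance between members (biomass excluded) is
#'   `1 - core_size / (core_size + 2 * variant_size)`;
#' * each member's FBA optimum is `uptake * yield_member`;
#' * the merged family model unions to
#'   `core_size + n_members * variant_size` reactions plus one biomass.
#'
#' @param n_members Number of member models (>= 1).
#' @param core_size Shared reactions per member (>= 2: exchange+transport).
#' @param variant_size Unique reactions per member (>= 1: the conversion).
#' @param yield_range Length-2 numeric, biomass yield per substrate unit.
#' @param seed Integer seed for the yield draws.
#' @param id_prefix Family name stem; also names the family substrate.
#' @param uptake Substrate uptake bound shared by all members.
#' @return Named list of [gem()]s (names are member ids), with attributes
#'   `yields` (named numeric) and `substrate` (exchange id stem).
#' @export
make_related_family <- function(n_members, core_size = 10, variant_size = 5,
                                yield_range = c(0.3, 0.7), seed = 1,
                                id_prefix = "fam", uptake = 10) {
  assert_(n_members >= 1, "n_members must be >= 1")
  assert_(core_size >= 2, "core_size must be >= 2 (exchange + transport chain)")
  assert_(variant_size >= 1, "variant_size must be >= 1 (member conversion)")
  assert_(length(yield_range) == 2 && all(yield_range > 0), "yields must be positive")

  sub <- paste0("S", id_prefix)
  yields <- with_seed_(seed, stats::runif(n_members, yield_range[1], yield_range[2]))
  members <- stats::setNames(vector("list", n_members), paste0(id_prefix, "_g", seq_len(n_members)))
  yields <- stats::setNames(yields, names(members))

  e <- paste0(sub, "_e"); cc <- paste0(sub, "_c")
  bio_met <- paste0("bio_", id_prefix, "_c")
  core_mets <- list(
    tibble::tibble(id = e, compartment = "e"),
    tibble::tibble(id = cc, compartment = "c"),
    tibble::tibble(id = bio_met, compartment = "c")
  )
  core_rxns <- list(
    reaction(paste0("EX_", sub), stats::setNames(-1, e), -uptake, 1000),
    reaction(paste0("T_", sub), stats::setNames(c(-1, 1), c(e, cc)), 0, 1000)
  )
  core_fill <- filler_rxns_(paste0(id_prefix, "_core"), core_size - 2L,
                            stats::setNames(core_mets, c(e, cc, bio_met)))

  for (m in names(members)) {
    var_fill <- filler_rxns_(m, variant_size - 1L, core_fill$mets)
    rxns <- c(core_rxns, core_fill$rxns,
              list(reaction(paste0("CV_", m),
                            stats::setNames(c(-1, yields[[m]]), c(cc, bio_met)), 0, 1000)),
              var_fill$rxns,
              list(reaction(paste0("biomass_", m), stats::setNames(-1, bio_met),
                            0, 1000, is_biomass = TRUE)))
    members[[m]] <- gem(m, dplyr::bind_rows(var_fill$mets), rxns, paste0("biomass_", m))
  }
  attr(members, "yields") <- yields
  attr(members, "substrate") <- sub
  members
}

#' Generate a synthetic multi-sample cohort with planted group structure
#'
#' Emulates a metagenome cohort: `n_groups` families of
#' `members_per_group` genera, each family with its own limiting substrate
#' and a family-characteristic biomass yield (so genera within a family
#' are metabolically similar while families differ), per-sample relative
#' abundances drawn from a flat Dirichlet, and per-(sample, taxon)
#' replication rates planted to correlate with the taxa's achievable
#' growth at Pearson `planted_correlation`:
#' `rep = rho * z(growth) + sqrt(1 - rho^2) * N(0, 1) + N(0, noise_sd)`.
#'
#' The returned medium bounds each family substrate at a community-level
#' uptake of 1 mmol/(g community)/h, which is limiting for typical
#' abundances; growth predictions therefore respond to the abundance
#' vector, which is what the sensitivity analysis perturbs.
#'
#' @param n_samples,n_groups,members_per_group Cohort dimensions.
#' @param planted_correlation Target Pearson in `[-1, 1]`.
#' @param noise_sd Extra measurement noise on replication rates.
#' @param seed Integer master seed.
#' @return List with `models` (named list of gems), `abundances`
#'   (tibble sample_id/taxon_id/abundance), `taxonomy` (tibble taxon_id/
#'   order/family/genus), `replication` (tibble sample_id/unit_id/value)
#'   and `medium`.
#' @export
make_cohort <- function(n_samples = 20, n_groups = 5, members_per_group = 3,
                        planted_correlation = 0.8, noise_sd = 0, seed = 1) {
  assert_(abs(planted_correlation) <= 1, "planted_correlation must lie in [-1, 1]")
  rho <- planted_correlation
  fam_ids <- paste0("fam", seq_len(n_groups))

  theta <- with_seed_(derive_seed_(seed, 1), stats::runif(n_groups, 0.2, 0.9))
  families <- purrr::imap(stats::setNames(fam_ids, fam_ids), function(f, nm) {
    i <- match(f, fam_ids)
    make_related_family(members_per_group, core_size = 6, variant_size = 2,
                        yield_range = theta[i] * c(0.9, 1.1),
                        seed = derive_seed_(seed, 2, i), id_prefix = f)
  })
  models <- purrr::flatten(unname(families))
  names(models) <- unlist(purrr::map(families, names))

  taxonomy <- dplyr::bind_rows(purrr::imap(families, function(fam, f) {
    tibble::tibble(taxon_id = names(fam), order = "ord1", family = f, genus = names(fam))
  }))

  # solo achievable growth of each genus: uptake x yield
  growth <- unlist(unname(purrr::map(families, ~ attr(.x, "yields")))) * 10
  stopifnot(identical(names(growth), names(models)))

  samples <- paste0("s", seq_len(n_samples))
  abundances <- dplyr::bind_rows(purrr::map(seq_len(n_samples), function(si) {
    w <- with_seed_(derive_seed_(seed, 3, si), stats::rgamma(length(models), shape = 1))
    tibble::tibble(sample_id = samples[si], taxon_id = names(models),
                   abundance = w / sum(w))
  }))

  z <- as.numeric(scale(growth))
  replication <- dplyr::bind_rows(purrr::map(seq_len(n_samples), function(si) {
    eps <- with_seed_(derive_seed_(seed, 4, si), stats::rnorm(length(growth)))
    extra <- if (noise_sd > 0) {
      with_seed_(derive_seed_(seed, 5, si), stats::rnorm(length(growth), sd = noise_sd))
    } else 0
    tibble::tibble(sample_id = samples[si], unit_id = names(growth),
                   value = rho * z + sqrt(max(0, 1 - rho^2)) * eps + extra)
  }))

  med <- medium(stats::setNames(rep(1, n_groups),
                                paste0("EX_S", fam_ids)))
  list(models = models, abundances = abundances, taxonomy = taxonomy,
       replication = replication, medium = med)
}

#' The four-member synthetic community benchmark
#'
#' Published observations for a four-species synthetic community
#' (Pedobacter sp., Rhodococcus globerulus, Stenotrophomonas indicatrix,
#' Chryseobacterium sp.): relative abundances (percent) on three sampling
#' days, experimentally derived growth rates, and the growth-rate
#' prediction columns of the standard and phylogenetically pooled variants
#' of two community simulators. Used as a worked example for correlation
#' checks; all numbers are as printed in the source study.
#'
#' @return List with `abundance` (tibble species x day, percent),
#'   `experimental` (named numeric), and `predictions` (tibble with
#'   columns micom, phylo_micom, optcom, phylo_optcom).
#' @export
syncom_fixture <- function() {
  species <- c("Pedobacter", "R_globerulus", "S_indicatrix", "Chryseobacterium")
  list(
    abundance = tibble::tibble(
      species = species,
      day1 = c(9.95, 11.12, 71.19, 7.74),
      day2 = c(4.77, 9.5, 76.02, 9.71),
      day3 = c(0.04, 22.53, 68.96, 8.47)
    ),
    experimental = stats::setNames(c(-4.955, 5.705, -1.115, 0.365), species),
    predictions = tibble::tibble(
      species = species,
      micom = c(82.67, 0, 0, 0),
      phylo_micom = c(0, 10.24, 10.24, 0),
      optcom = c(110.99, 111.64, 83.70, 64.121),
      phylo_optcom = c(0, 10.25, 10.25, 0)
    )
  )
}
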