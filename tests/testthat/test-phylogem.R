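# Grouping schemes, abundance aggregation and model merging.

test_that("group_by_rank partitions taxa by their lineage", {
  tax <- tibble::tibble(
    taxon_id = c("sp1", "sp2", "sp3", "sp4"),
    order = rep("o1", 4),
    family = c("f1", "f1", "f2", "f2")
  )
  s <- group_by_rank(tax, "family")
  expect_equal(groups_in_scheme(s), list(f1 = c("sp1", "sp2"), f2 = c("sp3", "sp4")))

  # one group when every taxon shares the rank value
  s2 <- group_by_rank(tax, "order")
  expect_length(unique(s2$group_id), 1)
  expect_setequal(s2$taxon_id, tax$taxon_id)

  # missing rank names the offending taxon
  tax$family[2] <- NA
  expect_error(group_by_rank(tax, "family"), "sp2")
  expect_error(group_by_rank(tax, "genus"), "not present")

  # the synthetic cohort taxonomy reproduces its planted families
  co <- make_cohort(n_samples = 2, n_groups = 3, members_per_group = 2, seed = 5)
  s3 <- group_by_rank(co$taxonomy, "family")
  expect_equal(sort(unique(s3$group_id)), paste0("fam", 1:3))
  expect_equal(unname(vapply(groups_in_scheme(s3), length, 0L)), rep(2L, 3))
  expect_true(all(startsWith(s3$taxon_id, s3$group_id)))
})

test_that("group_by_distance takes threshold components (single linkage)", {
  sim <- matrix(c(1, 0.7, 0.2,
                  0.7, 1, 0.7,
                  0.2, 0.7, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  s <- group_by_distance(sim, threshold = 0.6)
  expect_length(unique(s$group_id), 1)   # a-b-c chained through b

  # complete linkage refuses the chain
  s2 <- group_by_distance(sim, threshold = 0.6, linkage = "complete")
  expect_length(unique(s2$group_id), 2)

  # threshold above all off-diagonals: all singletons
  s3 <- group_by_distance(sim, threshold = 0.8)
  expect_length(unique(s3$group_id), 3)

  # threshold 0 merges everything
  s4 <- group_by_distance(sim, threshold = 0)
  expect_length(unique(s4$group_id), 1)

  expect_error(group_by_distance(sim, threshold = 1.2), "\\[0, 1\\]")
  asym <- sim; asym[1, 2] <- 0.9
  expect_error(group_by_distance(asym), "symmetric")
})

test_that("group_manual merges listed sets and leaves the rest singleton", {
  taxa <- c("ped", "rho", "ste", "chr")
  s <- group_manual(taxa, list(c("rho", "ste")))
  expect_length(unique(s$group_id), 3)
  merged_grp <- s$group_id[s$taxon_id == "rho"]
  expect_equal(s$group_id[s$taxon_id == "ste"], merged_grp)

  expect_equal(unique(group_manual(taxa, list())$group_id), taxa)
  expect_error(group_manual(taxa, list(c("rho", "nope"))), "unknown taxa")
  expect_error(group_manual(taxa, list(c("rho", "ste"), c("ste", "chr"))), "disjoint")
})

test_that("random_grouping preserves group sizes and is seed-reproducible", {
  taxa <- paste0("t", 1:6)
  template <- grouping_scheme(tibble::tibble(
    taxon_id = taxa, group_id = c("g1", "g1", "g1", "g2", "g2", "g3")
  ))
  sizes0 <- sort(unname(vapply(groups_in_scheme(template), length, 0L)))
  for (seed in 1:100) {
    r <- random_grouping(taxa, template, seed)
    expect_equal(sort(unname(vapply(groups_in_scheme(r), length, 0L))), sizes0)
  }
  expect_identical(random_grouping(taxa, template, 42),
                   random_grouping(taxa, template, 42))

  # all-singleton template: same partition back
  singles <- grouping_scheme(tibble::tibble(taxon_id = taxa, group_id = taxa))
  r <- random_grouping(taxa, singles, 7)
  expect_equal(unname(vapply(groups_in_scheme(r), length, 0L)), rep(1L, 6))

  # over many seeds assignments are roughly uniform: t1 shares a group
  # with each other taxon about equally often
  mates <- character(0)
  for (seed in 1:300) {
    r <- random_grouping(taxa, template, seed)
    g1 <- r$group_id[r$taxon_id == "t1"]
    mates <- c(mates, setdiff(r$taxon_id[r$group_id == g1], "t1"))
  }
  tab <- table(factor(mates, levels = paste0("t", 2:6)))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("aggregate_abundances sums members and preserves sample totals", {
  tab <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    taxon_id = rep(c("a", "b", "c"), 2),
    abundance = c(0.2, 0.3, 0.5, 0.1, 0.1, 0.8)
  )
  s <- grouping_scheme(tibble::tibble(taxon_id = c("a", "b", "c"),
                                      group_id = c("g", "g", "c")))
  out <- aggregate_abundances(tab, s)
  expect_equal(out$abundance[out$sample_id == "s1" & out$taxon_id == "g"], 0.5)

  # singleton scheme: unchanged values
  singles <- grouping_scheme(tibble::tibble(taxon_id = c("a", "b", "c"),
                                            group_id = c("a", "b", "c")))
  same <- aggregate_abundances(tab, singles)
  expect_equal(dplyr::arrange(same, sample_id, taxon_id),
               dplyr::arrange(tab, sample_id, taxon_id))

  # totals preserved exactly for random tables and random schemes
  for (seed in 1:20) {
    set.seed(seed)
    tab2 <- tibble::tibble(
      sample_id = rep(paste0("s", 1:3), each = 10),
      taxon_id = rep(paste0("t", 1:10), 3),
      abundance = stats::runif(30)
    )
    sch <- grouping_scheme(tibble::tibble(
      taxon_id = paste0("t", 1:10),
      group_id = paste0("g", sample(3, 10, replace = TRUE))
    ))
    agg <- aggregate_abundances(tab2, sch)
    t0 <- tapply(tab2$abundance, tab2$sample_id, sum)
    t1 <- tapply(agg$abundance, agg$sample_id, sum)
    expect_equal(as.numeric(t1[names(t0)]), as.numeric(t0), tolerance = 1e-12)
  }

  expect_error(aggregate_abundances(tab, grouping_scheme(
    tibble::tibble(taxon_id = c("a", "b"), group_id = c("g", "g")))),
    "missing from the grouping scheme")
})

test_that("merge_models averages biomass coefficients over a common basis", {
  mets <- tibble::tibble(id = c("X", "Y", "S_e"), compartment = c("c", "c", "e"))
  mk <- function(id, bio) {
    gem(id, mets, list(
      reaction("EX_S", c(S_e = -1), -10, 1000),
      reaction(paste0("fill_", id), c(S_e = -1, X = 1), 0, 1000),
      reaction(paste0("biomass_", id), bio, 0, 1000, is_biomass = TRUE)
    ), paste0("biomass_", id))
  }
  mA <- mk("A", c(X = -1))
  mB <- mk("B", c(X = -3, Y = -1))
  merged <- merge_models(list(mA, mB), "AB")
  st <- merged$reactions[[merged$objective_id]]$stoichiometry
  expect_equal(st[["X"]], -2)
  expect_equal(st[["Y"]], -0.5)
  expect_equal(merged$reactions[[merged$objective_id]]$lower_bound, 0)
  expect_equal(merged$reactions[[merged$objective_id]]$upper_bound, 1000)

  # N = 1: averaging is the identity
  m1 <- merge_models(list(mA), "solo")
  expect_equal(m1$reactions[[m1$objective_id]]$stoichiometry, c(X = -1))

  expect_error(merge_models(list(), "none"), "at least one")
})

test_that("merging identical models changes nothing that matters", {
  m <- chain_gem()
  for (n in c(2, 4)) {
    merged <- merge_models(rep(list(m), n), "copies")
    # same non-biomass reaction set, same biomass coefficients
    expect_setequal(reaction_set(merged), reaction_set(m))
    expect_equal(merged$reactions[[merged$objective_id]]$stoichiometry,
                 m$reactions[[m$objective_id]]$stoichiometry)
    expect_equal(fba(merged)$objective_value, fba(m)$objective_value,
                 tolerance = 1e-6)
  }
})

test_that("merged reaction set is the id-union plus one new biomass", {
  fam <- make_related_family(3, core_size = 7, variant_size = 4, seed = 9)
  merged <- merge_models(fam, "fam")
  union_ids <- unique(unlist(purrr::map(fam, reaction_set)))
  expect_setequal(reaction_set(merged), union_ids)
  expect_length(merged$reactions, 7 + 3 * 4 + 1)
  expect_lte(length(merged$reactions),
             sum(vapply(fam, function(g) length(g$reactions), 0L)))

  # conflicting duplicate definitions: first occurrence wins, with warning
  m1 <- chain_gem(10, 0.5, id = "c1")
  m2 <- chain_gem(10, 0.9, id = "c1")   # same reaction ids, other yield
  expect_warning(mm <- merge_models(list(m1, m2), "cc"), "collisions")
  expect_equal(fba(mm)$objective_value, 5, tolerance = 1e-6)
})

test_that("build_phylogems yields one merged model per group plus pooled abundances", {
  co <- make_cohort(n_samples = 3, n_groups = 2, members_per_group = 3, seed = 2)
  scheme <- group_by_rank(co$taxonomy, "family")
  pg <- build_phylogems(co$models, co$abundances, scheme)
  expect_length(pg$models, 2)
  expect_lte(length(pg$models), length(co$models))
  expect_setequal(unique(pg$abundances$taxon_id), names(pg$models))

  # group-level totals match taxon-level totals per sample
  t0 <- tapply(co$abundances$abundance, co$abundances$sample_id, sum)
  t1 <- tapply(pg$abundances$abundance, pg$abundances$sample_id, sum)
  expect_equal(as.numeric(t1[names(t0)]), as.numeric(t0), tolerance = 1e-12)

  # singleton scheme: merged models behave like the originals
  singles <- grouping_scheme(tibble::tibble(taxon_id = names(co$models),
                                            group_id = names(co$models)))
  pgs <- build_phylogems(co$models, co$abundances, singles)
  for (tx in names(co$models)[1:2]) {
    expect_setequal(reaction_set(pgs$models[[tx]]), reaction_set(co$models[[tx]]))
    expect_equal(fba(pgs$models[[tx]])$objective_value,
                 fba(co$models[[tx]])$objective_value, tolerance = 1e-6)
  }

  expect_error(build_phylogems(co$models[-1], co$abundances, scheme), "no model")
})
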