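# Community construction and the two growth strategies.

test_that("community structure carries suffixes, pool coupling and normalised abundances", {
  cm <- independent_community()
  expect_s3_class(cm, "community_model")
  expect_equal(sum(cm$members$abundance), 1, tolerance = 1e-12)
  member_rxns <- grep("__", names(cm$reactions), value = TRUE)
  expect_true(all(grepl("__(A|B)$", member_rxns)))

  # each member extracellular metabolite connects to exactly one pool met
  pool_mets <- cm$metabolites$id[cm$metabolites$compartment == "m"]
  expect_setequal(pool_mets, c("SA_e_m", "SB_e_m"))
  tr <- cm$reactions[["EX_SA__A"]]
  expect_equal(tr$stoichiometry[["SA_e_m"]], 0.6)  # a_i-scaled pool coupling

  # abundance cutoff drops trace members, rest renormalised
  mA <- make_toy_gem(substrates = list(SA = c(uptake = 10, yield = 0.5)), id = "cutA")
  mB <- make_toy_gem(substrates = list(SB = c(uptake = 8, yield = 0.25)), id = "cutB")
  cm2 <- build_community(list(A = mA, B = mB), c(A = 1, B = 1e-6),
                         abundance_cutoff = 1e-4)
  expect_equal(cm2$members$taxon_id, "A")
  expect_equal(cm2$members$abundance, 1)
  expect_error(build_community(list(A = mA), c(A = 0)), "empty community")
})

test_that("a single-member community equals the solo model", {
  m <- chain_gem()
  cm <- build_community(list(solo = m), c(solo = 1))
  expect_growth_equal(cooperative_tradeoff(cm, 1.0), 5)
  expect_growth_equal(community_fba_sum(cm), 5)
  # below fraction 1 the L2 stage settles exactly on the constraint
  for (fr in c(0.5, 0.1)) {
    expect_growth_equal(cooperative_tradeoff(cm, fr), fr * 5)
  }
})

test_that("members with disjoint substrates grow at their solo optima", {
  cm <- independent_community()
  res <- cooperative_tradeoff(cm)
  mu <- stats::setNames(res$member_growth$growth_rate, res$member_growth$taxon_id)
  expect_equal(mu[["A"]], 5, tolerance = 1e-6)
  expect_equal(mu[["B"]], 2, tolerance = 1e-6)
  expect_equal(res$community_growth, 0.6 * 5 + 0.4 * 2, tolerance = 1e-6)

  rs <- community_fba_sum(cm)
  expect_growth_equal(rs, c(5, 2))
})

test_that("growth results satisfy their invariants", {
  for (cm in list(independent_community(), shared_substrate_community(),
                  cross_feeding_community())) {
    for (res in list(cooperative_tradeoff(cm), community_fba_sum(cm))) {
      expect_equal(res$community_growth,
                   sum(res$member_growth$abundance * res$member_growth$growth_rate),
                   tolerance = 1e-6)
      expect_true(all(res$member_growth$growth_rate >= -1e-9))
    }
  }
})

test_that("cooperative tradeoff attains the stage-1 optimum and splits by L2", {
  cm <- shared_substrate_community()  # equal members, pool 10, yield 0.5
  res <- cooperative_tradeoff(cm, 1.0)
  # oracle: grid search over allocations of the shared pool
  oracle <- l2_split_oracle(c(0.5, 0.5), pool_uptake = 10,
                            member_uptake = 20, yield = 0.5)
  expect_equal(res$community_growth, oracle$G, tolerance = 1e-6)
  expect_equal(sort(res$member_growth$growth_rate), sort(oracle$mu), tolerance = 1e-4)
  # symmetric members: both at the community optimum
  expect_equal(res$member_growth$growth_rate, c(5, 5), tolerance = 1e-4)

  # lowering the fraction never raises community growth above G* and
  # never loses feasibility
  for (fr in c(0.8, 0.5, 0.2)) {
    r2 <- cooperative_tradeoff(cm, fr)
    expect_equal(r2$status, "optimal")
    expect_lte(r2$community_growth, res$community_growth + 1e-6)
    expect_gte(r2$community_growth, fr * res$community_growth - 1e-6)
  }
  expect_error(cooperative_tradeoff(cm, 0), "\\(0, 1\\]")
})

test_that("asymmetric shared-substrate allocation matches the closed form", {
  # a = (0.8, 0.2), pool U = 10, member bound 15, yield 0.5:
  # stage 1: G* = 0.5 * U * yield-normalised = 5 (all pool consumed);
  # stage 2 unconstrained L2 point mu = G* * a / ||a||^2 = 5*(.8,.2)/.68
  cm <- shared_substrate_community(a = c(x = 0.8, y = 0.2), pool_uptake = 10,
                                   member_uptake = 15, yield = 0.5)
  res <- cooperative_tradeoff(cm)
  mu <- stats::setNames(res$member_growth$growth_rate, res$member_growth$taxon_id)
  expect_equal(res$community_growth, 5, tolerance = 1e-6)
  expect_equal(mu[["x"]], 5 * 0.8 / 0.68, tolerance = 1e-4)
  expect_equal(mu[["y"]], 5 * 0.2 / 0.68, tolerance = 1e-4)
})

test_that("summed-growth strategy is deterministic under degeneracy", {
  cm <- shared_substrate_community()   # symmetric alternate optima
  r1 <- community_fba_sum(cm)
  r2 <- community_fba_sum(cm)
  expect_identical(r1$member_growth, r2$member_growth)
  # L2 tie-break picks the symmetric point
  expect_equal(r1$member_growth$growth_rate[1], r1$member_growth$growth_rate[2],
               tolerance = 1e-4)
})

test_that("knockouts renormalise and re-simulate the remainder", {
  # independent resources with non-binding pools: knockout changes nothing
  cm <- independent_community()
  mu0 <- cooperative_tradeoff(cm)$member_growth
  res <- knockout_taxon(cm, "A")
  expect_equal(res$member_growth$taxon_id, "B")
  expect_equal(res$member_growth$growth_rate,
               mu0$growth_rate[mu0$taxon_id == "B"], tolerance = 1e-6)

  # shared limited substrate, minor member: knocking out the dominant
  # competitor frees pool; closed-form survivor growth 0.5*min(15, 10) = 5
  cms <- shared_substrate_community(a = c(x = 0.8, y = 0.2), pool_uptake = 10,
                                    member_uptake = 15, yield = 0.5)
  mu_y0 <- cooperative_tradeoff(cms)$member_growth$growth_rate[2]
  ko <- knockout_taxon(cms, "x")
  expect_equal(ko$member_growth$growth_rate, 5, tolerance = 1e-6)
  expect_gt(ko$member_growth$growth_rate, mu_y0)

  # cross-feeding: the eater collapses without its feeder
  cmx <- cross_feeding_community()
  kox <- knockout_taxon(cmx, "a")
  expect_equal(kox$member_growth$taxon_id, "b")
  expect_equal(kox$member_growth$growth_rate, 0, tolerance = 1e-6)

  expect_error(knockout_taxon(cm, "nope"), "not a community member")
  solo <- build_community(list(s = chain_gem()), c(s = 1))
  expect_error(knockout_taxon(solo, "s"), "last remaining member")
})

test_that("pooled community member count equals group count", {
  co <- make_cohort(n_samples = 1, n_groups = 3, members_per_group = 3, seed = 4)
  scheme <- group_by_rank(co$taxonomy, "family")
  pg <- build_phylogems(co$models, co$abundances, scheme)
  df <- pg$abundances[pg$abundances$sample_id == "s1", ]
  cm <- build_community(pg$models, stats::setNames(df$abundance, df$taxon_id),
                        medium = co$medium)
  expect_equal(nrow(cm$members), 3)
  expect_lt(nrow(cm$members), length(co$models))
})

test_that("merging N identical taxa reproduces the unmerged community growth", {
  m <- chain_gem(10, 0.5, id = "same")
  models <- list(t1 = m, t2 = m, t3 = m)
  ab <- c(t1 = 1, t2 = 1, t3 = 1) / 3
  med <- medium(c(EX_Ssame = 10))
  unmerged <- cooperative_tradeoff(build_community(models, ab, med))

  scheme <- group_manual(names(models), list(names(models)))
  merged_model <- merge_models(models, unique(scheme$group_id))
  merged <- cooperative_tradeoff(
    build_community(stats::setNames(list(merged_model), unique(scheme$group_id)),
                    stats::setNames(1, unique(scheme$group_id)), med))
  expect_equal(merged$community_growth, unmerged$community_growth, tolerance = 1e-6)
})
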