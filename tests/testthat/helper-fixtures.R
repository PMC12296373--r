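# Shared fixtures, all built in code. Growth values cited in the tests
# are closed forms of the linear-pathway construction: a chain model's
# optimum is sum(uptake * yield), and community allocations on a limited
# pool follow the L2 distribution over the optimal face (derivations in
# the comments where used).

chain_gem <- function(uptake = 10, yield = 0.5, id = "chain") {
  make_toy_gem(substrates = stats::setNames(list(c(uptake = uptake, yield = yield)),
                                            paste0("S", id)),
               id = id)
}

two_substrate_gem <- function(id = "two") {
  make_toy_gem(substrates = list(A = c(uptake = 10, yield = 0.5),
                                 B = c(uptake = 8, yield = 0.25)),
               id = id)
}

# two identical members on one shared, pool-limited substrate
shared_substrate_community <- function(a = c(x = 0.5, y = 0.5), pool_uptake = 10,
                                       member_uptake = 20, yield = 0.5) {
  m <- make_toy_gem(substrates = list(S = c(uptake = member_uptake, yield = yield)),
                    id = "sharer")
  build_community(list(x = m, y = m), a, medium = medium(c(EX_S = pool_uptake)))
}

# a feeds b: b's only substrate is a's growth-coupled byproduct
cross_feeding_community <- function() {
  ma <- make_toy_gem(substrates = list(SA = c(uptake = 10, yield = 0.5)),
                     byproducts = "P", id = "feeder")
  mb <- make_toy_gem(substrates = list(P = c(uptake = 10, yield = 0.3)), id = "eater")
  build_community(list(a = ma, b = mb), c(a = 0.5, b = 0.5),
                  medium = medium(c(EX_SA = 10, EX_P = 0)))
}

# fully independent resources, media generous enough never to bind
independent_community <- function() {
  ma <- make_toy_gem(substrates = list(SA = c(uptake = 10, yield = 0.5)), id = "indA")
  mb <- make_toy_gem(substrates = list(SB = c(uptake = 8, yield = 0.25)), id = "indB")
  build_community(list(A = ma, B = mb), c(A = 0.6, B = 0.4),
                  medium = medium(c(EX_SA = 10, EX_SB = 8)))
}

# independent oracle for the two-stage community solve on ONE shared
# substrate with equal yields: stage 1 gives total pool-limited biomass;
# stage 2 minimises sum(mu^2) over allocations by grid search
l2_split_oracle <- function(abund, pool_uptake, member_uptake, yield, step = 1e-3) {
  # allocation t = member x's uptake flux; y takes the rest of the pool
  ts <- seq(0, min(member_uptake, pool_uptake / abund[1]), by = step)
  best <- NULL
  for (t in ts) {
    rest <- (pool_uptake - abund[1] * t) / abund[2]
    if (rest < -1e-12) next
    v2 <- min(member_uptake, rest)
    mu <- yield * c(t, v2)
    G <- sum(abund * mu)
    cand <- list(mu = mu, G = G, obj = sum(mu^2))
    if (is.null(best) || G > best$G + 1e-9 ||
        (abs(G - best$G) <= 1e-9 && cand$obj < best$obj)) best <- cand
  }
  best
}

expect_growth_equal <- function(res, expected, tol = 1e-6) {
  expect_equal(res$status, "optimal")
  expect_equal(sort(res$member_growth$growth_rate), sort(unname(expected)),
               tolerance = tol)
}
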