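# GEM data model, I/O and constraint-based primitives.

test_that("gem construction enforces the model invariants", {
  m <- chain_gem()
  expect_s3_class(m, "gem")
  expect_invisible(validate_gem(m))

  # objective must exist and be the unique biomass-flagged reaction
  bad <- m
  bad$objective_id <- "EX_Schain"
  expect_error(validate_gem(bad), "is_biomass")
  bad2 <- m
  bad2$objective_id <- "nope"
  expect_error(validate_gem(bad2), "no biomass objective")

  # stoichiometry must reference declared metabolites
  expect_error(
    gem("g", tibble::tibble(id = "a_c", compartment = "c"),
        list(reaction("r1", c(a_c = -1, ghost = 1), 0, 1, is_biomass = TRUE)),
        "r1"),
    "unknown metabolites"
  )
  # bounds must be ordered
  expect_error(reaction("r", c(a = -1), 5, 1), "lower_bound <= upper_bound")
})

test_that("FBA solves chain models to their closed-form optimum", {
  expect_equal(fba(chain_gem(10, 0.5))$objective_value, 5, tolerance = 1e-6)
  expect_equal(fba(two_substrate_gem())$objective_value, 7, tolerance = 1e-6)

  # all uptakes closed, no internal source: zero growth
  m <- two_substrate_gem()
  shut <- medium(c(EX_A = 0, EX_B = 0))
  expect_equal(fba(m, shut)$objective_value, 0, tolerance = 1e-9)

  # medium restricting to one substrate
  expect_equal(fba(m, medium(c(EX_A = 10)))$objective_value, 5, tolerance = 1e-6)

  # closed form holds across random chain parameters
  for (i in 1:25) {
    up <- stats::runif(1, 0, 20)
    yd <- stats::runif(1, 0.05, 2)
    expect_equal(fba(chain_gem(up, yd, id = "r"))$objective_value, up * yd,
                 tolerance = 1e-6)
  }

  # fluxes respect their bounds at the optimum
  fl <- fba(m)$fluxes
  lb <- vapply(m$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(m$reactions, `[[`, 0, "upper_bound")
  expect_true(all(fl >= lb - 1e-6 & fl <= ub + 1e-6))
})

test_that("FBA objective is invariant under reaction reordering and round-trips", {
  m <- two_substrate_gem()
  opt <- fba(m)$objective_value
  perm <- m
  perm$reactions <- perm$reactions[rev(seq_along(perm$reactions))]
  expect_equal(fba(perm)$objective_value, opt, tolerance = 1e-9)

  tf <- withr::local_tempfile(fileext = ".xml")
  write_gem(m, tf)
  expect_equal(fba(read_gem(tf))$objective_value, opt, tolerance = 1e-9)
})

test_that("FVA brackets fluxes correctly", {
  m <- two_substrate_gem()
  opt <- fba(m)$objective_value

  # the objective pinched at fraction 1
  r <- fva(m, reaction_ids = "biomass_two", fraction_of_optimum = 1)
  expect_equal(r$min, opt, tolerance = 1e-6)
  expect_equal(r$max, opt, tolerance = 1e-6)

  # dead-end (filler) reactions are blocked: range (0, 0)
  fam <- make_related_family(1, core_size = 4, variant_size = 2, seed = 1)
  filler <- grep("_f[0-9]+$", names(fam[[1]]$reactions), value = TRUE)
  rf <- fva(fam[[1]], reaction_ids = filler, fraction_of_optimum = 0)
  expect_true(all(abs(rf$min) < 1e-9 & abs(rf$max) < 1e-9))

  # a branch point between two equivalent conversions spans the full
  # attainable range (uptake-limited, 0..10) at fraction 0
  mets <- tibble::tibble(id = c("S_e", "S_c", "bio_c"), compartment = c("e", "c", "c"))
  branch <- gem("branch", mets, list(
    reaction("EX_S", c(S_e = -1), -10, 1000),
    reaction("T_S", c(S_e = -1, S_c = 1), 0, 1000),
    reaction("CV_A", c(S_c = -1, bio_c = 0.5), 0, 1000),
    reaction("CV_B", c(S_c = -1, bio_c = 0.5), 0, 1000),
    reaction("biomass_b", c(bio_c = -1), 0, 1000, is_biomass = TRUE)
  ), "biomass_b")
  rb <- fva(branch, reaction_ids = c("CV_A", "CV_B"), fraction_of_optimum = 0)
  expect_equal(rb$min, c(0, 0), tolerance = 1e-9)
  expect_equal(rb$max, c(10, 10), tolerance = 1e-6)

  # min <= max always, and both attainable under the growth constraint
  all_r <- fva(m, fraction_of_optimum = 0.5)
  expect_true(all(all_r$min <= all_r$max + 1e-9))
})

test_that("blocked exchange metabolites are exactly the planted dead ends", {
  base <- make_toy_gem(substrates = list(S = c(uptake = 10, yield = 0.5)),
                       byproducts = "P", id = "bl")
  mets <- dplyr::bind_rows(
    base$metabolites,
    tibble::tibble(id = c("D1_e", "D2_e"), name = c("D1_e", "D2_e"),
                   compartment = c("e", "e"))
  )
  rxns <- c(base$reactions, list(
    reaction("EX_D1", c(D1_e = -1), -10, 1000),
    reaction("EX_D2", c(D2_e = -1), -10, 1000)
  ))
  m <- gem("bl", mets, rxns, base$objective_id)

  blocked <- find_blocked_exchanges(m)
  expect_setequal(blocked, c("D1_e", "D2_e"))

  # subset of extracellular metabolites by construction
  extra <- m$metabolites$id[m$metabolites$compartment == "e"]
  expect_true(all(blocked %in% extra))

  # a fully coupled single-pathway model has none
  expect_length(find_blocked_exchanges(chain_gem()), 0)
})

test_that("SBML and JSON round-trips preserve structure", {
  m <- two_substrate_gem()
  for (ext in c(".xml", ".json")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_gem(m, tf)
    back <- read_gem(tf)
    expect_equal(back[names(back)], m[names(m)])
  }

  # unicode names survive
  mu <- chain_gem(id = "uni")
  mu$metabolites$name[1] <- "biomasse élevée β"
  tf <- withr::local_tempfile(fileext = ".xml")
  write_gem(mu, tf)
  expect_equal(read_gem(tf)$metabolites$name[1], mu$metabolites$name[1])

  # merged model round-trips with averaged biomass coefficients intact
  fam <- make_related_family(3, core_size = 5, variant_size = 2, seed = 3)
  merged <- merge_models(fam, "famX")
  tf2 <- withr::local_tempfile(fileext = ".json")
  write_gem(merged, tf2)
  back <- read_gem(tf2)
  st0 <- merged$reactions[[merged$objective_id]]$stoichiometry
  st1 <- back$reactions[[back$objective_id]]$stoichiometry
  expect_equal(st1[sort(names(st1))], st0[sort(names(st0))])
})

test_that("read_gem reports contract violations", {
  tf <- withr::local_tempfile(fileext = ".xml")
  m <- chain_gem()
  write_gem(m, tf)
  # strip the objective declaration -> explicit "no biomass objective"
  doc <- xml2::read_xml(tf)
  obj <- xml2::xml_find_first(doc, ".//fbc:listOfObjectives",
                              c(fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"))
  xml2::xml_remove(obj)
  xml2::write_xml(doc, tf)
  expect_error(read_gem(tf), "no biomass objective")

  tf2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not xml <", tf2)
  expect_error(read_gem(tf2), "parse failure")

  expect_error(read_gem("does/not/exist.xml"), "no such file")
})

test_that("medium CSV round-trips and rejects bad values", {
  med <- medium(c(EX_A = 10, EX_B = 0))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_medium(med, tf)
  expect_equal(read_medium(tf), med)
  expect_error(medium(c(EX_A = -1)), ">= 0")
})
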