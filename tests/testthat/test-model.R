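test_that("model construction cross-references all sheets and rejects bad rows", {
  m <- linear_model()
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$reactions), 3)
  expect_equal(nrow(m$metabolites), 4)
  expect_equal(m$uptake_reaction, "IN")

  mets <- tibble::tibble(id = c("A", "B"), carbon_count = c(2L, 2L))
  rxns <- tibble::tibble(id = "R")
  st <- tibble::tibble(reaction_id = "R", metabolite_id = c("A", "B"),
                       coef = c(-1, 1))
  expect_error(
    metabolic_model(mets, rxns, st,
                    regulations = tibble::tibble(reaction_id = "R",
                                                 inhibitor_id = "xyz",
                                                 mode = "competitive")),
    "unknown metabolite")
  expect_error(
    metabolic_model(mets, rxns, st,
                    regulations = tibble::tibble(reaction_id = "R",
                                                 inhibitor_id = "A",
                                                 mode = "allosteric")),
    "mode")
  expect_error(
    metabolic_model(mets, rxns,
                    tibble::tibble(reaction_id = "R", metabolite_id = "zz",
                                   coef = -1)),
    "unknown metabolite")
  expect_error(
    metabolic_model(dplyr::bind_rows(mets, mets[1, ]), rxns, st),
    "duplicate metabolite")
})

test_that("validate_model flags carbon imbalance and passes balanced maps", {
  mets <- tibble::tibble(id = c("A", "B"), carbon_count = 2L,
                         is_extracellular = c(TRUE, TRUE))
  rxns <- tibble::tibble(id = "R")
  st <- tibble::tibble(reaction_id = "R", metabolite_id = c("A", "B"),
                       coef = c(-1, 1))
  ok <- metabolic_model(mets, rxns, st,
                        atom_maps = tibble::tibble(
                          reaction_id = "R", role = c("substrate", "product"),
                          metabolite_id = c("A", "B"), atoms = c("ab", "ab")))
  expect_equal(nrow(validate_model(ok)), 0)

  mets2 <- tibble::tibble(id = c("A", "B"), carbon_count = c(2L, 1L),
                          is_extracellular = c(TRUE, TRUE))
  bad <- metabolic_model(mets2, rxns, st,
                         atom_maps = tibble::tibble(
                           reaction_id = "R", role = c("substrate", "product"),
                           metabolite_id = c("A", "B"), atoms = c("ab", "a")))
  rep <- validate_model(bad)
  expect_true("carbon_imbalance" %in% rep$check)

  # atom string length must match the carbon count
  wrong_len <- metabolic_model(mets2, rxns, st,
                               atom_maps = tibble::tibble(
                                 reaction_id = "R",
                                 role = c("substrate", "product"),
                                 metabolite_id = c("A", "B"),
                                 atoms = c("ab", "ab")))
  expect_true("atom_string_length" %in% validate_model(wrong_len)$check)
})

test_that("generated toys validate clean and malformed atom strings error", {
  expect_equal(nrow(validate_model(toy1())), 0)
  expect_equal(nrow(validate_model(toy2())), 0)
  mets <- tibble::tibble(id = c("A", "B"), carbon_count = 2L)
  rxns <- tibble::tibble(id = "R")
  st <- tibble::tibble(reaction_id = "R", metabolite_id = c("A", "B"),
                       coef = c(-1, 1))
  expect_error(
    metabolic_model(mets, rxns, st,
                    atom_maps = tibble::tibble(
                      reaction_id = "R", role = c("substrate", "product"),
                      metabolite_id = c("A", "B"), atoms = c("AB!", "ab"))),
    "malformed atom string")
})

test_that("reduce_network drops reactions, strips cofactors, keeps balance", {
  mets <- tibble::tibble(
    id = c("A", "B", "C", "atp", "adp"),
    carbon_count = c(2L, 2L, 2L, 0L, 0L),
    is_extracellular = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  rxns <- tibble::tibble(id = c("R1", "DEG"))
  st <- tibble::tibble(
    reaction_id = c("R1", "R1", "R1", "R1", "DEG", "DEG"),
    metabolite_id = c("A", "atp", "B", "adp", "B", "C"),
    coef = c(-1, -1, 1, 1, -1, 1))
  am <- tibble::tibble(reaction_id = "R1", role = c("substrate", "product"),
                       metabolite_id = c("A", "B"), atoms = c("ab", "ab"))
  m <- metabolic_model(mets, rxns, st, am)

  red <- reduce_network(m, list(drop_reactions = "DEG",
                                strip_metabolites = c("atp", "adp")))
  expect_equal(red$reactions$id, "R1")
  expect_false(any(c("atp", "adp") %in% red$stoichiometry$metabolite_id))
  expect_equal(nrow(validate_model(red)), 0)
  expect_equal(attr(red, "reaction_map")$full_id, "R1")

  expect_error(reduce_network(m, list(drop_reactions = "NOPE")),
               "absent reaction")
})

test_that("model and result files round-trip losslessly", {
  dir <- withr::local_tempdir()
  m <- toy2()
  write_model(m, dir)
  m2 <- read_model(dir, quiet = TRUE)
  for (field in c("metabolites", "reactions", "stoichiometry", "atom_maps",
                  "regulations")) {
    expect_equal(as.data.frame(m2[[field]]), as.data.frame(m[[field]]),
                 ignore_attr = TRUE)
  }
  expect_equal(m2$uptake_reaction, m$uptake_reaction)

  fl <- tibble::tibble(reaction_id = c("a", "b"), flux = c(1.234567891234, -2),
                       sd = c(0.1, 3), strain_id = "WT")
  p <- file.path(dir, "fluxes.tsv")
  write_flux_tsv(fl, p)
  expect_equal(as.data.frame(read_flux_tsv(p)), as.data.frame(fl))

  # header-only table round-trips as zero rows
  p0 <- file.path(dir, "empty.tsv")
  write_flux_tsv(fl[0, ], p0)
  expect_equal(nrow(read_flux_tsv(p0)), 0)

  res <- list(ssr = 338.123456789012, converged = TRUE,
              fluxes = list(reaction_id = c("a", "b"), flux = c(1, 2)))
  pj <- file.path(dir, "fit.json")
  write_json_result(res, pj)
  back <- read_json_result(pj)
  expect_identical(back$ssr, res$ssr)
  expect_identical(back$converged, TRUE)
})

test_that("binding orders default to declaration order with coefficient expansion", {
  mets <- tibble::tibble(id = c("A", "B", "P"), carbon_count = 1L)
  rxns <- tibble::tibble(id = "R")
  st <- tibble::tibble(reaction_id = "R", metabolite_id = c("A", "B", "P"),
                       coef = c(-2, -1, 1))
  m <- metabolic_model(mets, rxns, st)
  ord <- reaction_orders(m, "R")
  expect_equal(ord$substrates, c("A", "A", "B"))
  expect_equal(ord$products, "P")

  bo <- tibble::tibble(reaction_id = "R", role = c("substrate", "substrate",
                                                   "substrate", "product"),
                       position = c(1, 2, 3, 1),
                       metabolite_id = c("B", "A", "A", "P"))
  m2 <- metabolic_model(mets, rxns, st, binding_orders = bo)
  expect_equal(reaction_orders(m2, "R")$substrates, c("B", "A", "A"))
})
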