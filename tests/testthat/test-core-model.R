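test_that("stoichiometric matrix carries signed coefficients per reaction", {
  m <- new_model("t")
  m <- add_metabolite(m, "A", "c")
  m <- add_metabolite(m, "B", "c")
  m <- add_reaction(m, "r1", c("A[c]" = -1, "B[c]" = 1))
  m <- add_reaction(m, "r2", c("A[c]" = -2, "B[c]" = 1))
  S <- build_stoich_matrix(m)
  expect_equal(as.numeric(S["A[c]", "r1"]), -1)
  expect_equal(as.numeric(S["B[c]", "r1"]), 1)
  expect_equal(as.numeric(S["A[c]", "r2"]), -2)
})

test_that("stoichiometric matrix column sums match an iteration oracle", {
  m <- random_model(n_rxn = 5, n_met = 8, seed = 3)
  S <- build_stoich_matrix(m)
  for (rid in names(m$reactions)) {
    expect_equal(sum(S[, rid]), sum(m$reactions[[rid]]$stoich))
    expect_equal(sum(S[, rid] != 0), length(m$reactions[[rid]]$stoich))
  }
})

test_that("matrix construction is linear: concatenating reactions concatenates columns", {
  m <- random_model(n_rxn = 10, n_met = 10, seed = 5)
  ids <- names(m$reactions)
  S_all <- build_stoich_matrix(m)
  S_a <- build_stoich_matrix(m, ids[1:4])
  S_b <- build_stoich_matrix(m, ids[5:10])
  expect_equal(as.matrix(S_all), as.matrix(cbind(S_a, S_b)))
})

test_that("model invariants are enforced", {
  m <- new_model("t")
  m <- add_metabolite(m, "A", "c")
  expect_error(add_reaction(m, "r", c("Z[c]" = -1)), "unknown metabolites")
  m <- add_reaction(m, "r", c("A[c]" = -1), is_boundary = TRUE)
  expect_error(add_reaction(m, "r", c("A[c]" = 1)), "duplicate")
  # boundary with both sides violates the one-sidedness invariant
  m2 <- add_metabolite(m, "B", "c")
  m2 <- add_reaction(m2, "r2", c("A[c]" = -1, "B[c]" = 1), is_boundary = TRUE)
  expect_error(validate_model(m2), "both sides")
})

test_that("SBML round-trip is the identity on all model fields", {
  fix <- generate_fixtures(fixture_spec(seed = 11))
  for (model in list(fix$a, fix$b, linear_toy())) {
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(model, path)
    back <- read_sbml(path)
    expect_equal(back$reactions, model$reactions)
    expect_equal(back$metabolites, model$metabolites)
    expect_equal(back$compartments, model$compartments)
    expect_equal(back$genes, model$genes)
    expect_identical(back$biomass_reaction_id, model$biomass_reaction_id)
    # second write is byte-identical (deterministic writer)
    path2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("rational coefficients and GPR strings survive the round-trip", {
  m <- new_model("t")
  m <- add_metabolite(m, "A", "c")
  m <- add_metabolite(m, "B", "c")
  m <- add_reaction(m, "half", c("A[c]" = -0.5, "B[c]" = 1), "forward",
                    gpr = "(g1 and g2) or g3")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  back <- read_sbml(path)
  expect_identical(unname(back$reactions$half$stoich["A[c]"]), -0.5)
  expect_identical(gpr_to_string(back$reactions$half$gpr),
                   gpr_to_string(m$reactions$half$gpr))
})

test_that("legacy SBML L2 notes-based gene associations and bounds are read", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
 <model id="legacy">
  <listOfCompartments><compartment id="c"/></listOfCompartments>
  <listOfSpecies>
   <species id="M_a_c" compartment="c"/>
   <species id="M_b_c" compartment="c"/>
   <species id="M_b_b" compartment="c" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R_v1" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (b001 and b002) or b003</p>
    </body></notes>
    <listOfReactants><speciesReference species="M_a_c" stoichiometry="2"/></listOfReactants>
    <listOfProducts><speciesReference species="M_b_c"/></listOfProducts>
    <kineticLaw>
      <listOfParameters>
        <parameter id="LOWER_BOUND" value="0"/>
        <parameter id="UPPER_BOUND" value="999"/>
      </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="R_ex" reversible="true">
    <listOfReactants><speciesReference species="M_b_c"/></listOfReactants>
    <listOfProducts><speciesReference species="M_b_b"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  m <- read_sbml(path)
  expect_equal(length(m$reactions), 2)
  v1 <- m$reactions$v1
  expect_equal(unname(v1$stoich["a[c]"]), -2)
  expect_equal(v1$reversibility, "forward")
  expect_equal(v1$ub, 999)
  expect_setequal(gpr_genes(v1$gpr), c("b001", "b002", "b003"))
  # species flagged boundaryCondition makes the exchange one-sided
  expect_true(m$reactions$ex$is_boundary)
  expect_equal(m$reactions$ex$reversibility, "reversible")
})

test_that("missing SBML file and malformed XML give format errors", {
  expect_error(read_sbml(tempfile()), "parse failure")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><unclosed>", bad)
  expect_error(read_sbml(bad), "parse failure")
})

test_that("decision log replays to an identical model, stale inputs error", {
  fix <- generate_fixtures(fixture_spec(seed = 4))
  bcm <- build_bcm(list(fix$a, fix$b))
  rcm <- auto_refine(bcm$model, log = bcm$log)
  redone <- replay(rcm$log, list(fix$a, fix$b))
  expect_equal(redone$reactions, rcm$model$reactions)

  # serialization round-trip of the log preserves replay behaviour
  path <- withr::local_tempfile(fileext = ".ndjson")
  write_decision_log(rcm$log, path)
  log2 <- read_decision_log(path)
  redone2 <- replay(log2, list(fix$a, fix$b))
  expect_equal(redone2$reactions, rcm$model$reactions)

  other <- generate_fixtures(fixture_spec(seed = 99, n_chain = 9))
  expect_error(replay(rcm$log, list(other$a, other$b)), "stale")
})

test_that("an empty decision log replays to the naive union", {
  fix <- generate_fixtures(fixture_spec(seed = 4))
  models <- lapply(list(fix$a, fix$b), harmonize_compartments)
  log <- new_decision_log(models)
  expect_equal(replay(log, models)$reactions, naive_union(models)$reactions)
})
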