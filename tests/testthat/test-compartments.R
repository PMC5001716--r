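test_that("alternative transporters group per metabolite and membrane", {
  fix <- generate_fixtures(fixture_spec(seed = 22))
  merged <- build_bcm(list(fix$a, fix$b))$model
  groups <- find_alternative_transport(merged)
  want <- fix$truth$alt_transport[[1]]
  hit <- Filter(function(g) g$metabolite == want$metabolite, groups)
  expect_equal(length(hit), 1)
  expect_true(all(want$members %in% hit[[1]]$members))
  # a single transporter never forms a group
  singles <- Filter(function(g) g$metabolite == "bm", groups)
  expect_length(singles, 0)
})

test_that("alternative-transport output equals a brute-force scan on random models", {
  for (seed in 1:6) {
    m <- random_model(n_rxn = 25, n_met = 12, seed = seed)
    # scatter some metabolites into a second compartment to create transports
    set.seed(seed + 100)
    m <- add_compartment(m, "p")
    ids <- sample(unique(m$metabolites$id), 5)
    for (id in ids) m <- add_metabolite(m, id, "p")
    for (k in 1:6) {
      id <- sample(ids, 1)
      m <- add_reaction(m, paste0("tr", k),
                        stats::setNames(c(-1, 1), c(met_key(id, "c"), met_key(id, "p"))),
                        "reversible")
    }
    got <- find_alternative_transport(m)
    got_c <- canonical_groups(lapply(got, function(g) g$members))
    want_c <- canonical_groups(oracle_alt_transport(m))
    expect_identical(got_c, want_c)
  }
})

test_that("invalid transport: flagged membranes list crossing reactions exactly", {
  fix <- generate_fixtures(fixture_spec(seed = 23, invalid_transports = 3,
                                        alt_transporters = 0))
  g <- compartment_graph(fix$a)
  expect_message(find_invalid_transport(fix$a, g), "nothing to report")
  g$valid[(g$comp_a == "c" & g$comp_b == "e") |
            (g$comp_a == "e" & g$comp_b == "c")] <- FALSE
  hits <- find_invalid_transport(fix$a, g)
  expect_setequal(hits, fix$truth$invalid_transport)
})

test_that("splitting a transport conserves the net reaction and growth", {
  fix <- generate_fixtures(fixture_spec(seed = 24))
  b <- fix$b
  before <- simulate_growth(b, fix$medium)
  orig <- b$reactions$TS$stoich
  b2 <- add_compartment(b, "p", "periplasm")
  res <- split_transport(b2, "TS", "p")
  legs <- res$legs
  summed <- gsmerge:::cancel_stoich(c(res$model$reactions[[legs[1]]]$stoich,
                                      res$model$reactions[[legs[2]]]$stoich))
  expect_equal(summed[order(names(summed))], orig[order(names(orig))])
  expect_equal(simulate_growth(res$model, fix$medium), before, tolerance = 1e-6)
  # GPR is copied to both legs
  expect_identical(gpr_to_string(res$model$reactions[[legs[1]]]$gpr),
                   gpr_to_string(res$model$reactions[[legs[2]]]$gpr))
  expect_error(split_transport(b, "TS", "nope"), "not in model")
})

test_that("identical conversions in different compartments are paired", {
  m <- new_model("t")
  for (cp in c("c", "m")) {
    m <- add_metabolite(m, "A", cp)
    m <- add_metabolite(m, "B", cp)
    m <- add_reaction(m, paste0("r_", cp),
                      stats::setNames(c(-1, 1), met_key(c("A", "B"), cp)))
  }
  m <- add_reaction(m, "tr", c("A[c]" = -1, "A[m]" = 1))
  got <- find_alt_compartmentalization(m)
  expect_equal(nrow(got), 1)
  expect_setequal(c(got$rxn_a, got$rxn_b), c("r_c", "r_m"))
  expect_false("tr" %in% c(got$rxn_a, got$rxn_b))  # transports never appear
})

test_that("unknown-compartment reactions resolve against other-model twins", {
  fix <- generate_fixtures(fixture_spec(seed = 25, unknown_reactions = 4))
  merged <- build_bcm(list(fix$a, fix$b))$model
  props <- resolve_unknown_compartment(merged)
  truth <- fix$truth$unknown
  expect_equal(nrow(props), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- props[props$reaction == truth$reaction[i], ]
    if (truth$resolvable[i]) expect_equal(row$proposed_compartment, truth$expected[i])
    else expect_true(is.na(row$proposed_compartment))
  }
})

test_that("invalid boundary reactions are found and repaired conservatively", {
  fix <- generate_fixtures(fixture_spec(seed = 26))
  bad <- find_invalid_boundary(fix$b)
  expect_setequal(bad, fix$truth$invalid_boundary)
  expect_false("EX_S" %in% bad)
  # repair keeps the exchange usable and moves it to the extracellular side
  rep <- repair_boundary_reaction(fix$b, bad[1])
  expect_length(find_invalid_boundary(rep$model), 0)
  ext <- gsmerge:::met_key_parts(names(rep$model$reactions[[bad[1]]]$stoich))
  expect_equal(ext$compartment, "e")
  expect_true(rep$transport %in% names(rep$model$reactions))
  # growth unchanged by the repair
  expect_equal(simulate_growth(rep$model, fix$medium),
               simulate_growth(fix$b, fix$medium), tolerance = 1e-6)
})

test_that("removing a compartment folds diffusion chains and keeps chemistry", {
  fix <- generate_fixtures(fixture_spec(seed = 27))
  a <- fix$a
  before <- simulate_growth(a, fix$medium)
  exch_before <- sort(names(Filter(function(r) r$is_boundary, a$reactions)))
  res <- remove_compartment(a, "p", "c")
  m <- res$model
  expect_false("p" %in% m$compartments$id)
  expect_false(any(m$metabolites$compartment == "p"))
  # the pure p<->c diffusion leg cancelled away; the e->p leg now reads e->c
  expect_false("TS2" %in% names(m$reactions))
  expect_equal(names(m$reactions$TS1$stoich), c("S[c]", "S[e]"))
  # exchangeable metabolite set unchanged and growth preserved
  exch_after <- sort(names(Filter(function(r) r$is_boundary, m$reactions)))
  expect_identical(exch_after, exch_before)
  expect_equal(simulate_growth(m, fix$medium), before, tolerance = 1e-6)
})

test_that("split then remove-intermediate restores the net transport", {
  fix <- generate_fixtures(fixture_spec(seed = 28))
  b <- add_compartment(fix$b, "p", "periplasm")
  orig <- b$reactions$TS$stoich
  sp <- split_transport(b, "TS", "p")
  back <- remove_compartment(sp$model, "p", "c")$model
  # exactly one surviving reaction carries the original net stoichiometry
  sigs <- vapply(back$reactions, function(r)
    gsmerge:::stoich_signature(r$stoich), character(1))
  expect_true(gsmerge:::stoich_signature(orig) %in% sigs)
})

test_that("a periplasmic conversion survives compartment removal in the target", {
  m <- new_model("t")
  m <- add_compartment(m, "e", is_extracellular = TRUE)
  for (id in c("X")) { m <- add_metabolite(m, id, "p"); m <- add_metabolite(m, id, "c") }
  m <- add_metabolite(m, "Y", "p")
  # phosphatase-style: chemistry + transport in one reaction
  m <- add_reaction(m, "phos", c("X[p]" = -1, "Y[p]" = 1))
  m <- add_reaction(m, "tr", c("X[c]" = -1, "X[p]" = 1))
  res <- remove_compartment(m, "p", "c")
  expect_true("phos" %in% names(res$model$reactions))
  expect_equal(names(res$model$reactions$phos$stoich), c("X[c]", "Y[c]"))
  expect_false("tr" %in% names(res$model$reactions))   # pure transport cancels
})
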