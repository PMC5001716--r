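test_that("opposite-direction writings of one conversion are grouped", {
  m <- new_model("t")
  m <- add_metabolite(m, "A", "c")
  m <- add_metabolite(m, "B", "c")
  m <- add_reaction(m, "fwd", c("A[c]" = -1, "B[c]" = 1))
  m <- add_reaction(m, "bwd", c("A[c]" = 1, "B[c]" = -1))
  grps <- find_identical_net(m)
  expect_equal(length(grps), 1)
  expect_setequal(grps[[1]], c("fwd", "bwd"))
})

test_that("NADPH-producing vs consuming writings collide in the double matrix", {
  m <- new_model("t")
  for (id in c("A", "B", "nadp", "nadph")) m <- add_metabolite(m, id, "c")
  m <- add_reaction(m, "use", c("A[c]" = -1, "nadph[c]" = -1,
                                "B[c]" = 1, "nadp[c]" = 1))
  m <- add_reaction(m, "make", c("B[c]" = -1, "nadp[c]" = -1,
                                 "A[c]" = 1, "nadph[c]" = 1))
  grps <- find_identical_net(m)
  expect_setequal(grps[[1]], c("use", "make"))
})

test_that("detectors equal brute-force oracles on random models", {
  cfg <- default_config()
  pol <- merge_policy(proton_water_ignore = FALSE)
  for (seed in 1:25) {
    m <- random_model(n_rxn = sample(20:50, 1), n_met = sample(12:25, 1),
                      seed = seed)
    expect_identical(canonical_groups(find_identical_net(m, pol, cfg)),
                     oracle_identical_net(m))
    got_as <- canonical_groups(lapply(find_alt_stoichiometry(m, pol, cfg),
                                      function(g) g$members))
    expect_identical(got_as, oracle_alt_stoich(m))
    got_n <- find_nested(m, pol, cfg)
    want_n <- oracle_nested(m)
    expect_equal(nrow(got_n), if (is.null(want_n)) 0L else nrow(want_n))
    if (!is.null(want_n) && nrow(want_n)) {
      key <- function(d) sort(paste(d$inner, d$outer))
      expect_identical(key(got_n), key(want_n))
    }
  }
})

test_that("alternative stoichiometries auto-resolve only for a unique balanced member", {
  m <- new_model("t")
  m <- add_metabolite(m, "A", "c", "CH2O")
  m <- add_metabolite(m, "B", "c", "CH2O")
  m <- add_reaction(m, "bal", c("A[c]" = -1, "B[c]" = 1))
  m <- add_reaction(m, "unbal", c("A[c]" = -2, "B[c]" = 1))
  grp <- find_alt_stoichiometry(m)
  expect_equal(length(grp), 1)
  expect_equal(grp[[1]]$resolution, "auto")
  expect_equal(grp[[1]]$keep, "bal")

  # polymer-style case: no formula knowledge, stays pending
  m2 <- new_model("t")
  m2 <- add_metabolite(m2, "mono", "c")
  m2 <- add_metabolite(m2, "poly", "c")
  m2 <- add_reaction(m2, "n4", c("mono[c]" = -4, "poly[c]" = 1))
  m2 <- add_reaction(m2, "n5", c("mono[c]" = -5, "poly[c]" = 1))
  grp2 <- find_alt_stoichiometry(m2)
  expect_equal(grp2[[1]]$resolution, "pending")
})

test_that("redox-pair variants are detected and non-redox reactions never grouped", {
  fix <- generate_fixtures(fixture_spec(seed = 10, redox_twins = 2))
  merged <- build_bcm(list(fix$a, fix$b))$model
  got <- find_redox_variants(merged)
  got_members <- canonical_groups(lapply(got, function(g) g$members))
  for (twin in fix$truth$redox_twins)
    expect_true(list(sort(twin)) %in% got_members)
  # reactions without any redox metabolite never appear
  flat <- unlist(got_members)
  expect_false(any(c("R0", "EX_S", "T_bm") %in% flat))
})

test_that("redox-pair suggestions use the 80% co-occurrence rule", {
  m <- new_model("t")
  for (id in c("X", "Y", "s1", "s2", "s3", "s4", "s5")) m <- add_metabolite(m, id, "c")
  # X/Y on opposite sides in 4 of 4 reactions containing them
  for (i in 1:4)
    m <- add_reaction(m, paste0("r", i),
                      stats::setNames(c(-1, -1, 1, 1),
                                      met_key(c("X", paste0("s", i), "Y",
                                                paste0("s", i + 1)), "c")))
  sug <- suggest_redox_pairs(m)
  expect_true(nrow(sug) >= 1)
  hit <- sug[sug$id_a == "X" & sug$id_b == "Y", ]
  expect_equal(hit$fraction_a, 1.0)
  # a pair co-occurring in 3 of 10 reactions is not suggested
  m2 <- m
  for (i in 5:10)
    m2 <- add_reaction(m2, paste0("x", i),
                       stats::setNames(c(-1, 1), met_key(c("X", "s1"), "c")))
  sug2 <- suggest_redox_pairs(m2)
  expect_false(any(sug2$id_a == "X" & sug2$id_b == "Y"))
})

test_that("cofactor-optional reactions are nested; self-pairs excluded", {
  m <- new_model("t")
  for (id in c("A", "B", "P", "nad", "nadh")) m <- add_metabolite(m, id, "c")
  m <- add_reaction(m, "inner", c("A[c]" = -1, "B[c]" = -1, "P[c]" = 1))
  m <- add_reaction(m, "outer", c("A[c]" = -1, "B[c]" = -1, "P[c]" = 1,
                                  "nadh[c]" = -1, "nad[c]" = 1))
  got <- find_nested(m, merge_policy(proton_water_ignore = FALSE))
  expect_equal(got$inner, "inner")
  expect_equal(got$outer, "outer")
  expect_false(any(got$inner == got$outer))
})

test_that("similar reactions require genes, substrates and products jointly", {
  fix <- generate_fixtures(fixture_spec(seed = 14))
  merged <- build_bcm(list(fix$a, fix$b))$model
  got <- find_similar(merged, 1, 1, 1)
  want <- oracle_similar(merged, 1, 1, 1)
  key <- function(d) if (is.null(d) || !nrow(d)) character() else
    sort(paste(pmin(d$rxn_a, d$rxn_b), pmax(d$rxn_a, d$rxn_b)))
  expect_identical(key(got), key(want))
  # thresholds above any overlap empty the result
  expect_equal(nrow(find_similar(merged, 99, 99, 99)), 0)
})

test_that("lumped reactions: planted chain recovered, alternatives via penalty", {
  fix <- generate_fixtures(fixture_spec(seed = 16))
  merged <- build_bcm(list(fix$a, fix$b))$model
  truth <- fix$truth$lumped[[1]]
  nl <- find_lumped(merged, truth$candidate)
  got <- canonical_groups(nl)
  want <- canonical_groups(truth$nl_sets)
  expect_identical(got, want)
  # every returned set supports an exact steady-state cancellation
  exp <- gsmerge:::irreversible_expansion(merged)
  for (s in nl) {
    x <- attr(s, "fluxes")
    expect_lt(max(abs(exp$S %*% x)), 1e-8)
  }
})

test_that("isolated reactions yield no lumped sets; size cap terminates search", {
  m <- linear_toy()
  expect_length(find_lumped(m, "AX"), 0)
  cfg <- default_config()
  cfg$max_lumped_size <- 1L      # chain of length 2 exceeds the cap
  fix <- generate_fixtures(fixture_spec(seed = 16))
  merged <- build_bcm(list(fix$a, fix$b))$model
  expect_length(find_lumped(merged, fix$truth$lumped[[1]]$candidate, cfg), 0)
})

test_that("merging respects direction consensus and GPR policy", {
  mk <- function(dir2) {
    m <- new_model("t")
    m <- add_metabolite(m, "A", "c")
    m <- add_metabolite(m, "B", "c")
    m <- add_reaction(m, "r1", c("A[c]" = -1, "B[c]" = 1), "forward", gpr = "g1",
                      sources = "m1")
    add_reaction(m, "r2", c("A[c]" = -1, "B[c]" = 1), dir2, gpr = "g2",
                 sources = "m2")
  }
  agree <- merge_reactions(mk("forward"), c("r1", "r2"))
  expect_equal(agree$model$reactions$r1$reversibility, "forward")
  expect_setequal(agree$model$reactions$r1$sources, c("m1", "m2"))
  expect_setequal(gpr_genes(agree$model$reactions$r1$gpr), c("g1", "g2"))

  conflict <- merge_reactions(mk("backward"), c("r1", "r2"))
  expect_equal(conflict$model$reactions$r1$reversibility, "reversible")

  # predictor hook resolves instead of defaulting to reversible
  hook <- merge_policy(direction_mode = "consensus-then-predictor-hook",
                       direction_predictor = function(r) "forward")
  pred <- merge_reactions(mk("backward"), c("r1", "r2"), hook)
  expect_equal(pred$model$reactions$r1$reversibility, "forward")

  # strict GPR mode holds structural conflicts
  strict <- merge_reactions(mk("forward"), c("r1", "r2"),
                            merge_policy(gpr_mode = "strict"))
  expect_equal(strict$status, "pending")
  expect_equal(length(strict$model$reactions), 2)
})

test_that("merging refuses different net formulas without force", {
  m <- new_model("t")
  for (id in c("A", "B", "C")) m <- add_metabolite(m, id, "c")
  m <- add_reaction(m, "r1", c("A[c]" = -1, "B[c]" = 1))
  m <- add_reaction(m, "r2", c("A[c]" = -1, "C[c]" = 1))
  expect_error(merge_reactions(m, c("r1", "r2")), "refusing")
})

test_that("merging identical-net members preserves maximal biomass flux", {
  fix <- generate_fixtures(fixture_spec(seed = 19))
  merged <- build_bcm(list(fix$a, fix$b))$model
  before <- simulate_growth(merged, fix$medium)
  grps <- find_identical_net(merged)
  for (g in grps) {
    res <- merge_reactions(merged, g)
    if (res$status == "merged") merged <- res$model
  }
  expect_equal(simulate_growth(merged, fix$medium), before, tolerance = 1e-6)
})
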