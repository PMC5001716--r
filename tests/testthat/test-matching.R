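# attribute matrix, context scoring and the matching workflow

# two tiny models: identical 3-metabolite reaction with one gene, B renames C
toy_pair_merged <- function() {
  mk <- function(tag, cname) {
    m <- new_model(tag)
    for (id in c("A", "B", cname, "D")) m <- add_metabolite(m, id, "c")
    m <- add_reaction(m, paste0(tag, "_r1"),
                      stats::setNames(c(-1, -1, 1), met_key(c("A", "B", cname), "c")),
                      gpr = "g1")
    m <- add_reaction(m, paste0(tag, "_r2"),
                      stats::setNames(c(-1, 1), met_key(c(cname, "D"), "c")),
                      gpr = "g2")
    m
  }
  naive_union(list(mk("A", "C"), mk("B", "Csyn")))
}

test_that("co-occurrence entries follow the reaction structure", {
  merged <- toy_pair_merged()
  ctx <- build_context(merged)
  # in model A's column for C: A, B (reaction 1) and D (reaction 2) co-occur
  col <- ctx$M[, "C[c]::A"]
  expect_true(all(col[c("m:A[c]", "m:B[c]", "m:D[c]")] > 0))
  expect_true(all(col[setdiff(rownames(ctx$M),
                              c("m:A[c]", "m:B[c]", "m:D[c]", "g:g1", "g:g2"))] == 0))
})

test_that("row normalization weights rare connections more than hubs", {
  # one gene g touching 2 metabolites vs a hub metabolite touching many:
  # after per-row normalization the gene row entries (1/2) must exceed the
  # hub row entries (1/k, k > 2)
  m1 <- new_model("A")
  m2 <- new_model("B")
  for (tag in c("A", "B")) {
    m <- new_model(tag)
    m <- add_metabolite(m, "hub", "c")
    for (i in 1:6) m <- add_metabolite(m, paste0("x", i), "c")
    for (i in 1:5) m <- add_reaction(m, paste0(tag, "_h", i),
        stats::setNames(c(-1, 1), met_key(c("hub", paste0("x", i)), "c")))
    m <- add_reaction(m, paste0(tag, "_g"),
        stats::setNames(c(-1, 1), met_key(c("x5", "x6"), "c")), gpr = "g")
    if (tag == "A") m1 <- m else m2 <- m
  }
  merged <- naive_union(list(m1, m2))
  ctx <- build_context(merged)
  grow <- ctx$M["g:g", ]
  hubrow <- ctx$M["m:hub[c]", ]
  expect_equal(sum(grow), 1, tolerance = 1e-12)
  expect_equal(sum(hubrow), 1, tolerance = 1e-12)
  expect_gt(max(grow), max(hubrow))
})

test_that("every retained attribute row sums to one", {
  fix <- generate_fixtures(fixture_spec(seed = 3))
  merged <- build_bcm(list(fix$a, fix$b))$model
  ctx <- build_context(merged)
  expect_true(all(abs(rowSums(ctx$M) - 1) < 1e-12))
})

test_that("identical context columns score 1, disjoint ones score <= 0", {
  merged <- toy_pair_merged()
  ctx <- build_context(merged)
  sc <- score_matches(ctx)
  pair <- sc$candidates[sc$candidates$met_a == "C[c]" &
                          sc$candidates$met_b == "Csyn[c]", ]
  expect_equal(pair$score, 1.0, tolerance = 1e-12)
})

test_that("pairwise scores equal a brute-force Pearson implementation", {
  fix <- generate_fixtures(fixture_spec(seed = 6))
  merged <- build_bcm(list(fix$a, fix$b))$model
  ctx <- build_context(merged)
  sc <- score_matches(ctx)
  cols <- ctx$cols
  colid <- paste0(cols$key, "::", cols$model)
  for (i in seq_len(min(nrow(sc$candidates), 40))) {
    row <- sc$candidates[i, ]
    x <- ctx$M[, match(paste0(row$met_a, "::", row$model_a), colid)]
    y <- ctx$M[, match(paste0(row$met_b, "::", row$model_b), colid)]
    expect_equal(row$score, pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("score symmetry: score(i,j) = score(j,i)", {
  fix <- generate_fixtures(fixture_spec(seed = 6))
  merged <- build_bcm(list(fix$a, fix$b))$model
  ctx <- build_context(merged)
  M <- ctx$M
  for (i in 1:5) {
    a <- sample(ncol(M), 1); b <- sample(ncol(M), 1)
    expect_equal(stats::cor(M[, a], M[, b]), stats::cor(M[, b], M[, a]))
  }
})

test_that("thresholding respects the shared-score percentile and is one-to-one", {
  fix <- generate_fixtures(fixture_spec(seed = 9))
  merged <- build_bcm(list(fix$a, fix$b))$model
  ctx <- build_context(merged)
  sc <- score_matches(ctx)
  p0 <- threshold_matches(sc, percentile = 0)
  p100 <- threshold_matches(sc, percentile = 100)
  expect_true(all(p100$score >= max(sc$shared_scores) - 1e-12))
  expect_gte(nrow(p0), nrow(p100))
  expect_false(any(duplicated(c(p0$met_a, p0$met_b))))   # one-to-one
})

test_that("empty shared set is an error pointing at the namespace step", {
  sc <- list(candidates = data.frame(met_a = "x", met_b = "y", model_a = "A",
                                     model_b = "B", score = 1),
             shared_scores = numeric())
  expect_error(threshold_matches(sc), "namespace")
})

test_that("self-recovery: renamed metabolites match themselves at score 1", {
  fix <- generate_fixtures(fixture_spec(seed = 21, synonyms = 4))
  merged <- build_bcm(list(fix$a, fix$b))$model
  sc <- score_matches(build_context(merged))
  props <- threshold_matches(sc)
  found <- gsmerge:::pair_sig(props$met_a, props$met_b)
  want <- gsmerge:::pair_sig(fix$truth$synonyms$met_a, fix$truth$synonyms$met_b)
  expect_true(all(want %in% found))
  expect_equal(props$score[found %in% want], rep(1, length(want)), tolerance = 1e-9)
})

test_that("merging matched metabolites forms the new pathway and drops duplicates", {
  m <- new_model("t")
  for (id in c("A", "X", "Y", "B")) m <- add_metabolite(m, id, "c")
  m <- add_reaction(m, "r1", c("A[c]" = -1, "X[c]" = 1))
  m <- add_reaction(m, "r2", c("Y[c]" = -1, "B[c]" = 1))
  res <- merge_matched(m, data.frame(met_a = "X[c]", met_b = "Y[c]"))
  # path A -> X -> B now exists through the merged metabolite
  expect_false("Y[c]" %in% res$model$metabolites$key)
  expect_equal(names(res$model$reactions$r2$stoich),
               c("B[c]", "X[c]"))
})

test_that("formula-mismatched pairs (polymer granularity) are held, not merged", {
  m <- new_model("t")
  m <- add_metabolite(m, "poly4", "c", "C12H24O12")
  m <- add_metabolite(m, "poly5", "c", "C15H30O15")
  m <- add_metabolite(m, "s", "c")
  m <- add_reaction(m, "p4", c("s[c]" = -4, "poly4[c]" = 1))
  m <- add_reaction(m, "p5", c("s[c]" = -5, "poly5[c]" = 1))
  res <- merge_matched(m, data.frame(met_a = "poly4[c]", met_b = "poly5[c]"))
  expect_null(res$merged)
  expect_equal(res$held$reason, "formula mismatch")
  expect_true(all(c("poly4[c]", "poly5[c]") %in% res$model$metabolites$key))
})

test_that("degradation harness: perfect recovery intact, chance at full loss", {
  fix <- generate_fixtures(fixture_spec(seed = 13))
  merged <- build_bcm(list(fix$a, fix$b))$model
  roc <- roc_harness(merged, fix$truth$synonyms, fractions = c(0, 1),
                     repeats = 3, seed = 5)
  expect_equal(roc$sensitivity[roc$fraction == 0], 1)
  expect_equal(roc$specificity[roc$fraction == 0], 1)
  expect_lt(roc$sensitivity[roc$fraction == 1], 1)
})
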