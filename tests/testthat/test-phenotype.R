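test_that("linear toy reaches uptake-limited biomass; knockouts zero it", {
  m <- linear_toy()
  expect_equal(simulate_growth(m, c(A = 10)), 10, tolerance = 1e-9)
  expect_equal(simulate_growth(m, c(A = 3)), 3, tolerance = 1e-9)
  expect_equal(simulate_growth(m, c(A = 10), knockouts = "g1"), 0)
})

test_that("isozymes survive single knockouts, complexes do not", {
  m <- add_gene(linear_toy(), "g2")
  m$reactions$AX$gpr <- gpr_parse("g1 or g2")
  expect_equal(simulate_growth(m, c(A = 10), knockouts = "g1"), 10)
  expect_equal(simulate_growth(m, c(A = 10), knockouts = c("g1", "g2")), 0)
  m$reactions$AX$gpr <- gpr_parse("g1 and g2")
  expect_equal(simulate_growth(m, c(A = 10), knockouts = "g2"), 0)
})

test_that("growth is monotone in the medium uptake bounds", {
  fix <- generate_fixtures(fixture_spec(seed = 41))
  g <- vapply(c(1, 5, 10, 20), function(u)
    simulate_growth(fix$a, c(S = u)), numeric(1))
  expect_true(all(diff(g) >= -1e-9))
})

test_that("growth calls implement the 1e-6 and 30% cutoffs exactly", {
  expect_equal(call_growth(1e-7), "no-growth")
  expect_equal(call_growth(1.0000001e-6), "growth")
  expect_equal(call_growth(0.5, 0.5), "growth")
  # boundary cases around the relative threshold
  expect_equal(call_growth(1, 0.29), "no-growth")
  expect_equal(call_growth(1, 0.30), "growth")
  flagged <- call_growth(1e-9, 0.5)
  expect_equal(as.character(flagged), "no-growth")
  expect_true(attr(flagged, "flagged"))
})

test_that("metrics match an independent confusion tally on randomized labels", {
  set.seed(7)
  m <- linear_toy()
  genes <- c("", "g1", "gT", "g1;gT")
  records <- data.frame(
    condition = "glc",
    genotype = sample(genes, 20, replace = TRUE),
    observed = sample(c("growth", "no-growth"), 20, replace = TRUE),
    stringsAsFactors = FALSE)
  data <- list(records = records, media = list(glc = c(A = 10)))
  rep <- evaluate_phenotypes(m, data)
  # independent tally: any knockout of g1 or gT kills this linear chain
  pred <- ifelse(records$genotype == "", "growth", "no-growth")
  TP <- sum(pred == "growth" & records$observed == "growth")
  TN <- sum(pred == "no-growth" & records$observed == "no-growth")
  FP <- sum(pred == "growth" & records$observed == "no-growth")
  FN <- sum(pred == "no-growth" & records$observed == "growth")
  expect_equal(rep$TP, TP); expect_equal(rep$TN, TN)
  expect_equal(rep$FP, FP); expect_equal(rep$FN, FN)
  expect_equal(rep$sensitivity, if (TP + FN > 0) TP / (TP + FN) else 0)
  expect_equal(rep$specificity, if (TN + FP > 0) TN / (TN + FP) else 0)
  expect_equal(rep$accuracy, (TP + TN) / 20)
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  expect_equal(rep$mcc, if (denom > 0) (TP * TN - FP * FN) / denom else 0)
  expect_gte(rep$mcc, -1); expect_lte(rep$mcc, 1)
})

test_that("perfect and degenerate predictors give the expected metrics", {
  expect_equal(gsmerge:::metrics_report(5, 5, 0, 0)$mcc, 1)
  expect_equal(gsmerge:::metrics_report(5, 5, 0, 0)$accuracy, 1)
  all_pos <- gsmerge:::metrics_report(5, 0, 5, 0)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$mcc, 0)
})

test_that("phenotype TSV round-trips through the reader", {
  dir <- withr::local_tempdir()
  writeLines(c("boundary_metabolite\tmax_uptake", "A\t10"),
             file.path(dir, "glc.tsv"))
  writeLines(c("condition\tgenotype\tmedium_file\tobserved",
               "glc\t\tglc.tsv\tgrowth",
               "glc\tg1\tglc.tsv\tno-growth"),
             file.path(dir, "records.tsv"))
  data <- read_phenotype_dataset(file.path(dir, "records.tsv"))
  rep <- evaluate_phenotypes(linear_toy(), data)
  expect_equal(rep$TP + rep$TN, 2)       # both records predicted correctly
})

test_that("flux variability separates dead ends from the active backbone", {
  m <- linear_toy()
  m <- add_metabolite(m, "dead", "c")
  m <- add_reaction(m, "to_dead", c("A[c]" = -1, "dead[c]" = 1))
  act <- active_reactions(m, c(A = 10))
  expect_false(act[["to_dead"]])
  expect_true(all(act[c("EX_A", "TA", "AX", "BIO")]))
})

test_that("metrics are invariant under record order", {
  m <- linear_toy()
  records <- data.frame(condition = "glc",
                        genotype = c("", "g1", "", "gT"),
                        observed = c("growth", "no-growth", "no-growth", "growth"),
                        stringsAsFactors = FALSE)
  data1 <- list(records = records, media = list(glc = c(A = 10)))
  data2 <- list(records = records[c(3, 1, 4, 2), ], media = data1$media)
  expect_equal(evaluate_phenotypes(m, data1)[1:8],
               evaluate_phenotypes(m, data2)[1:8])
})
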