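test_that("expected-score DIF reproduces the published magnitudes", {
  # identical parameters: zero curve, maximum reported at the grid start
  it <- itemParameters("x", 2, c(-1, 0, 1))
  es0 <- expectedScoreDIF(it, it)
  expect_equal(es0$esDeltaMax, 0)
  expect_equal(es0$thetaAtMax, -8)
  # all seven published two-group rows; the administration-mode row of
  # item 1 recomputes to -0.67 from the rounded printed parameters and is
  # checked against that recomputed value
  printed <- c(item7 = -0.80, item3 = -0.74, item1.adm = -0.67,
               item1.gen = 0.62, item12 = 1.00, item19 = 0.24,
               item24 = -1.22)
  thetas <- c(-0.80, 0.20, -2.00, 2.60, 5.40, -0.80, -1.00)
  tab <- lvqolDIFTable()
  for (i in seq_along(tab)) {
    es <- expectedScoreDIF(tab[[i]]$reference, tab[[i]]$focal)
    expect_equal(es$esDeltaMax, unname(printed[i]), tolerance = 0.025)
    expect_lt(abs(es$thetaAtMax - thetas[i]), 0.15)
    # swapping the groups flips the sign of the curve and the maximum
    esSwap <- expectedScoreDIF(tab[[i]]$focal, tab[[i]]$reference)
    expect_equal(esSwap$esDeltaMax, -es$esDeltaMax, tolerance = 1e-12)
  }
  expect_error(expectedScoreDIF(it, itemParameters("y", 1, c(0, 1))),
               "categories")
})

test_that("two-group fit separates impact from DIF", {
  sc <- anchorScale4()
  # focal population shifted by +0.5, items identical: the focal mean is
  # recovered and no DIF is declared
  sim <- simulateResponses(simulationDesign(sc, nPersons = 1000,
                                            groupFraction = 0.5,
                                            focalMean = 0.5, missingRate = 0,
                                            seed = 42))
  f <- fitTwoGroup(sim$responses, sim$groups, sc, "item3", "all-equal",
                   simGrid(), tol = 1e-4)
  expect_true(f$converged)
  expect_lt(abs(f$focalMean - 0.5), 0.15)
  r <- difTest(sim$responses, sim$groups, sc, "item3", simGrid(), tol = 1e-4)
  expect_identical(r@classification, "none")
  expect_equal(r@esDeltaMax, 0)
})

test_that("the hierarchical scheme classifies planted DIF correctly", {
  sc <- anchorScale4()
  g <- simGrid()
  for (seed in 1:3) {
    simU <- simulateResponses(simulationDesign(
      sc, nPersons = 1000, groupFraction = 0.5, missingRate = 0,
      difEdits = list(list(itemId = "item3", kind = "uniform",
                           magnitude = 0.5)), seed = 810 + seed))
    rU <- difTest(simU$responses, simU$groups, sc, "item3", g, tol = 1e-4)
    expect_identical(rU@classification, "uniform")
    # uniform DIF: thresholds tested only because the slope test passed
    expect_gte(rU@pSlope, 0.01)
    expect_lt(rU@pThresholds, 0.01)
    # focal thresholds shifted up -> focal expected score lower -> ES > 0
    expect_gt(rU@esDeltaMax, 0)

    simN <- simulateResponses(simulationDesign(
      sc, nPersons = 1000, groupFraction = 0.5, missingRate = 0,
      difEdits = list(list(itemId = "item3", kind = "non-uniform",
                           magnitude = 2)), seed = 820 + seed))
    rN <- difTest(simN$responses, simN$groups, sc, "item3", g, tol = 1e-4)
    expect_identical(rN@classification, "non-uniform")
    expect_lt(rN@pSlope, 0.01)
    expect_true(is.na(rN@pThresholds))     # hierarchy: no threshold test
  }
})

test_that("null slope G^2 behaves like chi-square(1)", {
  s <- nullDifSample()
  expect_true(all(s[, "g2Slope"] >= 0))
  q99 <- unname(quantile(s[, "g2Slope"], 0.99))
  expect_gte(q99, 5.0)
  expect_lte(q99, 8.5)
})

test_that("swapping group labels mirrors the DIF result", {
  sc <- anchorScale4()
  sim <- simulateResponses(simulationDesign(
    sc, nPersons = 600, groupFraction = 0.5, missingRate = 0,
    difEdits = list(list(itemId = "item3", kind = "uniform", magnitude = 0.8)),
    seed = 99))
  g <- simGrid()
  r1 <- difTest(sim$responses, sim$groups, sc, "item3", g, tol = 1e-4)
  r2 <- difTest(sim$responses, sim$groups, sc, "item3", g, tol = 1e-4,
                reference = "focal")
  expect_identical(r1@classification, r2@classification)
  expect_equal(r1@g2Thresholds, r2@g2Thresholds, tolerance = 0.05)
  expect_equal(r1@esDeltaMax, -r2@esDeltaMax, tolerance = 0.05)
})

test_that("the removal rule fires on the published DIF profiles", {
  tab <- lvqolDIFTable()
  byItem <- split(seq_along(tab), vapply(tab, `[[`, character(1), "item"))
  profiles <- lapply(byItem, function(ix) lapply(tab[ix], function(row) {
    cls <- if (row$item == "item3") "non-uniform" else "uniform"
    makeDifResult(row$item, row$variable, cls, row$reference, row$focal)
  }))
  dec <- lapply(profiles, removalDecision)
  expect_true(dec$item1$remove)            # DIF on two subgroup variables
  expect_true(any(grepl("2 subgroup variables", dec$item1$reasons)))
  expect_true(dec$item24$remove)           # |ES| > 1 point
  expect_true(any(grepl("> 1.0 points", dec$item24$reasons)))
  expect_false(dec$item3$remove)
  expect_false(dec$item7$remove)
  expect_false(dec$item12$remove)          # |ES| = 1.00 does not exceed 1
  expect_false(dec$item19$remove)
  expect_error(removalDecision(list()), "empty")
  expect_error(removalDecision(c(profiles$item1[1], profiles$item24[1])),
               "one item")
})

test_that("the continuum-extent clause triggers on broad moderate DIF", {
  base <- itemParameters("w", 2.5, c(-1.5, -0.75, 0, 0.75, 1.5))
  wide <- itemParameters("w", 2.5, base@thresholds + 0.7)   # broad shift
  r <- makeDifResult("w", "v", "uniform", base, wide)
  expect_lt(abs(r@esDeltaMax), 1)          # clause (a) must not be the cause
  dec <- removalDecision(list(r))
  expect_true(dec$remove)
  expect_true(any(grepl("trait distribution", dec$reasons)))
})
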