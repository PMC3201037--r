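test_that("reference tables carry the published structure", {
  scales <- lvqolReferenceScales()
  expect_named(scales, c("Basic aspects", "Mobility", "Adjustment",
                         "Reading and fine work"))
  expect_length(scales[["Reading and fine work"]]@items, 7L)
  expect_length(scales[["Adjustment"]]@items, 4L)
  expect_equal(sum(vapply(scales, function(s) length(s@items), integer(1))),
               21L)
  expect_equal(unname(slopes(scales[["Adjustment"]])[1]), 1.26)
  expect_equal(unname(slopes(scales[["Reading and fine work"]])["item20"]),
               5.02)
  expect_equal(thresholds(scales[["Reading and fine work"]])[["item20"]],
               c(-1.28, -0.93, -0.36, 0.02, 0.98))
  # every transcribed item satisfies the container invariants (validity
  # already ran); all are 6-category items
  for (s in scales) expect_true(all(nCategories(s) == 6L))
  expect_length(lvqolDIFTable(), 7L)
})

test_that("simulation is deterministic and respects the code range", {
  sc <- anchorScale4()
  d <- simulationDesign(sc, nPersons = 150, groupFraction = 0.4,
                        focalMean = 0.3, missingRate = 0.05,
                        difEdits = list(list(itemId = "item3",
                                             kind = "uniform",
                                             magnitude = 0.5)), seed = 12)
  s1 <- simulateResponses(d); s2 <- simulateResponses(d)
  expect_identical(responseCodes(s1$responses), responseCodes(s2$responses))
  expect_identical(s1$groups, s2$groups)
  expect_identical(s1$truth$theta, s2$truth$theta)
  X <- responseCodes(s1$responses)
  obs <- X[!is.na(X)]
  expect_true(all(obs %in% 0:5))
  # a different seed changes the draw
  s3 <- simulateResponses(simulationDesign(sc, nPersons = 150,
                                           groupFraction = 0.4, seed = 13))
  expect_false(identical(responseCodes(s1$responses),
                         responseCodes(s3$responses)))
})

test_that("missingness matches the study's 4.5% non-response rate", {
  all21 <- scaleParameters("LVQOL-21",
                           unlist(lapply(lvqolReferenceScales(), slot, "items"),
                                  recursive = FALSE))
  miss <- vapply(1:50, function(i) {
    sim <- simulateResponses(simulationDesign(all21, nPersons = 296,
                                              seed = 1200 + i))
    mean(is.na(responseCodes(sim$responses)))
  }, numeric(1))
  expect_lt(abs(mean(miss) - 0.045), 0.01)
})

test_that("DIF edits act on the focal parameters exactly as declared", {
  sc <- anchorScale4()
  # magnitude-zero edits leave the focal scale identical to the reference
  s0 <- simulateResponses(simulationDesign(
    sc, nPersons = 50, groupFraction = 0.5,
    difEdits = list(list(itemId = "item3", kind = "uniform", magnitude = 0)),
    seed = 1))
  expect_equal(s0$truth$focalScale, s0$truth$referenceScale)
  sU <- simulateResponses(simulationDesign(
    sc, nPersons = 50, groupFraction = 0.5,
    difEdits = list(list(itemId = "item3", kind = "uniform", magnitude = 0.7)),
    seed = 1))
  expect_equal(thresholds(sU$truth$focalScale)[["item3"]],
               thresholds(sc)[["item3"]] + 0.7)
  sN <- simulateResponses(simulationDesign(
    sc, nPersons = 50, groupFraction = 0.5,
    difEdits = list(list(itemId = "item3", kind = "non-uniform",
                         magnitude = 1.5)), seed = 1))
  expect_equal(slopes(sN$truth$focalScale)[["item3"]],
               1.5 * slopes(sc)[["item3"]])
  # per-threshold uniform edit vectors are accepted
  sV <- simulateResponses(simulationDesign(
    sc, nPersons = 50, groupFraction = 0.5,
    difEdits = list(list(itemId = "item3", kind = "uniform",
                         magnitude = c(0.1, 0.2, 0.3, 0.4, 0.5))), seed = 1))
  expect_equal(thresholds(sV$truth$focalScale)[["item3"]],
               thresholds(sc)[["item3"]] + c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_error(simulationDesign(sc, difEdits = list(
    list(itemId = "ghost", kind = "uniform", magnitude = 1))), "edit")
})

test_that("marginal category frequencies match the quadrature oracle", {
  sc <- anchorScale4()
  sim <- simulateResponses(simulationDesign(sc, nPersons = 5000,
                                            groupFraction = 0,
                                            missingRate = 0, seed = 77))
  X <- responseCodes(sim$responses)
  g <- abilityGrid(nPoints = 201)
  for (i in seq_along(sc@items)) {
    expected <- as.vector(crossprod(categoryProbs(sc@items[[i]], g@points),
                                    g@weights))
    observed <- tabulate(X[, i] + 1L, 6L) / nrow(X)
    se <- sqrt(expected * (1 - expected) / nrow(X))
    expect_true(all(abs(observed - expected) < 3 * se + 0.005))
  }
})

test_that("calibration round-trips the published Reading parameters", {
  sc <- lvqolReferenceScales()[["Reading and fine work"]]
  sim <- simulateResponses(simulationDesign(sc, nPersons = 2000,
                                            groupFraction = 0, seed = 321))
  fit <- fitGRM(sim$responses, simGrid(), tol = 1e-4)
  expect_true(calibrationConverged(fit))
  expect_lte(sqrt(mean((slopes(calibratedScale(fit)) - slopes(sc))^2)), 0.3)
})
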