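test_that("summed-score recursion equals exhaustive pattern enumeration", {
  set.seed(404)
  g <- abilityGrid(nPoints = 15)
  for (rep in 1:8) {
    nI <- sample(2:4, 1); K <- sample(2:4, 1)
    its <- lapply(seq_len(nI), function(i) randomItem(paste0("i", i), m = K - 1L))
    sc <- scaleParameters("enum", its)
    sd_ <- summedScoreDistribution(sc, g)
    expect_lt(max(abs(sd_@mass - enumScoreDist(its, g@points))), 1e-12)
    # prior-weighted marginal distribution is a probability distribution
    expect_equal(sum(as.vector(crossprod(sd_@mass, g@weights))), 1,
                 tolerance = 1e-10)
  }
  # single item: base case reduces to the category probabilities
  it <- randomItem("solo")
  sd1 <- summedScoreDistribution(scaleParameters("s", list(it)), g)
  expect_equal(sd1@mass, unname(categoryProbs(it, g@points)), tolerance = 1e-14)
  # saturation: huge slope, theta above all thresholds -> all mass on max
  hot <- scaleParameters("h", list(itemParameters("h", 200, c(-2, -1.5, -1))))
  mh <- summedScoreDistribution(hot, abilityGrid(2, 4, 5))@mass
  expect_equal(mh[, 4], rep(1, 5), tolerance = 1e-12)
})

test_that("S-X2 is invariant to person order and non-target column order", {
  sc <- anchorScale4()
  sim <- simulateResponses(simulationDesign(sc, nPersons = 400,
                                            groupFraction = 0, seed = 61))
  g <- simGrid()
  f0 <- sx2ItemFit(sim$responses, sc, "item3", g)
  X <- responseCodes(sim$responses)
  perm <- sample(nrow(X))
  f1 <- sx2ItemFit(responseMatrix(X[perm, ], 6L), sc, "item3", g)
  expect_equal(f1@statistic, f0@statistic, tolerance = 1e-12)
  expect_identical(f1@df, f0@df)
  ord <- c(4, 2, 1, 3)                      # keep item3, shuffle the rest
  sc2 <- scaleParameters("anchors", sc@items[ord])
  f2 <- sx2ItemFit(responseMatrix(X[, ord], 6L), sc2, "item3", g)
  expect_equal(f2@statistic, f0@statistic, tolerance = 1e-12)
  # misfit flag is the p < alpha rule
  expect_identical(f0@misfit, f0@pValue < 0.01)
  expect_error(sx2ItemFit(sim$responses, sc, "nope", g), "no item")
})

test_that("S-X2 p-values are approximately uniform under the generating model", {
  p <- sx2NullSample()
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("S-X2 detects a mis-specified slope", {
  # responses generated with the slope doubled relative to the scale used
  # for the expected tables; no refitting, isolating the statistic's power
  sc <- anchorScale4()
  twisted <- sc
  twisted@items[[2]] <- itemParameters("item3", 2 * sc@items[[2]]@slope,
                                       sc@items[[2]]@thresholds)
  g <- simGrid()
  hits <- 0L
  for (i in 1:20) {
    sim <- simulateResponses(simulationDesign(twisted, nPersons = 1000,
                                              groupFraction = 0,
                                              missingRate = 0, seed = 500 + i))
    if (sx2ItemFit(sim$responses, sc, "item3", g)@misfit) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("expected cell counts respect the collapse threshold", {
  sc <- anchorScale4()
  sim <- simulateResponses(simulationDesign(sc, nPersons = 250,
                                            groupFraction = 0, seed = 62))
  f <- sx2ItemFit(sim$responses, sc, "item2", simGrid(), minExpected = 1)
  for (e in f@collapsedTable$expected) expect_true(all(e >= 1 | length(e) == 1L))
  expect_gte(f@df, 1L)
  expect_error(
    sx2ItemFit(responseMatrix(responseCodes(sim$responses)[1:5, ], 6L),
               sc, "item2", simGrid()), "insufficient")
})

test_that("residual correlation screen is quiet under local independence", {
  sc <- lvqolReferenceScales()[["Mobility"]]
  quiet <- 0L
  for (i in 1:100) {
    sim <- simulateResponses(simulationDesign(sc, nPersons = 1000,
                                              groupFraction = 0,
                                              missingRate = 0.02,
                                              seed = 700 + i))
    rc <- residualCorrelations(sim$responses, sc)
    if (max(abs(rc[upper.tri(rc)]), na.rm = TRUE) < 0.10) quiet <- quiet + 1L
    if (i == 1) {
      expect_equal(unname(diag(rc)), rep(1, 5))
      expect_s3_class(attr(rc, "flagged"), "data.frame")
    }
  }
  expect_gte(quiet, 95L)
})

test_that("residual correlation screen flags duplicated items", {
  sc <- lvqolReferenceScales()[["Mobility"]]
  sim <- simulateResponses(simulationDesign(sc, nPersons = 800,
                                            groupFraction = 0, seed = 71))
  X <- responseCodes(sim$responses)
  X2 <- cbind(X, X[, 2, drop = FALSE]); colnames(X2)[6] <- "dup"
  sc2 <- scaleParameters("m", c(sc@items, list(
    itemParameters("dup", sc@items[[2]]@slope, sc@items[[2]]@thresholds))))
  rc <- residualCorrelations(responseMatrix(X2, 6L), sc2)
  expect_gt(rc["item3", "dup"], 0.10)
  fl <- attr(rc, "flagged")
  expect_true(any(fl$item1 == "item3" & fl$item2 == "dup"))
  # a stricter threshold flags more, a looser one nothing
  rcLoose <- residualCorrelations(responseMatrix(X2, 6L), sc2,
                                  flagThreshold = 0.9)
  expect_identical(nrow(attr(rcLoose, "flagged")), 0L)
})
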