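# Independent oracles and shared fixtures. Oracles never call the code
# paths they check: information by finite differences of category
# probabilities, summed scores by exhaustive pattern enumeration,
# marginal likelihoods by direct quadrature formulas.

# Fisher information of one graded item by central finite differences of
# the category probabilities: sum_j (dP_j/dtheta)^2 / P_j
fisherInfoFD <- function(item, theta, h = 1e-5) {
  vapply(theta, function(t) {
    p0 <- categoryProbs(item, t)[1, ]
    d <- (categoryProbs(item, t + h)[1, ] - categoryProbs(item, t - h)[1, ]) / (2 * h)
    sum(d^2 / p0)
  }, numeric(1))
}

# summed-score distribution by exhaustive enumeration over all response
# patterns (feasible for <= 4 items x <= 4 categories)
enumScoreDist <- function(items, theta) {
  Ks <- vapply(items, nCategories, integer(1))
  maxS <- sum(Ks - 1L)
  M <- matrix(0, length(theta), maxS + 1L)
  pats <- expand.grid(lapply(Ks, function(k) 0:(k - 1L)))
  for (r in seq_len(nrow(pats))) {
    pr <- rep(1, length(theta))
    for (i in seq_along(items))
      pr <- pr * categoryProbs(items[[i]], theta)[, pats[r, i] + 1L]
    s <- sum(pats[r, ])
    M[, s + 1L] <- M[, s + 1L] + pr
  }
  M
}

randomItem <- function(id = "r", m = 5L) {
  itemParameters(id, runif(1, 0.5, 3), sort(rnorm(m)))
}

# a compact 4-item anchor scale used by the simulation studies (moderate
# and high slopes, realistic threshold spread)
anchorScale4 <- function() {
  scaleParameters("anchors",
                  lvqolReferenceScales()[["Mobility"]]@items[c(1, 2, 3, 5)])
}

simGrid <- function() abilityGrid(-5, 5, 21)

# session-level cache so expensive simulation studies run once and are
# shared between property tests and acceptance checks
.simCache <- new.env(parent = emptyenv())
cachedSim <- function(key, expr) {
  if (is.null(.simCache[[key]])) assign(key, force(expr), envir = .simCache)
  get(key, envir = .simCache)
}

# 500 null replicates of the likelihood-ratio slope (non-uniform DIF) test
# at n = 500 per group: both groups drawn from the same population with
# identical parameters; G^2 = 2(ll_free - ll_slopeEqual) on 1 df
nullDifSample <- function() cachedSim("nullDif", {
  sc <- anchorScale4(); g <- simGrid()
  t(vapply(1:500, function(i) {
    sim <- simulateResponses(simulationDesign(
      sc, nPersons = 1000, groupFraction = 0.5, missingRate = 0,
      seed = 2000 + i))
    fF <- fitTwoGroup(sim$responses, sim$groups, sc, "item3", "free",
                      g, tol = 3e-4, parTol = 3e-3, mstepIter = 2L)
    fS <- fitTwoGroup(sim$responses, sim$groups, sc, "item3", "slope-equal",
                      g, tol = 3e-4, parTol = 3e-3, mstepIter = 2L,
                      start = fF$state)
    g2 <- max(2 * (fF$logLik - fS$logLik), 0)
    c(g2Slope = g2, pSlope = pchisq(g2, 1, lower.tail = FALSE))
  }, numeric(2)))
})

# 200 null replicates of S-X2 with re-calibration on each replicate
sx2NullSample <- function() cachedSim("sx2Null", {
  sc <- anchorScale4(); g <- simGrid()
  vapply(1:200, function(i) {
    sim <- simulateResponses(simulationDesign(
      sc, nPersons = 500, groupFraction = 0, missingRate = 0, seed = 3000 + i))
    fit <- fitGRM(sim$responses, g, tol = 1e-3, parTol = 1e-3, start = sc)
    sx2ItemFit(sim$responses, calibratedScale(fit), "item3", g)@pValue
  }, numeric(1))
})

# one end-to-end pipeline run with a planted large uniform-DIF item
plantedPipeline <- function() cachedSim("plantedPipe", {
  sc <- lvqolReferenceScales()[["Reading and fine work"]]
  sim <- simulateResponses(simulationDesign(
    sc, nPersons = 600, groupFraction = 0.5,
    difEdits = list(list(itemId = "item21", kind = "uniform", magnitude = 1.3)),
    missingRate = 0.045, seed = 21))
  report <- runReevaluation(
    sim$responses, data.frame(gender = sim$groups),
    dimensions = list("Reading" = itemIds(sc)), grid = simGrid(),
    emTol = 1e-4, emParTol = 1e-3, mstepIter = 5L, seed = 5)
  list(sim = sim, report = report)
})

# synthetic DIFResult for decision-rule unit tests
makeDifResult <- function(itemId, variable, classification,
                          reference, focal, alpha = 0.01,
                          esGrid = seq(-8, 8, by = 0.01)) {
  es <- expectedScoreDIF(reference, focal, esGrid)
  m <- length(reference@thresholds)
  if (classification == "non-uniform") {
    pS <- 1e-4; g2T <- NA_real_; pT <- NA_real_
  } else {
    pS <- 0.5
    g2T <- 20; pT <- if (classification == "uniform") 1e-3 else 0.5
  }
  new("DIFResult", itemId = itemId, variable = variable,
      groupLabels = c("A", "B"),
      g2Slope = if (is.na(g2T)) 15 else 0.5, dfSlope = 1L, pSlope = pS,
      g2Thresholds = g2T, dfThresholds = as.integer(m), pThresholds = pT,
      classification = classification,
      esTheta = es$theta, esCurve = es$esCurve,
      esDeltaMax = es$esDeltaMax, thetaAtMax = es$thetaAtMax,
      groupParameters = list(reference = reference, focal = focal),
      focalMean = 0, focalSd = 1,
      logLik = c(free = 0, slopeEqual = 0, allEqual = 0), alpha = alpha)
}
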