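test_that("marginal log-likelihood matches direct quadrature", {
  g <- abilityGrid()
  # one person, one binary item, response 1: log sum_q w_q logistic(a(t_q-b))
  it <- itemParameters("i1", 1.4, 0.3)
  rm1 <- responseMatrix(matrix(1L, 1, 1, dimnames = list("p1", "i1")), 2L)
  sc <- scaleParameters("s", it)
  direct <- log(sum(g@weights * plogis(1.4 * (g@points - 0.3))))
  expect_equal(marginalLogLik(rm1, sc, g), direct, tolerance = 1e-10)
  # the default grid is quadrature-converged: 61 vs 101 points agree closely
  g101 <- abilityGrid(nPoints = 101)
  expect_lt(abs(marginalLogLik(rm1, sc, g) - marginalLogLik(rm1, sc, g101)),
            1e-4)
  # all-missing rows contribute an empty product: log-likelihood 0
  rmNA <- responseMatrix(matrix(NA_integer_, 2, 1,
                                dimnames = list(c("a", "b"), "i1")), 2L)
  expect_equal(marginalLogLik(rmNA, sc, g), 0)
  # duplicating every person exactly doubles the log-likelihood
  sim <- simulateResponses(simulationDesign(anchorScale4(), nPersons = 40,
                                            groupFraction = 0, seed = 8))
  X <- responseCodes(sim$responses)
  X2 <- rbind(X, X); rownames(X2) <- paste0("p", seq_len(nrow(X2)))
  expect_equal(marginalLogLik(responseMatrix(X2, 6L), anchorScale4(), g),
               2 * marginalLogLik(sim$responses, anchorScale4(), g),
               tolerance = 1e-10)
  expect_error(marginalLogLik(sim$responses, scaleParameters("s", it), g),
               "do not match")
})

test_that("EM calibration recovers generating parameters and is a fixed point", {
  sc <- anchorScale4()
  sim <- simulateResponses(simulationDesign(sc, nPersons = 600,
                                            groupFraction = 0, seed = 31))
  fit <- fitGRM(sim$responses, simGrid())
  expect_true(calibrationConverged(fit))
  est <- calibratedScale(fit)
  expect_lt(sqrt(mean((slopes(est) - slopes(sc))^2)), 0.5)
  expect_lt(sqrt(mean((unlist(thresholds(est)) - unlist(thresholds(sc)))^2)),
            0.25)
  # fitted marginal log-likelihood agrees with the independent evaluation
  expect_equal(marginalLogLik(sim$responses, est, simGrid()),
               calibrationLogLik(fit), tolerance = 1e-6)
  # thresholds of every fitted item remain strictly ordered
  for (b in thresholds(est)) expect_true(all(diff(b) > 0))
  # the solution is a fixed point: refitting from it moves nothing
  refit <- fitGRM(sim$responses, simGrid(), start = est)
  expect_true(calibrationConverged(refit))
  expect_lte(refit@nIterations, 30L)
  expect_equal(calibrationLogLik(refit), calibrationLogLik(fit),
               tolerance = 1e-6)
  expect_equal(slopes(calibratedScale(refit)), slopes(est), tolerance = 1e-3)
})

test_that("binary items match a direct optimizer of the same marginal likelihood", {
  set.seed(77)
  its <- list(itemParameters("a", 1.2, -0.5), itemParameters("b", 1.8, 0.2),
              itemParameters("c", 0.9, 0.7))
  sc <- scaleParameters("bin", its)
  sim <- simulateResponses(simulationDesign(sc, nPersons = 500,
                                            groupFraction = 0,
                                            missingRate = 0, seed = 78))
  g <- simGrid()
  fit <- fitGRM(sim$responses, g, tol = 1e-7, parTol = 1e-6)
  # brute-force route: direct BFGS on all 6 natural parameters at once
  X <- responseCodes(sim$responses)
  nll <- function(v) {
    if (any(v[c(1, 3, 5)] <= 0)) return(1e10)
    ll <- 0
    L <- matrix(1, nrow(X), length(g@points))
    for (i in 1:3) {
      ps <- plogis(v[2 * i - 1] * (g@points - v[2 * i]))
      L <- L * rbind(1 - ps, ps)[X[, i] + 1L, , drop = FALSE]
    }
    -sum(log(as.vector(L %*% g@weights)))
  }
  v0 <- c(1.2, -0.5, 1.8, 0.2, 0.9, 0.7)
  opt <- optim(v0, nll, method = "BFGS", control = list(maxit = 500,
                                                        reltol = 1e-12))
  est <- calibratedScale(fit)
  v <- as.vector(rbind(slopes(est), vapply(thresholds(est), `[`, numeric(1), 1)))
  expect_equal(v, opt$par, tolerance = 1e-3)
})

test_that("degenerate and gappy items are handled as specified", {
  sc <- anchorScale4()
  sim <- simulateResponses(simulationDesign(sc, nPersons = 300,
                                            groupFraction = 0, seed = 55))
  X <- responseCodes(sim$responses)
  # single observed category: hard error naming the item
  Xbad <- X; Xbad[, 2] <- 1L
  expect_error(fitGRM(responseMatrix(Xbad, 6L), simGrid()), "item3")
  # unobserved intermediate category: collapsed with the lower neighbour
  Xgap <- X; Xgap[Xgap[, 1] == 3L, 1] <- 2L
  fit <- fitGRM(responseMatrix(Xgap, 6L), simGrid())
  expect_named(fit@collapseMaps, "item2")
  expect_equal(nCategories(calibratedScale(fit))[[1]], 5L)
  expect_true(calibrationConverged(fit))
})

test_that("EAP scoring returns the prior for empty patterns and respects symmetry", {
  g <- abilityGrid()
  # two symmetric items; mirrored response patterns score as negatives
  its <- list(itemParameters("a", 1.5, c(-1, 0, 1)),
              itemParameters("b", 1.5, c(-1, 0, 1)))
  sc <- scaleParameters("sym", its)
  X <- matrix(c(0L, 1L,        # person 1
                3L, 2L,        # person 2: mirror of person 1
                NA, NA),       # person 3: nothing observed
              3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("a", "b")))
  ep <- eapScores(responseMatrix(X, 4L), sc, g)
  expect_equal(ep$eap[1], -ep$eap[2], tolerance = 1e-8)
  expect_equal(ep$eap[3], 0, tolerance = 1e-10)
  expect_equal(ep$posteriorSd[3], sqrt(sum(g@weights * g@points^2)),
               tolerance = 1e-10)
  expect_equal(ep$nObserved, c(2L, 2L, 0L))
  # posterior SD shrinks below the prior SD once something is observed
  expect_true(all(ep$posteriorSd[1:2] < 1))
})

test_that("subject separation behaves at its extremes and on realistic data", {
  ok <- data.frame(eap = c(-1, 0, 1), posteriorSd = c(1e-9, 1e-9, 1e-9),
                   nObserved = 3L)
  expect_equal(subjectSeparation(ok), 1.0, tolerance = 1e-12)
  flat <- data.frame(eap = rep(0.4, 5), posteriorSd = rep(0.5, 5),
                     nObserved = 2L)
  expect_equal(subjectSeparation(flat), 0.0)
  degenerate <- data.frame(eap = rep(0, 3), posteriorSd = rep(0, 3),
                           nObserved = 1L)
  expect_error(subjectSeparation(degenerate), "zero total variance")
  # a well-targeted 7-item scale separates simulated respondents sharply
  sc <- lvqolReferenceScales()[["Reading and fine work"]]
  sim <- simulateResponses(simulationDesign(sc, nPersons = 1000,
                                            groupFraction = 0, seed = 91))
  ep <- eapScores(sim$responses, sc, abilityGrid())
  expect_gt(cor(ep$eap, sim$truth$theta), 0.85)
  expect_gte(subjectSeparation(ep), 0.85)
})
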