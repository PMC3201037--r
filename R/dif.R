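# Two-group IRT likelihood-ratio DIF analysis: anchored multigroup
# marginal estimation with an estimated focal population (impact separated
# from DIF), hierarchical slope/threshold G^2 tests, expected-score DIF
# magnitude, and the item-removal rule.

.checkGroups <- function(groups, n, reference) {
  groups <- as.factor(groups)
  if (length(groups) != n) stop("'groups' must have one label per person")
  lev <- levels(droplevels(groups))
  if (length(lev) != 2L) stop("exactly two subgroup labels required, got: ",
                              paste(lev, collapse = ", "))
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference group '", reference, "' not found")
    lev <- c(reference, setdiff(lev, reference))
  }
  if (min(table(groups)) < 2L) stop("each subgroup needs at least 2 persons")
  factor(as.character(groups), levels = lev)
}

# Multigroup EM with the reference prior fixed at N(0,1) and the focal
# prior N(mu, sigma) estimated. All items except `studied` are anchors
# (equal across groups). The studied item obeys `constraint`.
.fitTwoGroupCore <- function(XR, XF, Ks, studied, constraint, points, wR,
                             startPars, startStudiedFocal, startFocal,
                             tol, parTol, maxIter, mstepIter = 10L) {
  nI <- length(Ks)
  pars <- startPars                      # free-par vector per item (reference)
  parF <- startStudiedFocal              # focal studied item (free par)
  mu <- startFocal[1]; sg <- startFocal[2]
  m <- Ks[studied] - 1L
  # make the start obey the constraint, so EM monotonicity holds from the
  # first iteration even when warm-started from a less constrained fit
  if (constraint == "all-equal") {
    parF <- pars[[studied]]
  } else if (constraint == "slope-equal") {
    shared <- (pars[[studied]][1] + parF[1]) / 2
    pars[[studied]][1] <- shared; parF[1] <- shared
  }

  jointPar <- function() {               # slope-equal packing
    pR <- pars[[studied]]; pF <- parF
    c(pR[1], pR[-1], pF[-1])
  }
  unpackJoint <- function(v) {
    list(ref = c(v[1], v[2:(m + 1L)]), foc = c(v[1], v[(m + 2L):(2L * m + 1L)]))
  }

  llOld <- -Inf; converged <- FALSE; iter <- 0L
  repeat {
    PR <- lapply(pars, .probMatFree, theta = points)
    PF <- PR
    if (constraint != "all-equal") PF[[studied]] <- .probMatFree(parF, points)
    wF <- dnorm(points, mu, sg); wF <- wF / sum(wF)
    eR <- .estep(XR, PR, wR)
    eF <- .estep(XF, PF, wF)
    ll <- eR$logLik + eF$logLik
    if (ll < llOld - 1e-8)
      warning(sprintf("two-group EM log-likelihood decreased (%.3g)", llOld - ll))
    if (iter >= maxIter) { llOld <- ll; break }
    iter <- iter + 1L
    parOldFlat <- c(unlist(pars), parF, mu, sg)

    for (i in seq_len(nI)[-studied])
      pars[[i]] <- .mstepItem(eR$counts[[i]] + eF$counts[[i]], pars[[i]],
                              points, mstepIter)
    rR <- eR$counts[[studied]]; rF <- eF$counts[[studied]]
    if (constraint == "all-equal") {
      pars[[studied]] <- .mstepItem(rR + rF, pars[[studied]], points, mstepIter)
      parF <- pars[[studied]]
    } else if (constraint == "free") {
      pars[[studied]] <- .mstepItem(rR, pars[[studied]], points, mstepIter)
      parF <- .mstepItem(rF, parF, points, mstepIter)
    } else {                             # slope-equal, thresholds free
      nll <- function(v) {
        u <- unpackJoint(v)
        pR_ <- .fromFree(u$ref); pF_ <- .fromFree(u$foc)
        .nllNatural(rR, pR_$slope, pR_$thresholds, points)$value +
          .nllNatural(rF, pF_$slope, pF_$thresholds, points)$value
      }
      gr <- function(v) {
        u <- unpackJoint(v)
        pR_ <- .fromFree(u$ref); pF_ <- .fromFree(u$foc)
        dR <- .nllNatural(rR, pR_$slope, pR_$thresholds, points)
        dF <- .nllNatural(rF, pF_$slope, pF_$thresholds, points)
        gR <- .freeGrad(u$ref, dR$dSlope, dR$dThr)
        gF <- .freeGrad(u$foc, dF$dSlope, dF$dThr)
        c(gR[1] + gF[1], gR[-1], gF[-1])
      }
      v <- optim(jointPar(), nll, gr, method = "BFGS",
                 control = list(maxit = mstepIter))$par
      u <- unpackJoint(v)
      pars[[studied]] <- u$ref; parF <- u$foc
    }
    nq <- colSums(eF$posterior)          # expected focal counts per node
    nllF <- function(v) {
      if (v[2] < log(1e-3)) return(Inf)
      w <- dnorm(points, v[1], exp(v[2]))
      s <- sum(w)
      if (s <= 0) return(Inf)
      -sum(nq * log(pmax(w / s, .EPS)))
    }
    vF <- optim(c(mu, log(sg)), nllF, method = "BFGS",
                control = list(maxit = 10))$par
    mu <- vF[1]; sg <- exp(vF[2])

    dPar <- max(abs(c(unlist(pars), parF, mu, sg) - parOldFlat))
    if (abs(ll - llOld) < tol && dPar < parTol) {
      converged <- TRUE; llOld <- ll; break
    }
    llOld <- ll
  }
  list(pars = pars, parFocal = parF, logLik = llOld, focalMean = mu,
       focalSd = sg, nIterations = iter, converged = converged)
}

#' Anchored two-group GRM fit for DIF testing
#'
#' Fits the graded response model to two subgroups jointly: all items other
#' than the studied one are anchors constrained equal across groups; the
#' reference-group trait prior is fixed at N(0,1) while the focal group's
#' prior mean and SD are estimated, so that population impact is separated
#' from item DIF. The studied item's parameters obey `constraint`:
#' `"all-equal"` (no DIF), `"slope-equal"` (thresholds free across groups),
#' or `"free"` (slope and thresholds free).
#'
#' @param responses a [ResponseMatrix-class].
#' @param groups two-level factor (or character) of subgroup labels.
#' @param scale starting/anchor [ScaleParameters-class] (typically the
#'   pooled calibration of the dimension).
#' @param studiedItem item id under study.
#' @param constraint `"all-equal"`, `"slope-equal"` or `"free"`.
#' @param grid an [AbilityGrid-class] (points shared by both groups;
#'   reference weights standard normal).
#' @param reference reference-group label (default: first factor level).
#' @param tol,parTol,maxIter,mstepIter EM controls as in [fitGRM()].
#' @param start optional warm start: list with `pars`, `parFocal`,
#'   `focalMean`, `focalSd` from a previous fit.
#' @return list with `reference`/`focal` ([ScaleParameters-class] per
#'   group), `studiedReference`/`studiedFocal` ([ItemParameters-class]),
#'   `logLik`, `focalMean`, `focalSd`, `nIterations`, `converged`, and the
#'   internal state (`state`) reusable as `start`.
#' @export
fitTwoGroup <- function(responses, groups, scale, studiedItem,
                        constraint = c("all-equal", "slope-equal", "free"),
                        grid = abilityGrid(), reference = NULL,
                        tol = 1e-5, parTol = 1e-4, maxIter = 500L,
                        start = NULL, mstepIter = 10L) {
  constraint <- match.arg(constraint)
  stopifnot(is(responses, "ResponseMatrix"), is(scale, "ScaleParameters"))
  .checkScaleMatch(responses, scale)
  if (length(scale@items) < 2L)
    stop("anchored DIF testing needs at least one anchor item besides the studied item")
  X <- responses@codes
  groups <- .checkGroups(groups, nrow(X), reference)
  ids <- itemIds(scale)
  studied <- match(studiedItem, ids)
  if (is.na(studied)) stop("no item '", studiedItem, "' in the scale")
  XR <- X[groups == levels(groups)[1], , drop = FALSE]
  XF <- X[groups == levels(groups)[2], , drop = FALSE]
  for (Xg in list(XR, XF))
    if (all(is.na(Xg[, studied])))
      stop("a subgroup has no observations on studied item '", studiedItem, "'")
  Ks <- vapply(scale@items, function(i) length(i@thresholds) + 1L, integer(1))

  if (is.null(start)) {
    startPars <- lapply(scale@items, function(i) .toFree(i@slope, i@thresholds))
    start <- list(pars = startPars, parFocal = startPars[[studied]],
                  focalMean = 0, focalSd = 1)
  }
  fit <- .fitTwoGroupCore(XR, XF, Ks, studied, constraint, grid@points,
                          grid@weights, start$pars, start$parFocal,
                          c(start$focalMean, start$focalSd),
                          tol, parTol, maxIter, mstepIter)
  natural <- function(par, id) {
    p <- .fromFree(par); itemParameters(id, p$slope, p$thresholds)
  }
  refItems <- lapply(seq_along(ids), function(i) natural(fit$pars[[i]], ids[i]))
  focItems <- refItems
  focItems[[studied]] <- natural(fit$parFocal, ids[studied])
  list(reference = scaleParameters(scale@scaleName, refItems),
       focal = scaleParameters(scale@scaleName, focItems),
       studiedReference = refItems[[studied]],
       studiedFocal = focItems[[studied]],
       logLik = fit$logLik, focalMean = fit$focalMean, focalSd = fit$focalSd,
       nIterations = fit$nIterations, converged = fit$converged,
       groupLabels = levels(groups), constraint = constraint,
       state = list(pars = fit$pars, parFocal = fit$parFocal,
                    focalMean = fit$focalMean, focalSd = fit$focalSd))
}

#' Expected-score DIF curve and magnitude
#'
#' Difference between two groups' expected item scores across the trait
#' continuum. The magnitude of DIF is the signed difference of largest
#' absolute value over the scan grid (first group minus second), reported
#' with its location (smallest such theta on ties). The default grid
#' extends to \[-8, 8\] because threshold DIF can push the maximum far into
#' the tails (the LVQOL analysis reports one maximum at theta = 5.40).
#'
#' @param groupA,groupB [ItemParameters-class] of the two groups (equal
#'   category counts).
#' @param theta strictly increasing scan grid (default
#'   `seq(-8, 8, by = 0.01)`).
#' @return list with `theta`, `esCurve` (A minus B per grid point),
#'   `esDeltaMax` and `thetaAtMax`.
#' @examples
#' row <- lvqolDIFTable()[[7]]    # item 24, male vs female
#' expectedScoreDIF(row$reference, row$focal)$esDeltaMax   # -1.22
#' @export
expectedScoreDIF <- function(groupA, groupB, theta = seq(-8, 8, by = 0.01)) {
  stopifnot(is(groupA, "ItemParameters"), is(groupB, "ItemParameters"))
  if (length(groupA@thresholds) != length(groupB@thresholds))
    stop("groups must have the same number of response categories")
  if (is.unsorted(theta, strictly = TRUE))
    stop("'theta' must be strictly increasing")
  es <- .expScore(groupA@slope, groupA@thresholds, theta) -
        .expScore(groupB@slope, groupB@thresholds, theta)
  i <- which.max(abs(es))          # first index on exact ties
  list(theta = theta, esCurve = es, esDeltaMax = es[i], thetaAtMax = theta[i])
}

#' Hierarchical likelihood-ratio DIF test for one item
#'
#' Fits the anchored two-group model with the studied item free,
#' slope-equal and all-equal, and performs the hierarchical scheme: the
#' slope (non-uniform DIF) test G^2 = 2(ll_free - ll_slopeEqual) on 1 df;
#' only when it is not significant at `alpha`, the threshold (uniform DIF)
#' test G^2 = 2(ll_slopeEqual - ll_allEqual) on m df (m = number of
#' thresholds, 5 for 6-category items). The expected-score DIF curve is
#' computed from the least-constrained significant model (free for
#' non-uniform, slope-equal for uniform) or the all-equal model when no
#' DIF is found (zero curve).
#'
#' @inheritParams fitTwoGroup
#' @param alpha per-test significance level (default 0.01, the level used
#'   as multiple-testing control in the LVQOL analysis).
#' @param esGrid scan grid for [expectedScoreDIF()].
#' @param variable subgroup variable name recorded in the result.
#' @return a [DIFResult-class].
#' @export
difTest <- function(responses, groups, scale, studiedItem,
                    grid = abilityGrid(), reference = NULL, alpha = 0.01,
                    esGrid = seq(-8, 8, by = 0.01), variable = "group",
                    tol = 1e-5, parTol = 1e-4, maxIter = 500L,
                    mstepIter = 10L) {
  fFree <- fitTwoGroup(responses, groups, scale, studiedItem, "free",
                       grid, reference, tol, parTol, maxIter,
                       mstepIter = mstepIter)
  stFree <- fFree$state
  stSE <- stFree
  stSE$pars[[match(studiedItem, itemIds(scale))]] <-
    local({  # shared-slope start: average the two groups' log-slopes
      pR <- stFree$pars[[match(studiedItem, itemIds(scale))]]
      pR[1] <- (pR[1] + stFree$parFocal[1]) / 2; pR
    })
  stSE$parFocal[1] <- stSE$pars[[match(studiedItem, itemIds(scale))]][1]
  fSE <- fitTwoGroup(responses, groups, scale, studiedItem, "slope-equal",
                     grid, reference, tol, parTol, maxIter, start = stSE,
                     mstepIter = mstepIter)
  fAE <- fitTwoGroup(responses, groups, scale, studiedItem, "all-equal",
                     grid, reference, tol, parTol, maxIter, start = fSE$state,
                     mstepIter = mstepIter)

  m <- length(scaleItem(scale, studiedItem)@thresholds)
  g2Slope <- max(2 * (fFree$logLik - fSE$logLik), 0)
  pSlope <- pchisq(g2Slope, 1, lower.tail = FALSE)
  if (pSlope < alpha) {
    g2Thr <- NA_real_; pThr <- NA_real_
    classification <- "non-uniform"
    esFit <- fFree
  } else {
    g2Thr <- max(2 * (fSE$logLik - fAE$logLik), 0)
    pThr <- pchisq(g2Thr, m, lower.tail = FALSE)
    classification <- if (pThr < alpha) "uniform" else "none"
    esFit <- if (pThr < alpha) fSE else fAE
  }
  es <- expectedScoreDIF(esFit$studiedReference, esFit$studiedFocal, esGrid)
  new("DIFResult", itemId = studiedItem, variable = variable,
      groupLabels = fFree$groupLabels,
      g2Slope = g2Slope, dfSlope = 1L, pSlope = pSlope,
      g2Thresholds = g2Thr, dfThresholds = as.integer(m), pThresholds = pThr,
      classification = classification,
      esTheta = es$theta, esCurve = es$esCurve,
      esDeltaMax = es$esDeltaMax, thetaAtMax = es$thetaAtMax,
      groupParameters = list(reference = esFit$studiedReference,
                             focal = esFit$studiedFocal),
      focalMean = esFit$focalMean, focalSd = esFit$focalSd,
      logLik = c(free = fFree$logLik, slopeEqual = fSE$logLik,
                 allEqual = fAE$logLik),
      alpha = alpha)
}

#' Item-removal decision from DIF profiles
#'
#' Applies the removal rule to all DIF results of one item: remove when
#' (a) any expected-score DIF magnitude exceeds `esThreshold` (1 point on
#' the 0-5 scale), (b) significant DIF occurs on at least `minVariables`
#' subgroup variables, or (c) DIF extends over a large part of the
#' disability continuum — operationalised as the expected-score difference
#' exceeding `extentEs` over a trait region carrying at least `extentMass`
#' of standard-normal probability.
#'
#' @param results list of [DIFResult-class] objects for a single item
#'   (one per subgroup variable).
#' @param esThreshold clause (a) magnitude (default 1.0 score points).
#' @param minVariables clause (b) count (default 2).
#' @param extentEs,extentMass clause (c) operationalisation (defaults 0.5
#'   points over >= 25% of standard-normal mass).
#' @return list with `remove` (logical), `reasons` (character; triggered
#'   clauses) and `itemId`.
#' @export
removalDecision <- function(results, esThreshold = 1.0, minVariables = 2L,
                            extentEs = 0.5, extentMass = 0.5) {
  if (!length(results)) stop("empty DIF result list")
  stopifnot(all(vapply(results, is, logical(1), "DIFResult")))
  ids <- unique(vapply(results, function(r) r@itemId, character(1)))
  if (length(ids) != 1L) stop("all DIF results must refer to one item")
  reasons <- character()
  esMax <- vapply(results, function(r) r@esDeltaMax, numeric(1))
  if (any(abs(esMax) > esThreshold)) {
    vars <- vapply(results, function(r) r@variable, character(1))
    reasons <- c(reasons, sprintf(
      "expected-score difference > %.1f points (|ES| = %.2f on '%s')",
      esThreshold, max(abs(esMax)), vars[which.max(abs(esMax))]))
  }
  sig <- vapply(results, function(r) r@classification != "none", logical(1))
  if (sum(sig) >= minVariables) {
    reasons <- c(reasons, sprintf(
      "significant DIF on %d subgroup variables (%s)", sum(sig),
      paste(vapply(results[sig], function(r) r@variable, character(1)),
            collapse = ", ")))
  }
  for (r in results) {
    mass <- sum(stats::dnorm(r@esTheta)[abs(r@esCurve) > extentEs]) *
      mean(diff(r@esTheta))
    if (mass >= extentMass) {
      reasons <- c(reasons, sprintf(
        "|ES| > %.2f over %.0f%% of the trait distribution on '%s'",
        extentEs, 100 * mass, r@variable))
      break
    }
  }
  list(itemId = ids, remove = length(reasons) > 0L, reasons = reasons)
}
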