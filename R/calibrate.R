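# Marginal maximum likelihood calibration of the graded response model:
# Bock-Aitkin EM over a fixed quadrature grid, EAP person scoring, and
# subject-separation (empirical) reliability.

# --- free parameterization keeping every iterate valid --------------------
# par = (log slope, first threshold, log increments); guarantees slope > 0
# and strictly increasing thresholds in every EM iterate.
.toFree <- function(slope, thresholds) {
  d <- diff(thresholds)
  c(log(slope), thresholds[1], if (length(d)) log(pmax(d, 1e-6)))
}

.fromFree <- function(par) {
  thr <- cumsum(c(par[2], exp(par[-(1:2)])))
  list(slope = exp(par[1]), thresholds = thr)
}

.probMatFree <- function(par, theta) {
  p <- .fromFree(par)
  .catProbs(p$slope, p$thresholds, theta)
}

# E-step likelihood: persons x grid matrix of response-pattern likelihoods.
# Pmats: list (per item) of Q x K_i category-probability matrices.
# Missing codes contribute a factor 1 (ignorable missingness).
.patternLik <- function(X, Pmats) {
  n <- nrow(X); Q <- nrow(Pmats[[1]])
  L <- matrix(1, n, Q)
  for (i in seq_along(Pmats)) {
    K <- ncol(Pmats[[i]])
    Paug <- cbind(Pmats[[i]], 1)
    idx <- X[, i] + 1L
    idx[is.na(idx)] <- K + 1L
    L <- L * t(Paug[, idx, drop = FALSE])
  }
  L
}

# posterior weights, expected category counts and marginal log-likelihood
.estep <- function(X, Pmats, weights) {
  L <- .patternLik(X, Pmats)
  M <- t(t(L) * weights)
  denom <- rowSums(M)
  ll <- sum(log(denom))
  post <- M / denom
  counts <- vector("list", length(Pmats))
  for (i in seq_along(Pmats)) {
    K <- ncol(Pmats[[i]])
    Ind <- matrix(0, nrow(X), K)
    obs <- which(!is.na(X[, i]))
    Ind[cbind(obs, X[obs, i] + 1L)] <- 1
    counts[[i]] <- crossprod(post, Ind)       # Q x K expected counts
  }
  list(logLik = ll, posterior = post, counts = counts)
}

# negative expected complete-data log-likelihood and its analytic gradient
# with respect to the natural parameters (slope, thresholds).
# r: Q x K expected counts. Returns list(value, dSlope, dThr).
.nllNatural <- function(r, slope, thr, theta) {
  ps <- cbind(1, .cumProbs(slope, thr, theta), 0)     # Q x (m+2) boundaries
  m1 <- length(thr) + 1L
  P <- pmax(ps[, 1:m1, drop = FALSE] - ps[, 2:(m1 + 1L), drop = FALSE], .EPS)
  val <- -sum(r * log(P))
  ratio <- r / P                                       # Q x K
  # D_qk = ratio at category k minus ratio at category k-1, boundaries k=1..m
  D <- ratio[, 2:m1, drop = FALSE] - ratio[, 1:(m1 - 1L), drop = FALSE]
  s <- ps[, 2:m1, drop = FALSE] * (1 - ps[, 2:m1, drop = FALSE])
  Ds <- D * s
  dA <- -sum(Ds * outer(theta, thr, "-"))
  dB <- slope * colSums(Ds)
  list(value = val, dSlope = dA, dThr = dB)
}

# chain rule from natural to free parameters (log slope, b1, log increments)
.freeGrad <- function(par, dSlope, dThr) {
  m <- length(dThr)
  g <- numeric(length(par))
  g[1] <- dSlope * exp(par[1])
  g[2] <- sum(dThr)
  if (m > 1L)
    g[3:(m + 1L)] <- exp(par[3:(m + 1L)]) *
      rev(cumsum(rev(dThr)))[-1]                       # sum over k >= t+1
  g
}

# M-step for one item: maximize sum(r * log P) over the free parameters
.mstepItem <- function(r, parStart, theta, maxit = 10L) {
  nll <- function(par) {
    p <- .fromFree(par)
    .nllNatural(r, p$slope, p$thresholds, theta)$value
  }
  gr <- function(par) {
    p <- .fromFree(par)
    d <- .nllNatural(r, p$slope, p$thresholds, theta)
    .freeGrad(par, d$dSlope, d$dThr)
  }
  # a few quasi-Newton steps per EM cycle (generalized EM): the E-step is
  # re-run so often that fully maximizing each M-step is wasted effort
  fit <- optim(parStart, nll, gr, method = "BFGS",
               control = list(maxit = maxit))
  fit$par
}

.checkScaleMatch <- function(responses, scale) {
  if (!identical(itemIds(scale), colnames(responses@codes)))
    stop("scale items and response columns do not match: [",
         paste(itemIds(scale), collapse = ", "), "] vs [",
         paste(colnames(responses@codes), collapse = ", "), "]")
}

#' Marginal log-likelihood of a graded response model
#'
#' Log-likelihood of the response matrix with the latent trait integrated
#' out over the quadrature grid: for each person, the log of the
#' prior-weighted sum over grid points of the product of category
#' probabilities of the observed responses (missing entries skipped).
#'
#' @param responses a [ResponseMatrix-class]; columns must match the scale's
#'   items in order.
#' @param scale a [ScaleParameters-class].
#' @param grid an [AbilityGrid-class].
#' @return single numeric value.
#' @export
marginalLogLik <- function(responses, scale, grid = abilityGrid()) {
  stopifnot(is(responses, "ResponseMatrix"), is(scale, "ScaleParameters"),
            is(grid, "AbilityGrid"))
  .checkScaleMatch(responses, scale)
  Pmats <- lapply(scale@items,
                  function(i) .catProbs(i@slope, i@thresholds, grid@points))
  L <- .patternLik(responses@codes, Pmats)
  sum(log(as.vector(L %*% grid@weights)))
}

# collapse unobserved intermediate categories of one item's codes onto the
# lower observed neighbour; returns recoded vector, new K and the mapping
.collapseItem <- function(x, K) {
  obs <- sort(unique(x[!is.na(x)]))
  if (length(obs) == K) return(list(x = x, K = K, map = NULL))
  map <- match(x, obs) - 1L                 # rank among observed codes
  list(x = map, K = length(obs),
       map = setNames(seq_along(obs) - 1L, obs))
}

#' Fit the graded response model by marginal maximum likelihood
#'
#' Bock-Aitkin EM with a fixed standard-normal latent-trait prior: the
#' E-step forms posterior weights of each person over the quadrature grid;
#' the M-step maximises each item's expected complete-data log-likelihood by
#' quasi-Newton search in a parameterization (log slope, first threshold,
#' log threshold increments) under which every iterate is a valid ordered
#' GRM. The prior is never re-standardised after fitting, which identifies
#' the scale. Missing responses are treated as ignorable and skipped.
#'
#' Items for which an intermediate category was never observed are collapsed
#' onto the lower neighbouring category for estimation; the applied mapping
#' is reported in the result. An item with fewer than two observed
#' categories is an error.
#'
#' @param responses a [ResponseMatrix-class].
#' @param grid an [AbilityGrid-class] (default 61 points on \[-6, 6\] with
#'   standard-normal weights).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-5).
#' @param parTol maximum absolute parameter change tolerance (default 1e-4).
#' @param maxIter maximum EM iterations (default 500); exceeding it flags
#'   `converged = FALSE` rather than erroring.
#' @param start optional [ScaleParameters-class] of starting values.
#' @param standardErrors compute parameter standard errors from the inverse
#'   finite-difference observed-information matrix (default `FALSE`; adds
#'   O(p^2) likelihood evaluations).
#' @param mstepIter quasi-Newton steps per item per M-step (generalized EM;
#'   smaller values trade more, cheaper EM iterations).
#' @param scaleName label for the fitted scale.
#' @return a [CalibrationResult-class].
#' @examples
#' sim <- simulateResponses(simulationDesign(
#'   scale = lvqolReferenceScales()[["Adjustment"]], nPersons = 300, seed = 7))
#' fit <- fitGRM(sim$responses)
#' calibratedScale(fit)
#' @export
fitGRM <- function(responses, grid = abilityGrid(), tol = 1e-5, parTol = 1e-4,
                   maxIter = 500L, start = NULL, standardErrors = FALSE,
                   mstepIter = 10L, scaleName = "scale") {
  stopifnot(is(responses, "ResponseMatrix"), is(grid, "AbilityGrid"))
  X <- responses@codes
  K0 <- responses@nCategories
  nI <- ncol(X)
  ids <- colnames(X)

  # per-item category usability + collapse of unobserved intermediates
  Ks <- integer(nI); maps <- setNames(vector("list", nI), ids)
  for (i in seq_len(nI)) {
    nObsCat <- length(unique(X[!is.na(X[, i]), i]))
    if (nObsCat < 2L)
      stop("degenerate item '", ids[i], "': fewer than 2 observed categories")
    cl <- .collapseItem(X[, i], K0)
    X[, i] <- cl$x; Ks[i] <- cl$K; maps[[i]] <- cl$map
  }
  maps <- maps[!vapply(maps, is.null, logical(1))]

  theta <- grid@points; w <- grid@weights
  pars <- vector("list", nI)
  if (!is.null(start)) {
    stopifnot(is(start, "ScaleParameters"))
    if (!identical(itemIds(start), ids)) stop("'start' items do not match responses")
    for (i in seq_len(nI))
      pars[[i]] <- .toFree(start@items[[i]]@slope, start@items[[i]]@thresholds)
  } else {
    for (i in seq_len(nI)) {
      pj <- vapply(seq_len(Ks[i] - 1L),
                   function(j) mean(X[, i] >= j, na.rm = TRUE), numeric(1))
      pj <- pmin(pmax(pj, 1e-3), 1 - 1e-3)
      b0 <- -qlogis(pj)
      b0 <- cummax(b0 + seq_along(b0) * 1e-6)  # enforce strict order at start
      pars[[i]] <- .toFree(1, b0)
    }
  }

  llOld <- -Inf; converged <- FALSE; iter <- 0L
  repeat {
    Pmats <- lapply(pars, .probMatFree, theta = theta)
    e <- .estep(X, Pmats, w)
    if (e$logLik < llOld - 1e-8)
      warning(sprintf("EM log-likelihood decreased at iteration %d (%.3g)",
                      iter, llOld - e$logLik))
    parOld <- pars
    if (iter >= maxIter) { llOld <- e$logLik; break }
    iter <- iter + 1L
    for (i in seq_len(nI))
      pars[[i]] <- .mstepItem(e$counts[[i]], pars[[i]], theta, mstepIter)
    dPar <- max(abs(unlist(lapply(seq_len(nI), function(i) {
      a <- .fromFree(pars[[i]]); b <- .fromFree(parOld[[i]])
      c(a$slope - b$slope, a$thresholds - b$thresholds)
    }))))
    if (abs(e$logLik - llOld) < tol && dPar < parTol) {
      converged <- TRUE; llOld <- e$logLik; break
    }
    llOld <- e$logLik
  }

  items <- lapply(seq_len(nI), function(i) {
    p <- .fromFree(pars[[i]])
    itemParameters(ids[i], p$slope, p$thresholds)
  })
  scale <- scaleParameters(scaleName, items)

  se <- rep(NA_real_, sum(Ks))
  names(se) <- unlist(lapply(seq_len(nI), function(i)
    paste0(ids[i], ".", c("slope", paste0("b", seq_len(Ks[i] - 1L))))))
  if (standardErrors) se[] <- .observedInfoSE(X, scale, grid)
  new("CalibrationResult", scale = scale, standardErrors = se,
      logLik = llOld, nIterations = iter, converged = converged,
      grid = grid, collapseMaps = maps)
}

# standard errors from the finite-difference observed-information matrix of
# the marginal log-likelihood at the solution (natural parameterization)
.observedInfoSE <- function(X, scale, grid, h = 1e-4) {
  theta <- grid@points; w <- grid@weights
  pack <- unlist(lapply(scale@items, function(i) c(i@slope, i@thresholds)))
  sizes <- vapply(scale@items, function(i) length(i@thresholds) + 1L, integer(1))
  ll <- function(v) {
    off <- 0; Pmats <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      sl <- v[off + 1L]; th <- v[off + 1L + seq_len(sizes[i] - 1L)]
      if (sl <= 0 || is.unsorted(th)) return(NA_real_)
      Pmats[[i]] <- .catProbs(sl, th, theta)
      off <- off + sizes[i]
    }
    sum(log(as.vector(.patternLik(X, Pmats) %*% w)))
  }
  p <- length(pack)
  H <- matrix(NA_real_, p, p)
  f0 <- ll(pack)
  for (a in seq_len(p)) for (b in a:p) {
    ea <- eb <- rep(0, p); ea[a] <- h; eb[b] <- h
    if (a == b) {
      H[a, a] <- (ll(pack + ea) - 2 * f0 + ll(pack - ea)) / h^2
    } else {
      H[a, b] <- H[b, a] <-
        (ll(pack + ea + eb) - ll(pack + ea - eb) -
         ll(pack - ea + eb) + ll(pack - ea - eb)) / (4 * h^2)
    }
  }
  V <- try(solve(-H), silent = TRUE)
  if (inherits(V, "try-error") || anyNA(V) || any(diag(V) <= 0)) {
    warning("observed-information matrix not positive definite; SEs set to NA")
    return(rep(NA_real_, p))
  }
  sqrt(diag(V))
}

#' Expected a posteriori (EAP) person scores
#'
#' Posterior mean and standard deviation of the latent trait for every
#' person, given a calibrated scale and the prior grid. Persons without any
#' observed response carry the prior mean and SD.
#'
#' @param responses a [ResponseMatrix-class].
#' @param scale a calibrated [ScaleParameters-class] (or a
#'   [CalibrationResult-class], whose scale and grid are then used).
#' @param grid an [AbilityGrid-class].
#' @return data.frame with columns `person`, `eap`, `posteriorSd`,
#'   `nObserved`, in input person order.
#' @export
eapScores <- function(responses, scale, grid = abilityGrid()) {
  if (is(scale, "CalibrationResult")) {
    grid <- scale@grid; scale <- scale@scale
  }
  stopifnot(is(responses, "ResponseMatrix"), is(scale, "ScaleParameters"),
            is(grid, "AbilityGrid"))
  .checkScaleMatch(responses, scale)
  X <- responses@codes
  Pmats <- lapply(scale@items,
                  function(i) .catProbs(i@slope, i@thresholds, grid@points))
  L <- .patternLik(X, Pmats)
  M <- t(t(L) * grid@weights)
  post <- M / rowSums(M)
  eap <- as.vector(post %*% grid@points)
  m2 <- as.vector(post %*% grid@points^2)
  data.frame(person = rownames(X), eap = eap,
             posteriorSd = sqrt(pmax(m2 - eap^2, 0)),
             nObserved = rowSums(!is.na(X)), row.names = NULL)
}

#' Index of subject separation (empirical reliability)
#'
#' Reliability of the EAP trait estimates:
#' \eqn{\mathrm{var}(\hat\theta) / (\mathrm{var}(\hat\theta) +
#' \overline{\mathrm{SD}^2_{post}})} — the ratio of between-person variance
#' to between-person plus average posterior variance.
#'
#' @param posteriors data.frame from [eapScores()].
#' @return value in \[0, 1\].
#' @export
subjectSeparation <- function(posteriors) {
  stopifnot(is.data.frame(posteriors),
            all(c("eap", "posteriorSd") %in% names(posteriors)))
  keep <- posteriors$nObserved >= 1L
  if (sum(keep) < 2L) stop("need at least 2 persons with observed responses")
  v <- var(posteriors$eap[keep])
  tot <- v + mean(posteriors$posteriorSd[keep]^2)
  if (tot <= 0) stop("undefined reliability: zero total variance")
  v / tot
}
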