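# S-X2-type goodness-of-fit for graded items via summed-score
# distributions, and a residual-correlation screen for local dependence.

#' Conditional summed-score distribution of a scale
#'
#' Distribution of the scale sum score given the latent trait, at every grid
#' point, via the Lord-Wingersky recursion generalised to polytomous items:
#' the score distribution after adding an item is the convolution of the
#' previous distribution with that item's category probabilities.
#'
#' @param scale a [ScaleParameters-class].
#' @param grid an [AbilityGrid-class].
#' @return a [ScoreDistribution-class] with support
#'   `0..sum(nCategories - 1)`.
#' @export
summedScoreDistribution <- function(scale, grid = abilityGrid()) {
  stopifnot(is(scale, "ScaleParameters"), is(grid, "AbilityGrid"))
  .scoreMass(scale@items, grid@points)
}

# recursion core on a plain item list / theta vector; returns ScoreDistribution
.scoreMass <- function(items, theta) {
  Q <- length(theta)
  M <- matrix(1, Q, 1)
  for (it in items) {
    P <- .catProbs(it@slope, it@thresholds, theta)   # Q x K
    K <- ncol(P)
    S <- ncol(M)
    out <- matrix(0, Q, S + K - 1L)
    for (k in seq_len(K))
      out[, k:(k + S - 1L)] <- out[, k:(k + S - 1L)] + M * P[, k]
    M <- out
  }
  new("ScoreDistribution", support = 0:(ncol(M) - 1L), mass = M, theta = theta)
}

# observed/expected collapsing for the S-X2 table.
# O, E: score-group x category matrices (equal row sums). Returns retained
# cell lists per merged group.
.collapseTable <- function(O, E, K, minExpected) {
  # phase A: merge rest-score groups until each could hold all cells at the
  # minimum count (row total >= K * minExpected); sparse rows fold inward
  # from the tails, interior rows toward their nearer tail.
  groups <- as.list(seq_len(nrow(O)))
  repeat {
    tots <- vapply(groups, function(g) sum(E[g, ]), numeric(1))
    bad <- which(tots < K * minExpected)
    if (!length(bad) || length(groups) == 1L) break
    nG <- length(groups)
    v <- if (1 %in% bad) 1L else if (nG %in% bad) nG else bad[1]
    into <- if (v == 1L) 2L
            else if (v == nG) nG - 1L
            else if (v <= nG / 2) v - 1L else v + 1L
    groups[[into]] <- sort(c(groups[[into]], groups[[v]]))
    groups[[v]] <- NULL
  }
  # phase B: within each merged group, merge sparse categories with the
  # adjacent retained cell.
  obs <- exp <- cells <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    o <- colSums(O[groups[[gi]], , drop = FALSE])
    e <- colSums(E[groups[[gi]], , drop = FALSE])
    cell <- as.list(seq_len(K))
    repeat {
      ev <- vapply(cell, function(cc) sum(e[cc]), numeric(1))
      if (all(ev >= minExpected) || length(cell) == 1L) break
      v <- which.min(ev)
      into <- if (v == 1L) 2L
              else if (v == length(cell)) v - 1L
              else if (ev[v - 1] <= ev[v + 1]) v - 1L else v + 1L
      cell[[into]] <- sort(c(cell[[into]], cell[[v]]))
      cell[[v]] <- NULL
    }
    obs[[gi]] <- vapply(cell, function(cc) sum(o[cc]), numeric(1))
    exp[[gi]] <- vapply(cell, function(cc) sum(e[cc]), numeric(1))
    cells[[gi]] <- cell
  }
  list(groups = groups, cells = cells, observed = obs, expected = exp)
}

#' S-X2 item goodness-of-fit test
#'
#' Compares observed and model-expected item-category frequencies
#' conditional on the rest score (the scale sum excluding the studied
#' item), in the Orlando-Thissen construction generalised to polytomous
#' items. Expected cell proportions are
#' \eqn{E_{ks} \propto \int P_k(\theta) \, P(\mathrm{rest}=s \mid \theta)
#' \, dF(\theta)}; sparse cells are collapsed (adjacent rest-score groups
#' first, then adjacent categories) until every expected count reaches
#' `minExpected`. Degrees of freedom are the independent retained cells
#' (one less than the cell count of each rest-score group) minus the
#' studied item's free parameters, floored at 1.
#'
#' Rows missing the studied item are dropped; rows keep contributing when
#' at least `minRestProp` of the remaining items are observed, in which
#' case the rest score and its conditional distribution use that row's
#' observed items only.
#'
#' @param responses a [ResponseMatrix-class].
#' @param scale the calibrated [ScaleParameters-class] (statistics are
#'   computed after calibration on the same data, without per-item
#'   refitting).
#' @param itemId studied item.
#' @param grid an [AbilityGrid-class].
#' @param minExpected minimum expected cell count before collapsing
#'   (default 1).
#' @param minRestProp minimum fraction of observed rest items for a row to
#'   be retained (default 0.8).
#' @param alpha misfit significance level (default 0.01).
#' @return a [FitStatistic-class].
#' @export
sx2ItemFit <- function(responses, scale, itemId, grid = abilityGrid(),
                       minExpected = 1, minRestProp = 0.8, alpha = 0.01) {
  stopifnot(is(responses, "ResponseMatrix"), is(scale, "ScaleParameters"))
  .checkScaleMatch(responses, scale)
  ids <- itemIds(scale)
  j <- match(itemId, ids)
  if (is.na(j)) stop("no item '", itemId, "' in the scale")
  it <- scale@items[[j]]
  K <- length(it@thresholds) + 1L
  X <- responses@codes
  restObs <- !is.na(X[, -j, drop = FALSE])
  keep <- !is.na(X[, j]) & rowMeans(restObs) >= minRestProp
  if (sum(keep) < 10L)
    stop("insufficient data for S-X2 on item '", itemId, "'")
  X <- X[keep, , drop = FALSE]
  restObs <- restObs[keep, , drop = FALSE]
  restItems <- scale@items[-j]
  w <- grid@weights
  Pk <- .catProbs(it@slope, it@thresholds, grid@points)

  pat <- apply(restObs, 1, paste, collapse = "")
  maxS <- sum(vapply(restItems, function(x) length(x@thresholds), integer(1)))
  O <- E <- matrix(0, maxS + 1L, K)
  for (p in unique(pat)) {
    rows <- which(pat == p)
    sel <- restObs[rows[1], ]
    sc <- rowSums(X[rows, -j, drop = FALSE][, sel, drop = FALSE], na.rm = TRUE)
    sd_ <- .scoreMass(restItems[sel], grid@points)
    den <- as.vector(crossprod(sd_@mass, w))                  # per score
    num <- crossprod(sd_@mass, w * Pk)                        # score x K
    pi_p <- num / pmax(den, .EPS)
    ns <- tabulate(sc + 1L, nbins = ncol(sd_@mass))
    supp <- seq_along(ns)
    O[supp, ] <- O[supp, ] + t(vapply(seq_along(ns), function(s) {
      r <- rows[sc == s - 1L]
      tabulate(X[r, j] + 1L, nbins = K)
    }, numeric(K)))
    E[supp, ] <- E[supp, ] + ns * pi_p
  }
  nonEmpty <- rowSums(E) > 0
  O <- O[nonEmpty, , drop = FALSE]; E <- E[nonEmpty, , drop = FALSE]

  coll <- .collapseTable(O, E, K, minExpected)
  stat <- 0; dfCells <- 0L
  for (gi in seq_along(coll$observed)) {
    o <- coll$observed[[gi]]; e <- coll$expected[[gi]]
    ok <- e > 0
    stat <- stat + sum((o[ok] - e[ok])^2 / e[ok])
    dfCells <- dfCells + length(o) - 1L
  }
  nFree <- 1L + (K - 1L)          # slope + thresholds of the studied item
  df <- max(dfCells - nFree, 1L)
  p <- pchisq(stat, df, lower.tail = FALSE)
  new("FitStatistic", itemId = itemId, statistic = stat, df = as.integer(df),
      pValue = p, misfit = p < alpha,
      collapsedTable = list(observed = coll$observed, expected = coll$expected,
                            scoreGroups = coll$groups, categoryCells = coll$cells))
}

#' Residual correlation screen for local dependence
#'
#' Compares each item pair's observed Pearson correlation with the
#' correlation the fitted model implies under local independence
#' (both moments obtained by quadrature over the trait prior); the residual
#' is their difference. Excess positive residuals indicate locally
#' dependent pairs (similar content or wording). Pairs whose absolute
#' residual reaches `flagThreshold` (default 0.10, just above the 0.09
#' level treated as unproblematic in the LVQOL screening) are reported in
#' the `"flagged"` attribute. Cells with fewer than 3 pairwise-complete
#' persons are `NA`.
#'
#' @param responses a [ResponseMatrix-class].
#' @param scale the calibrated [ScaleParameters-class].
#' @param grid an [AbilityGrid-class].
#' @param flagThreshold absolute residual correlation triggering a flag.
#' @return item x item residual correlation matrix (diagonal 1 by
#'   convention) with a `"flagged"` attribute: data.frame of flagged pairs
#'   and their residual r.
#' @export
residualCorrelations <- function(responses, scale, grid = abilityGrid(),
                                 flagThreshold = 0.10) {
  stopifnot(is(responses, "ResponseMatrix"), is(scale, "ScaleParameters"))
  .checkScaleMatch(responses, scale)
  X <- responses@codes
  w <- grid@weights
  nI <- ncol(X)
  # model-implied moments under local independence
  Emat <- vapply(scale@items,
                 function(i) .expScore(i@slope, i@thresholds, grid@points),
                 numeric(length(grid@points)))                 # Q x I
  E2 <- vapply(scale@items, function(i) {
    P <- .catProbs(i@slope, i@thresholds, grid@points)
    as.vector(P %*% (seq_len(ncol(P)) - 1L)^2)
  }, numeric(length(grid@points)))
  m1 <- as.vector(crossprod(Emat, w))
  v <- as.vector(crossprod(E2, w)) - m1^2
  cv <- crossprod(Emat * sqrt(w)) - tcrossprod(m1)     # E[E_i E_j] - m_i m_j
  rmod <- cv / tcrossprod(sqrt(v))
  diag(rmod) <- 1
  cc <- crossprod(!is.na(X))                           # pairwise-complete n
  robs <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  cors <- robs - rmod
  cors[cc < 3L] <- NA_real_
  diag(cors) <- 1
  dimnames(cors) <- list(colnames(X), colnames(X))
  idx <- which(upper.tri(cors) & !is.na(cors) & abs(cors) >= flagThreshold,
               arr.ind = TRUE)
  flagged <- data.frame(item1 = colnames(X)[idx[, 1]],
                        item2 = colnames(X)[idx[, 2]],
                        r = cors[idx])
  attr(cors, "flagged") <- flagged
  cors
}
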