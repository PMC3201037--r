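# Synthetic response generation with the statistical structure the analysis
# assumes: GRM responses under a normal latent trait, a two-group design
# with injectable uniform/non-uniform DIF and population impact, and MCAR
# item non-response. Defaults mirror the LVQOL study population: n = 296,
# 6 response categories, 4.5% item non-response, 61.8% in the focal group
# (the study's female fraction).

#' Specify a simulation design
#'
#' @param scale generating [ScaleParameters-class] (reference-group
#'   parameters).
#' @param nPersons number of respondents (default 296, the study sample).
#' @param groupFraction fraction of persons in the focal group (default
#'   0.618, the study's female fraction); set 0 for a single-group design.
#' @param focalMean,focalSd focal-population trait distribution (impact);
#'   the reference population is standard normal.
#' @param difEdits list of DIF edits, each
#'   `list(itemId=, kind = "uniform"|"non-uniform", magnitude=)`. A uniform
#'   edit shifts every focal threshold by `magnitude` (or by a per-threshold
#'   vector); a non-uniform edit multiplies the focal slope by `magnitude`.
#' @param missingRate MCAR item non-response probability (default 0.045,
#'   the study's overall 4.5% rate); scalar or per-item vector.
#' @param variable,groupLabels subgroup variable name and the
#'   reference/focal labels used in outputs.
#' @param seed integer RNG seed; identical designs reproduce identical data.
#' @return validated design (list with class `"SimulationDesign"`).
#' @export
simulationDesign <- function(scale, nPersons = 296L, groupFraction = 0.618,
                             focalMean = 0, focalSd = 1, difEdits = list(),
                             missingRate = 0.045, variable = "group",
                             groupLabels = c("reference", "focal"),
                             seed = 1L) {
  stopifnot(is(scale, "ScaleParameters"))
  nPersons <- as.integer(nPersons)
  if (nPersons < 2L) stop("'nPersons' must be >= 2")
  if (groupFraction < 0 || groupFraction > 1) stop("'groupFraction' must be in [0,1]")
  if (!is.finite(focalMean) || !is.finite(focalSd) || focalSd <= 0)
    stop("invalid focal population parameters")
  if (any(missingRate < 0) || any(missingRate > 1)) stop("'missingRate' must be in [0,1]")
  ids <- itemIds(scale)
  for (e in difEdits) {
    if (!all(c("itemId", "kind", "magnitude") %in% names(e)) ||
        !e$itemId %in% ids || !e$kind %in% c("uniform", "non-uniform"))
      stop("each DIF edit needs itemId (in scale), kind ('uniform'/'non-uniform'), magnitude")
    if (e$kind == "non-uniform" && (length(e$magnitude) != 1L || e$magnitude <= 0))
      stop("non-uniform edit magnitude must be a single positive slope factor")
  }
  structure(list(scale = scale, nPersons = nPersons,
                 groupFraction = groupFraction, focalMean = focalMean,
                 focalSd = focalSd, difEdits = difEdits,
                 missingRate = missingRate, variable = variable,
                 groupLabels = groupLabels, seed = as.integer(seed)),
            class = "SimulationDesign")
}

# apply DIF edits to the reference parameters to obtain focal parameters
.applyEdits <- function(scale, difEdits) {
  items <- scale@items
  ids <- itemIds(scale)
  for (e in difEdits) {
    i <- match(e$itemId, ids)
    it <- items[[i]]
    if (e$kind == "uniform") {
      shift <- e$magnitude
      if (!length(shift) %in% c(1L, length(it@thresholds)))
        stop("uniform edit magnitude must be scalar or one value per threshold")
      thr <- sort(it@thresholds + shift)
      items[[i]] <- itemParameters(it@itemId, it@slope, thr)
    } else {
      items[[i]] <- itemParameters(it@itemId, it@slope * e$magnitude, it@thresholds)
    }
  }
  scaleParameters(scale@scaleName, items)
}

#' Simulate graded responses with subgroup structure
#'
#' Draws latent traits from N(0,1) for reference-group persons and from
#' N(focalMean, focalSd^2) for focal-group persons, then draws each item
#' response from the GRM category probabilities at that person's trait —
#' using focal-edited parameters for focal persons — and finally masks
#' entries missing completely at random. The returned truth record retains
#' everything needed for recovery checks.
#'
#' @param design a design from [simulationDesign()].
#' @return list with elements `responses` ([ResponseMatrix-class]),
#'   `groups` (factor, reference level first), `variable`,
#'   and `truth` (list: `theta`, `referenceScale`, `focalScale`,
#'   `difEdits`, `seed`).
#' @examples
#' d <- simulationDesign(lvqolReferenceScales()[["Adjustment"]],
#'                       nPersons = 100, seed = 42)
#' sim <- simulateResponses(d)
#' sim$responses
#' @export
simulateResponses <- function(design) {
  if (!inherits(design, "SimulationDesign"))
    stop("'design' must come from simulationDesign()")
  set.seed(design$seed)
  n <- design$nPersons
  refScale <- design$scale
  focScale <- .applyEdits(refScale, design$difEdits)
  ids <- itemIds(refScale)
  nI <- length(ids)
  K <- unique(nCategories(refScale))
  if (length(K) != 1L)
    stop("all items of the generating scale must share one category count")

  focal <- runif(n) < design$groupFraction
  theta <- ifelse(focal, rnorm(n, design$focalMean, design$focalSd), rnorm(n))

  X <- matrix(NA_integer_, n, nI, dimnames = list(paste0("p", seq_len(n)), ids))
  for (i in seq_len(nI)) {
    u <- runif(n)
    for (g in c(FALSE, TRUE)) {
      rows <- which(focal == g)
      if (!length(rows)) next
      it <- (if (g) focScale else refScale)@items[[i]]
      cum <- .cumProbs(it@slope, it@thresholds, theta[rows])  # rows x m
      X[rows, i] <- as.integer(rowSums(cum > u[rows]))
    }
  }
  rate <- rep(design$missingRate, length.out = nI)
  for (i in seq_len(nI))
    X[runif(n) < rate[i], i] <- NA_integer_

  groups <- factor(ifelse(focal, design$groupLabels[2], design$groupLabels[1]),
                   levels = design$groupLabels)
  list(responses = responseMatrix(X, K), groups = groups,
       variable = design$variable,
       truth = list(theta = theta, referenceScale = refScale,
                    focalScale = focScale, difEdits = design$difEdits,
                    seed = design$seed))
}
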