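#' @import methods
#' @importFrom stats dnorm pchisq plogis optim var cor qlogis runif rnorm rbinom setNames
NULL

#' Item parameters of the graded response model
#'
#' One polytomous item under Samejima's graded response model (GRM): a single
#' discrimination (slope) \eqn{\alpha > 0} and \eqn{m} ordered thresholds
#' \eqn{\beta_1 \le \dots \le \beta_m} on the latent-trait scale, for an item
#' with \eqn{m + 1} ordered response categories coded \code{0..m}.
#'
#' @slot itemId single character label, unique within a scale.
#' @slot slope positive discrimination parameter (logit units per trait unit).
#' @slot thresholds numeric vector of ordered category thresholds
#'   (latent-trait units); length is one less than the number of categories.
#'
#' @seealso [itemParameters()], [categoryProbs()], [expectedItemScore()]
#' @export
setClass("ItemParameters",
  representation(itemId = "character", slope = "numeric", thresholds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@itemId) != 1L || is.na(object@itemId) || !nzchar(object@itemId))
      msg <- c(msg, "'itemId' must be a single non-empty string")
    if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope <= 0)
      msg <- c(msg, "'slope' must be a single finite positive number")
    if (length(object@thresholds) < 1L || anyNA(object@thresholds) ||
        any(!is.finite(object@thresholds)))
      msg <- c(msg, "'thresholds' must be a non-empty finite numeric vector")
    else if (is.unsorted(object@thresholds))
      msg <- c(msg, "'thresholds' must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' Construct GRM item parameters
#'
#' @param itemId item label.
#' @param slope positive discrimination parameter.
#' @param thresholds ordered numeric thresholds; `length(thresholds) + 1`
#'   response categories are implied.
#' @return an [ItemParameters-class] object.
#' @examples
#' itemParameters("item24", slope = 1.83,
#'                thresholds = c(-1.22, -0.92, -0.38, -0.15, 1.13))
#' @export
itemParameters <- function(itemId, slope, thresholds) {
  new("ItemParameters", itemId = as.character(itemId), slope = as.numeric(slope),
      thresholds = as.numeric(thresholds))
}

#' A calibrated scale (one questionnaire dimension)
#'
#' An ordered collection of [ItemParameters-class] forming one unidimensional
#' scale, e.g. one of the four LVQOL dimensions.
#'
#' @slot scaleName dimension label.
#' @slot items list of `ItemParameters` with unique item ids.
#' @export
setClass("ScaleParameters",
  representation(scaleName = "character", items = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@scaleName) != 1L)
      msg <- c(msg, "'scaleName' must be a single string")
    if (length(object@items) == 0L)
      msg <- c(msg, "a scale must contain at least one item")
    if (!all(vapply(object@items, is, logical(1), "ItemParameters")))
      msg <- c(msg, "all elements of 'items' must be ItemParameters")
    else {
      ids <- vapply(object@items, function(x) x@itemId, character(1))
      if (anyDuplicated(ids)) msg <- c(msg, "item ids must be unique")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a scale from item parameters
#'
#' @param scaleName dimension label.
#' @param items list of [ItemParameters-class].
#' @return a [ScaleParameters-class] object.
#' @export
scaleParameters <- function(scaleName, items) {
  if (is(items, "ItemParameters")) items <- list(items)
  new("ScaleParameters", scaleName = as.character(scaleName), items = items)
}

#' Quadrature grid over the latent trait
#'
#' Discrete representation of the latent-trait prior used for marginal
#' maximum likelihood and EAP scoring: strictly increasing points with
#' positive weights summing to one.
#'
#' @slot points strictly increasing trait values.
#' @slot weights positive prior masses, normalised to sum to 1.
#' @export
setClass("AbilityGrid",
  representation(points = "numeric", weights = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@points) < 2L || is.unsorted(object@points, strictly = TRUE))
      msg <- c(msg, "'points' must be strictly increasing with length >= 2")
    if (length(object@weights) != length(object@points) ||
        any(object@weights <= 0))
      msg <- c(msg, "'weights' must be positive and match 'points'")
    else if (abs(sum(object@weights) - 1) > 1e-10)
      msg <- c(msg, "'weights' must sum to 1 (tolerance 1e-10)")
    if (length(msg)) msg else TRUE
  })

#' Construct a normal-prior quadrature grid
#'
#' Equally spaced points with standard-normal (or general normal) ordinates
#' renormalised to unit mass — the fixed prior of marginal estimation.
#'
#' @param from,to grid range (default \[-6, 6\]).
#' @param nPoints number of points (default 61).
#' @param mean,sd prior mean and standard deviation (default standard normal).
#' @return an [AbilityGrid-class].
#' @export
abilityGrid <- function(from = -6, to = 6, nPoints = 61L, mean = 0, sd = 1) {
  p <- seq(from, to, length.out = nPoints)
  w <- dnorm(p, mean, sd)
  new("AbilityGrid", points = p, weights = w / sum(w))
}

#' Ordinal response matrix
#'
#' Persons by items matrix of integer Likert codes `0..nCategories-1`;
#' missing responses are `NA` (explicit, never an in-range code).
#'
#' @slot codes integer matrix with `NA` for missing; dimnames give person and
#'   item labels.
#' @slot nCategories number of response categories shared by all items
#'   (6 for the LVQOL: 0 "No problem" .. 5 "Not able because of vision").
#' @export
setClass("ResponseMatrix",
  representation(codes = "matrix", nCategories = "integer"),
  validity = function(object) {
    msg <- character()
    k <- object@nCategories
    if (length(k) != 1L || is.na(k) || k < 2L)
      msg <- c(msg, "'nCategories' must be a single integer >= 2")
    x <- object@codes
    if (!is.numeric(x))
      msg <- c(msg, "'codes' must be a numeric/integer matrix")
    else {
      obs <- x[!is.na(x)]
      if (length(obs) && (any(obs != round(obs)) || any(obs < 0) || any(obs > k - 1)))
        msg <- c(msg, sprintf("observed codes must be integers in 0..%d", k - 1))
    }
    if (is.null(rownames(x)) || is.null(colnames(x)))
      msg <- c(msg, "'codes' must carry person rownames and item colnames")
    if (length(msg)) msg else TRUE
  })

#' Construct a response matrix
#'
#' @param codes numeric matrix of codes in `0..nCategories-1`, `NA` = missing.
#'   Default dimnames (`p1..`, column `item1..`) are added when absent.
#' @param nCategories number of response categories (default 6).
#' @return a [ResponseMatrix-class].
#' @export
responseMatrix <- function(codes, nCategories = 6L) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) rownames(codes) <- paste0("p", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("item", seq_len(ncol(codes)))
  storage.mode(codes) <- "integer"
  new("ResponseMatrix", codes = codes, nCategories = as.integer(nCategories))
}

#' Result of a marginal maximum likelihood calibration
#'
#' @slot scale fitted [ScaleParameters-class].
#' @slot standardErrors named numeric vector of parameter standard errors
#'   (`NA` when not requested).
#' @slot logLik maximised marginal log-likelihood.
#' @slot nIterations EM iterations used.
#' @slot converged logical convergence flag.
#' @slot grid the [AbilityGrid-class] used.
#' @slot collapseMaps named list of category-collapse mappings applied to
#'   items with unobserved intermediate categories (empty when none).
#' @export
setClass("CalibrationResult",
  representation(scale = "ScaleParameters", standardErrors = "numeric",
                 logLik = "numeric", nIterations = "integer",
                 converged = "logical", grid = "AbilityGrid",
                 collapseMaps = "list"),
  validity = function(object) {
    if (!is.finite(object@logLik)) "log-likelihood must be finite" else TRUE
  })

#' Test information curve
#'
#' Per-item and total Fisher information over a trait grid, optionally
#' including the unit information contributed by the standard-normal prior,
#' with the measurement standard error \eqn{SE(\theta) = 1/\sqrt{I(\theta)}}.
#'
#' @slot theta evaluation grid.
#' @slot itemInformation matrix (theta by item) of item informations.
#' @slot totalInformation per-theta totals (+1 when `priorIncluded`).
#' @slot priorIncluded logical.
#' @slot standardError `1/sqrt(totalInformation)`.
#' @export
setClass("InformationCurve",
  representation(theta = "numeric", itemInformation = "matrix",
                 totalInformation = "numeric", priorIncluded = "logical",
                 standardError = "numeric"),
  validity = function(object) {
    msg <- character()
    tot <- rowSums(object@itemInformation) + as.numeric(object@priorIncluded)
    if (max(abs(tot - object@totalInformation)) > 1e-9)
      msg <- c(msg, "total information must equal item sum (+ prior) within 1e-9")
    if (max(abs(object@standardError - 1 / sqrt(object@totalInformation))) > 1e-9)
      msg <- c(msg, "standard error must equal 1/sqrt(total) within 1e-9")
    if (length(msg)) msg else TRUE
  })

#' Summed-score distribution given the latent trait
#'
#' Conditional distribution of the scale sum score over a trait grid,
#' computed by the Lord-Wingersky recursion generalised to graded items;
#' the building block of the S-X2 expected tables.
#'
#' @slot support integer scores `0..max`.
#' @slot mass matrix (grid point by score); rows sum to 1.
#' @slot theta the grid points.
#' @export
setClass("ScoreDistribution",
  representation(support = "integer", mass = "matrix", theta = "numeric"),
  validity = function(object) {
    if (max(abs(rowSums(object@mass) - 1)) > 1e-10)
      "each conditional score distribution must sum to 1 within 1e-10" else TRUE
  })

#' S-X2-type item fit statistic
#'
#' @slot itemId studied item.
#' @slot statistic S-X2 value (sum of (O-E)^2/E over retained cells).
#' @slot df chi-square degrees of freedom.
#' @slot pValue upper-tail p.
#' @slot misfit `TRUE` iff `pValue < alpha` (default alpha 0.01).
#' @slot collapsedTable list with observed and expected matrices after
#'   collapsing, plus the rest-score group boundaries.
#' @export
setClass("FitStatistic",
  representation(itemId = "character", statistic = "numeric", df = "integer",
                 pValue = "numeric", misfit = "logical", collapsedTable = "list"),
  validity = function(object) {
    msg <- character()
    if (object@statistic < 0) msg <- c(msg, "statistic must be nonnegative")
    if (object@df < 1L) msg <- c(msg, "df must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Result of a hierarchical likelihood-ratio DIF test
#'
#' Two-group IRT likelihood-ratio DIF analysis of one item: the 1-df slope
#' (non-uniform DIF) G^2 test, the 5-df threshold (uniform DIF) G^2 test —
#' performed only when the slope test is not significant, following the
#' hierarchical scheme — and the expected-score DIF magnitude.
#'
#' @slot itemId studied item.
#' @slot variable subgroup variable name.
#' @slot groupLabels reference and focal labels (in that order).
#' @slot g2Slope,dfSlope,pSlope slope-equality likelihood-ratio test.
#' @slot g2Thresholds,dfThresholds,pThresholds threshold-equality test
#'   (`NA` when the slope test was significant).
#' @slot classification one of `"none"`, `"uniform"`, `"non-uniform"`.
#' @slot esTheta,esCurve expected-score difference curve (reference minus
#'   focal) on the scan grid.
#' @slot esDeltaMax signed maximum-magnitude expected-score difference.
#' @slot thetaAtMax its location (smallest such theta on ties).
#' @slot groupParameters list with `reference` and `focal` [ItemParameters-class]
#'   from the model used for the expected-score curve.
#' @slot focalMean,focalSd estimated focal-population parameters
#'   (reference fixed at N(0,1)).
#' @slot logLik named vector of maximised log-likelihoods of the fitted
#'   models (`free`, `slopeEqual`, `allEqual`).
#' @slot alpha significance level of the hierarchical scheme (0.01 in the
#'   LVQOL analysis, as multiple-testing control).
#' @export
setClass("DIFResult",
  representation(itemId = "character", variable = "character",
                 groupLabels = "character",
                 g2Slope = "numeric", dfSlope = "integer", pSlope = "numeric",
                 g2Thresholds = "numeric", dfThresholds = "integer",
                 pThresholds = "numeric", classification = "character",
                 esTheta = "numeric", esCurve = "numeric",
                 esDeltaMax = "numeric", thetaAtMax = "numeric",
                 groupParameters = "list", focalMean = "numeric",
                 focalSd = "numeric", logLik = "numeric", alpha = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@classification %in% c("none", "uniform", "non-uniform"))
      msg <- c(msg, "classification must be none/uniform/non-uniform")
    hier <- is.na(object@g2Thresholds) == (object@pSlope < object@alpha)
    if (!isTRUE(hier))
      msg <- c(msg, "threshold test must be present iff slope test non-significant")
    if (length(msg)) msg else TRUE
  })
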