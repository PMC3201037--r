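#' Item identifiers
#'
#' @param x an [ItemParameters-class], [ScaleParameters-class],
#'   [CalibrationResult-class] or [ResponseMatrix-class].
#' @return character vector of item ids.
#' @name itemIds
NULL

#' Discrimination parameters
#'
#' @param x an [ItemParameters-class] or [ScaleParameters-class].
#' @return numeric vector of slopes (named by item for scales).
#' @name slopes
NULL

#' Threshold parameters
#'
#' @param x an [ItemParameters-class] or [ScaleParameters-class].
#' @return numeric vector of thresholds, or a named list for a scale.
#' @name thresholds
NULL

#' Number of response categories
#'
#' @param x an [ItemParameters-class], [ScaleParameters-class] or
#'   [ResponseMatrix-class].
#' @return integer.
#' @name nCategories
NULL

#' Raw response codes
#'
#' @param x a [ResponseMatrix-class].
#' @return integer matrix with `NA` for missing responses.
#' @name responseCodes
NULL

#' @rdname itemIds
setMethod("itemIds", "ItemParameters", function(x) x@itemId)
#' @rdname itemIds
setMethod("itemIds", "ScaleParameters",
  function(x) unname(vapply(x@items, function(i) i@itemId, character(1))))
#' @rdname itemIds
setMethod("itemIds", "CalibrationResult", function(x) itemIds(x@scale))
#' @rdname itemIds
setMethod("itemIds", "ResponseMatrix", function(x) colnames(x@codes))

#' @rdname slopes
setMethod("slopes", "ItemParameters", function(x) x@slope)
#' @rdname slopes
setMethod("slopes", "ScaleParameters",
  function(x) setNames(vapply(x@items, function(i) i@slope, numeric(1)), itemIds(x)))

#' @rdname thresholds
setMethod("thresholds", "ItemParameters", function(x) x@thresholds)
#' @rdname thresholds
setMethod("thresholds", "ScaleParameters",
  function(x) setNames(lapply(x@items, function(i) i@thresholds), itemIds(x)))

#' @rdname nCategories
setMethod("nCategories", "ItemParameters", function(x) length(x@thresholds) + 1L)
#' @rdname nCategories
setMethod("nCategories", "ScaleParameters",
  function(x) vapply(x@items, nCategories, integer(1)))
#' @rdname nCategories
setMethod("nCategories", "ResponseMatrix", function(x) x@nCategories)

#' @rdname responseCodes
setMethod("responseCodes", "ResponseMatrix", function(x) x@codes)

#' Extract items from a scale
#'
#' @param x a [ScaleParameters-class].
#' @param id item id (single character) or index.
#' @return an [ItemParameters-class].
#' @export
scaleItem <- function(x, id) {
  stopifnot(is(x, "ScaleParameters"))
  if (is.character(id)) {
    hit <- match(id, itemIds(x))
    if (is.na(hit)) stop("no item '", id, "' in scale '", x@scaleName, "'")
    id <- hit
  }
  x@items[[id]]
}

#' Scale of a calibration result
#' @param x a [CalibrationResult-class].
#' @return the fitted [ScaleParameters-class].
#' @export
calibratedScale <- function(x) {
  stopifnot(is(x, "CalibrationResult"))
  x@scale
}

#' @export
#' @describeIn calibratedScale maximised marginal log-likelihood.
calibrationLogLik <- function(x) {
  stopifnot(is(x, "CalibrationResult"))
  x@logLik
}

#' @export
#' @describeIn calibratedScale convergence flag.
calibrationConverged <- function(x) {
  stopifnot(is(x, "CalibrationResult"))
  x@converged
}

#' DIF classification of a test result
#' @param x a [DIFResult-class].
#' @return `"none"`, `"uniform"` or `"non-uniform"`.
#' @export
difClassification <- function(x) {
  stopifnot(is(x, "DIFResult"))
  x@classification
}

#' @export
#' @describeIn difClassification signed maximum expected-score difference.
esDeltaMax <- function(x) {
  stopifnot(is(x, "DIFResult"))
  x@esDeltaMax
}

setMethod("show", "ItemParameters", function(object) {
  cat(sprintf("GRM item '%s': slope %.3f, %d categories\n  thresholds: %s\n",
      object@itemId, object@slope, length(object@thresholds) + 1L,
      paste(sprintf("%.3f", object@thresholds), collapse = ", ")))
})

setMethod("show", "ScaleParameters", function(object) {
  cat(sprintf("GRM scale '%s' (%d items)\n", object@scaleName, length(object@items)))
  df <- data.frame(slope = round(slopes(object), 3))
  b <- t(vapply(object@items, function(i) i@thresholds,
                numeric(length(object@items[[1]]@thresholds))))
  colnames(b) <- paste0("b", seq_len(ncol(b)))
  print(cbind(df, round(b, 3)))
})

setMethod("show", "ResponseMatrix", function(object) {
  miss <- mean(is.na(object@codes))
  cat(sprintf("ResponseMatrix: %d persons x %d items, %d categories, %.1f%% missing\n",
      nrow(object@codes), ncol(object@codes), object@nCategories, 100 * miss))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("GRM calibration of '%s': logLik %.3f, %d EM iterations (%s)\n",
      object@scale@scaleName, object@logLik, object@nIterations,
      if (object@converged) "converged" else "NOT converged"))
  show(object@scale)
})

setMethod("show", "InformationCurve", function(object) {
  i <- which.max(object@totalInformation)
  cat(sprintf(
    "InformationCurve over [%.1f, %.1f] (%d items%s): max %.2f at theta = %.2f (SE %.2f)\n",
    min(object@theta), max(object@theta), ncol(object@itemInformation),
    if (object@priorIncluded) ", prior included" else "",
    object@totalInformation[i], object@theta[i], object@standardError[i]))
})

setMethod("show", "FitStatistic", function(object) {
  cat(sprintf("S-X2 item fit '%s': X2 = %.2f, df = %d, p = %.4f%s\n",
      object@itemId, object@statistic, object@df, object@pValue,
      if (object@misfit) " [misfit]" else ""))
})

setMethod("show", "DIFResult", function(object) {
  cat(sprintf("DIF test: item '%s' on '%s' (%s vs %s)\n", object@itemId,
      object@variable, object@groupLabels[1], object@groupLabels[2]))
  cat(sprintf("  slope G2(%d) = %.2f, p = %.4f\n", object@dfSlope,
      object@g2Slope, object@pSlope))
  if (!is.na(object@g2Thresholds))
    cat(sprintf("  threshold G2(%d) = %.2f, p = %.4f\n", object@dfThresholds,
        object@g2Thresholds, object@pThresholds))
  cat(sprintf("  classification: %s; ES_dmax = %.2f at theta = %.2f\n",
      object@classification, object@esDeltaMax, object@thetaAtMax))
})
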