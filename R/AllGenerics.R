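#' @rdname itemIds
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname slopes
#' @export
setGeneric("slopes", function(x) standardGeneric("slopes"))

#' @rdname thresholds
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname nCategories
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' Category response probabilities of a graded item
#'
#' Probability of each response category `0..m` at trait value(s) `theta`,
#' obtained as adjacent differences of the cumulative ("category or higher")
#' probabilities: \eqn{P_j = P^*_j - P^*_{j+1}} with \eqn{P^*_0 = 1} and
#' \eqn{P^*_{m+1} = 0}.
#'
#' @param item an [ItemParameters-class].
#' @param theta numeric vector of trait values.
#' @return matrix `length(theta)` by `nCategories`; rows sum to 1.
#' @export
setGeneric("categoryProbs", function(item, theta) standardGeneric("categoryProbs"))

#' Expected item score
#'
#' \eqn{E[X \mid \theta] = \sum_j j P_j(\theta) = \sum_{j \ge 1} P^*_j(\theta)},
#' on the observed 0..m category scale; the quantity whose between-group
#' difference measures DIF magnitude.
#'
#' @param item an [ItemParameters-class].
#' @param theta numeric vector of trait values.
#' @return numeric vector in `[0, m]`, strictly increasing in `theta`.
#' @export
setGeneric("expectedItemScore", function(item, theta) standardGeneric("expectedItemScore"))

#' Item Fisher information
#'
#' Samejima's graded-model closed form
#' \eqn{I_i(\theta) = \alpha^2 \sum_j (w_j - w_{j+1})^2 / P_j} with
#' \eqn{w_j = P^*_j (1 - P^*_j)} over the category boundaries.
#'
#' @param item an [ItemParameters-class].
#' @param theta numeric vector of trait values.
#' @return nonnegative numeric vector.
#' @export
setGeneric("itemInformation", function(item, theta) standardGeneric("itemInformation"))

#' Test information curve of a scale
#'
#' Sums item informations over a trait grid and, when `priorIncluded`, adds
#' the unit information of the standard-normal prior — the convention of
#' marginal-estimation software, under which the LVQOL information maxima
#' (25.0, 18.9, 8.4, 8.2) are reported. The standard error of measurement is
#' \eqn{1/\sqrt{I(\theta)}}.
#'
#' @param scale a [ScaleParameters-class].
#' @param theta strictly increasing grid (default `seq(-4, 4, by = 0.1)`).
#' @param priorIncluded logical (default `TRUE`).
#' @return an [InformationCurve-class].
#' @export
setGeneric("scaleInformation",
  function(scale, theta = seq(-4, 4, by = 0.1), priorIncluded = TRUE)
    standardGeneric("scaleInformation"))

#' @rdname responseCodes
#' @export
setGeneric("responseCodes", function(x) standardGeneric("responseCodes"))
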