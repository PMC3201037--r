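# Core graded-response-model mathematics. Internal helpers operate on plain
# (slope, thresholds) vectors for speed; exported S4 methods wrap them.

.EPS <- 1e-300  # probability floor for logs only; never fed back into sums

# cumulative P*_j(theta) for j = 1..m, theta vectorised: T x m matrix
.cumProbs <- function(slope, thresholds, theta) {
  plogis(slope * outer(theta, thresholds, "-"))
}

# category probabilities: T x (m+1), rows telescoping to exactly 1
.catProbs <- function(slope, thresholds, theta) {
  ps <- cbind(1, .cumProbs(slope, thresholds, theta), 0)
  m1 <- length(thresholds) + 1L
  ps[, 1:m1, drop = FALSE] - ps[, 2:(m1 + 1L), drop = FALSE]
}

.expScore <- function(slope, thresholds, theta) {
  rowSums(.cumProbs(slope, thresholds, theta))
}

# Samejima graded-model information, boundary-weight form
.itemInfo <- function(slope, thresholds, theta) {
  ps <- cbind(1, .cumProbs(slope, thresholds, theta), 0)
  w <- ps * (1 - ps)                       # w = P*(1 - P*); 0 at both ends
  m1 <- length(thresholds) + 1L
  p <- ps[, 1:m1, drop = FALSE] - ps[, 2:(m1 + 1L), drop = FALSE]
  dw <- w[, 1:m1, drop = FALSE] - w[, 2:(m1 + 1L), drop = FALSE]
  ok <- p > 0
  slope^2 * rowSums(ifelse(ok, dw^2 / pmax(p, .EPS), 0))
}

#' Cumulative category probability of the graded response model
#'
#' Probability of responding in category `j` or higher,
#' \eqn{P^*(\theta) = \mathrm{logistic}(\alpha(\theta - \beta))}; strictly
#' increasing in `theta`. The boundary conventions \eqn{P^*_0 = 1} and
#' \eqn{P^*_{m+1} = 0} are applied by callers.
#'
#' @param slope positive discrimination \eqn{\alpha}.
#' @param threshold threshold \eqn{\beta} (latent-trait units).
#' @param theta trait value(s).
#' @return probabilities in (0, 1), vectorised over `theta`.
#' @examples
#' cumulativeProb(2, 0.5, 0.5)            # theta at the threshold: 0.5
#' cumulativeProb(1.83, -1.22, -1)        # 0.5993
#' @export
cumulativeProb <- function(slope, threshold, theta) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0)
    stop("'slope' must be a single finite positive number")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric")
  plogis(slope * (theta - threshold))
}

#' @rdname categoryProbs
setMethod("categoryProbs", "ItemParameters", function(item, theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  p <- .catProbs(item@slope, item@thresholds, theta)
  dimnames(p) <- list(NULL, paste0("cat", 0:(ncol(p) - 1L)))
  p
})

#' @rdname expectedItemScore
setMethod("expectedItemScore", "ItemParameters", function(item, theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  .expScore(item@slope, item@thresholds, theta)
})

#' @rdname itemInformation
setMethod("itemInformation", "ItemParameters", function(item, theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  .itemInfo(item@slope, item@thresholds, theta)
})

#' @rdname scaleInformation
setMethod("scaleInformation", "ScaleParameters",
  function(scale, theta = seq(-4, 4, by = 0.1), priorIncluded = TRUE) {
    if (length(theta) < 1L) stop("empty theta grid")
    if (is.unsorted(theta, strictly = TRUE)) stop("'theta' must be strictly increasing")
    info <- vapply(scale@items, function(i) .itemInfo(i@slope, i@thresholds, theta),
                   numeric(length(theta)))
    info <- matrix(info, nrow = length(theta),
                   dimnames = list(NULL, itemIds(scale)))
    tot <- rowSums(info) + as.numeric(priorIncluded)
    new("InformationCurve", theta = theta, itemInformation = info,
        totalInformation = tot, priorIncluded = isTRUE(priorIncluded),
        standardError = 1 / sqrt(tot))
  })

#' Information curve as a data frame
#'
#' @param curve an [InformationCurve-class].
#' @return data.frame with `theta`, one column per item, `total` and `se` —
#'   the CSV export layout.
#' @export
informationTable <- function(curve) {
  stopifnot(is(curve, "InformationCurve"))
  out <- data.frame(theta = curve@theta, curve@itemInformation,
                    total = curve@totalInformation, se = curve@standardError,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
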