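# Published LVQOL graded-response parameter tables, transcribed from the
# re-evaluation study: the re-calibrated 21-item instrument (four
# dimensions) and the two-group parameter rows of the items that showed DIF.

.lvqolRecalibrated <- list(
  "Basic aspects" = list(
    item6  = list("Seeing moving objects",      2.06, c(-1.21, -0.66,  0.13,  0.66, 2.55)),
    item7  = list("Eyes getting tired",         2.61, c(-1.25, -0.96, -0.29,  0.25, 2.10)),
    item8  = list("Seeing the television",      2.18, c(-1.69, -1.18, -0.34,  0.21, 1.98)),
    item9  = list("Glare (dazzled by lights)",  1.81, c(-2.17, -1.80, -1.20, -0.51, 1.76)),
    item10 = list("Getting right amount light", 2.12, c(-1.83, -1.26, -0.37,  0.22, 2.32))),
  "Mobility" = list(
    item2  = list("Night vision inside house",  1.66, c(-1.42, -0.88,  0.32,  0.85, 3.16)),
    item3  = list("Seeing steps or curbs",      3.56, c(-1.04, -0.68, -0.09,  0.17, 1.55)),
    item4  = list("Depth/distance perception",  2.41, c(-0.80, -0.45,  0.09,  0.51, 1.98)),
    item15 = list("Getting around outdoors",    5.26, c(-1.07, -0.75, -0.14,  0.22, 1.72)),
    item16 = list("Crossing a road with traffic", 3.35, c(-1.11, -0.69, -0.25, 0.12, 1.52))),
  "Adjustment" = list(
    item11 = list("Understand eye condition",   1.26, c(-0.94, -0.47,  0.22,  0.68, 3.48)),
    item12 = list("Unhappy situation in life",  3.23, c(-0.63, -0.37,  0.51,  0.93, 3.22)),
    item13 = list("Frustration with doing tasks", 3.41, c(-1.06, -0.69, 0.02,  0.38, 2.44)),
    item14 = list("Visiting friends and family", 1.37, c(-0.44, -0.13,  0.52,  0.89, 2.99))),
  "Reading and fine work" = list(
    item17 = list("Reading large print",        2.14, c(-0.14,  0.19,  0.85,  1.17, 2.10)),
    item18 = list("Reading newspaper/books",    3.98, c(-1.42, -1.06, -0.61, -0.26, 0.92)),
    item19 = list("Reading labels",             3.50, c(-1.79, -1.44, -0.94, -0.54, 0.79)),
    item20 = list("Reading letters and mail",   5.02, c(-1.28, -0.93, -0.36,  0.02, 0.98)),
    item21 = list("Finding out the time",       1.91, c(-0.50, -0.16,  0.59,  1.13, 2.27)),
    item22 = list("Writing",                    3.55, c(-1.04, -0.71, -0.17,  0.17, 1.06)),
    item23 = list("Reading own handwriting",    3.17, c(-0.81, -0.41,  0.11,  0.51, 1.31))))

#' Re-calibrated LVQOL reference scales
#'
#' The published item parameters of the 21-item Low Vision Quality Of Life
#' questionnaire after removal of the two DIF items, grouped into its four
#' dimensions ("Basic aspects", "Mobility", "Adjustment", "Reading and fine
#' work"). Items have 6 response categories (codes 0-5). Item content labels
#' are attached as the `names()` of each scale's item list.
#'
#' @return named list of four [ScaleParameters-class] objects.
#' @examples
#' scales <- lvqolReferenceScales()
#' slopes(scales[["Reading and fine work"]])
#' @export
lvqolReferenceScales <- function() {
  out <- lapply(names(.lvqolRecalibrated), function(dim) {
    rows <- .lvqolRecalibrated[[dim]]
    items <- lapply(names(rows), function(id)
      itemParameters(id, rows[[id]][[2]], rows[[id]][[3]]))
    names(items) <- vapply(rows, `[[`, character(1), 1)
    scaleParameters(dim, items)
  })
  names(out) <- names(.lvqolRecalibrated)
  out
}

.lvqolDIFRows <- list(
  list(item = "item7", content = "Eyes getting tired", dimension = "Basic aspects",
       variable = "visualAcuity", groups = c("Low vision", "Moderate vision loss"),
       slope = c(2.50, 2.50),
       b = list(c(-0.93, -0.65, -0.10, 0.32, 2.13), c(-1.37, -1.23, -0.54, 0.10, 1.86)),
       g2 = 15.7, df = 5L, p = 0.008, esDeltaMax = -0.80, thetaAtMax = -0.80),
  list(item = "item3", content = "Seeing steps or curbs", dimension = "Mobility",
       variable = "visualAcuity", groups = c("Low vision", "Moderate vision loss"),
       slope = c(2.38, 5.76),
       b = list(c(-0.97, -0.61, -0.01, 0.21, 1.56), c(-0.96, -0.71, -0.26, -0.02, 1.68)),
       g2 = 14.2, df = 1L, p = 0.001, esDeltaMax = -0.74, thetaAtMax = 0.20),
  list(item = "item1", content = "Vision in general", dimension = "Adjustment",
       variable = "administration", groups = c("Self", "Assisted"),
       slope = c(1.99, 1.99),
       b = list(c(-1.98, -1.44, -0.14, 0.38, 2.33), c(-2.47, -2.30, -0.56, -0.09, 2.33)),
       g2 = 19.4, df = 5L, p = 0.002, esDeltaMax = -0.70, thetaAtMax = -2.00),
  list(item = "item1", content = "Vision in general", dimension = "Adjustment",
       variable = "gender", groups = c("Male", "Female"),
       slope = c(2.08, 2.08),
       b = list(c(-2.05, -1.44, 0.04, 0.40, 1.95), c(-1.83, -1.57, -0.27, 0.24, 3.37)),
       g2 = 17.9, df = 5L, p = 0.003, esDeltaMax = 0.62, thetaAtMax = 2.60),
  list(item = "item12", content = "Unhappy situation in life", dimension = "Adjustment",
       variable = "gender", groups = c("Male", "Female"),
       slope = c(3.27, 3.27),
       b = list(c(-0.74, -0.31, 0.56, 1.03, 3.06), c(-0.39, -0.27, 0.51, 0.88, 7.57)),
       g2 = 15.4, df = 5L, p = 0.009, esDeltaMax = 1.00, thetaAtMax = 5.40),
  list(item = "item19", content = "Reading labels", dimension = "Reading and fine work",
       variable = "eyeCondition", groups = c("AMD", "Other"),
       slope = c(3.77, 3.77),
       b = list(c(-1.34, -1.21, -0.94, -0.46, 0.68), c(-1.48, -1.16, -0.63, -0.51, 0.68)),
       g2 = 17.8, df = 5L, p = 0.003, esDeltaMax = 0.24, thetaAtMax = -0.80),
  list(item = "item24", content = "Using tools", dimension = "Reading and fine work",
       variable = "gender", groups = c("Male", "Female"),
       slope = c(1.83, 1.83),
       b = list(c(-1.22, -0.92, -0.38, -0.15, 1.13), c(-1.80, -1.58, -1.39, -0.94, 1.05)),
       g2 = 35.2, df = 5L, p = 0.001, esDeltaMax = -1.22, thetaAtMax = -1.00))

#' Published two-group parameters of the LVQOL DIF items
#'
#' The seven two-group parameter rows reported for the LVQOL items that
#' showed significant DIF, with the published likelihood-ratio statistics
#' and expected-score DIF magnitudes. Each entry carries both groups'
#' [ItemParameters-class] (first-listed group is the reference of the sign
#' convention: reference minus focal).
#'
#' @return list of entries with fields `item`, `content`, `dimension`,
#'   `variable`, `groups`, `reference`/`focal` (`ItemParameters`), `g2`,
#'   `df`, `p`, `esDeltaMax`, `thetaAtMax`.
#' @examples
#' row <- lvqolDIFTable()[[7]]   # item 24, male vs female
#' expectedScoreDIF(row$reference, row$focal)$esDeltaMax
#' @export
lvqolDIFTable <- function() {
  lapply(.lvqolDIFRows, function(r) {
    r$reference <- itemParameters(r$item, r$slope[1], r$b[[1]])
    r$focal <- itemParameters(r$item, r$slope[2], r$b[[2]])
    r
  })
}
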