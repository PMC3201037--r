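# End-to-end re-evaluation workflow: per-dimension calibration, S-X2 item
# fit, DIF testing on every configured subgroup variable, item removal,
# re-calibration, post-removal DIF re-testing, and information/reliability
# reporting.

#' Run the full IRT re-evaluation pipeline
#'
#' Per dimension (dimensions are always calibrated independently):
#' calibrate by marginal maximum likelihood; test every item's S-X2 fit;
#' run the hierarchical likelihood-ratio DIF test for every item x subgroup
#' variable; apply the removal rule; re-calibrate without removed items;
#' re-test the remaining previously-flagged items (post-removal DIF is
#' restricted to dimensions that lost an item); and report the test
#' information curve and subject separation of the final calibration.
#' Estimation failure in one dimension is recorded without aborting the
#' others.
#'
#' @param responses a [ResponseMatrix-class] holding all items.
#' @param groups data.frame of two-level factors (persons in the row order
#'   of `responses`; one column per subgroup variable). First factor level
#'   = reference group.
#' @param dimensions named list mapping dimension name to item-id vector;
#'   every item used must belong to exactly one dimension.
#' @param difVariables variables to test (default: all columns of
#'   `groups`).
#' @param grid quadrature [AbilityGrid-class].
#' @param infoTheta information-curve grid (default `seq(-4, 4, 0.1)`).
#' @param esGrid expected-score scan grid (default `seq(-8, 8, 0.01)`).
#' @param alphaDif,alphaFit significance levels (defaults 0.01).
#' @param esThreshold,minVariables,extentEs,extentMass removal-rule
#'   parameters, see [removalDecision()].
#' @param priorIncluded include the unit prior term in information curves.
#' @param standardErrors compute calibration standard errors.
#' @param emTol,emParTol,mstepIter EM controls forwarded to [fitGRM()] and
#'   [difTest()].
#' @param seed integer; recorded and set for reproducibility.
#' @param outdir optional directory: when given, [writeReport()] is called.
#' @param verbose print progress.
#' @return a `PipelineReport` (list): `dimensions` (per-dimension results),
#'   `removedItems`, `metadata`.
#' @export
runReevaluation <- function(responses, groups, dimensions,
                            difVariables = colnames(groups),
                            grid = abilityGrid(),
                            infoTheta = seq(-4, 4, by = 0.1),
                            esGrid = seq(-8, 8, by = 0.01),
                            alphaDif = 0.01, alphaFit = 0.01,
                            esThreshold = 1.0, minVariables = 2L,
                            extentEs = 0.5, extentMass = 0.5,
                            priorIncluded = TRUE, standardErrors = FALSE,
                            emTol = 1e-5, emParTol = 1e-4, mstepIter = 10L,
                            seed = 1L, outdir = NULL, verbose = FALSE) {
  stopifnot(is(responses, "ResponseMatrix"), is.data.frame(groups))
  if (nrow(groups) != nrow(responses@codes))
    stop("'groups' must have one row per person")
  if (!all(difVariables %in% colnames(groups)))
    stop("unknown DIF variables: ",
         paste(setdiff(difVariables, colnames(groups)), collapse = ", "))
  allItems <- unlist(dimensions, use.names = FALSE)
  if (anyDuplicated(allItems))
    stop("items assigned to more than one dimension: ",
         paste(unique(allItems[duplicated(allItems)]), collapse = ", "))
  missingItems <- setdiff(allItems, itemIds(responses))
  if (length(missingItems))
    stop("items not in the response matrix: ", paste(missingItems, collapse = ", "))
  if (alphaDif <= 0 || alphaDif >= 1 || alphaFit <= 0 || alphaFit >= 1)
    stop("alpha levels must lie in (0, 1)")
  set.seed(seed)
  say <- function(...) if (verbose) message(...)

  dimOut <- vector("list", length(dimensions))
  names(dimOut) <- names(dimensions)
  for (dim in names(dimensions)) {
    dimOut[[dim]] <- tryCatch({
      ids <- dimensions[[dim]]
      sub <- responseMatrix(responses@codes[, ids, drop = FALSE],
                            responses@nCategories)
      say("calibrating '", dim, "' (", length(ids), " items)")
      cal <- fitGRM(sub, grid, tol = emTol, parTol = emParTol,
                    standardErrors = standardErrors, mstepIter = mstepIter,
                    scaleName = dim)
      scale <- calibratedScale(cal)

      fits <- lapply(ids, function(id)
        sx2ItemFit(sub, scale, id, grid, alpha = alphaFit))
      names(fits) <- ids

      difs <- list()
      for (v in difVariables) for (id in ids) {
        say("  DIF: ", id, " x ", v)
        difs[[paste(id, v, sep = ".")]] <-
          difTest(sub, groups[[v]], scale, id, grid, alpha = alphaDif,
                  esGrid = esGrid, variable = v, tol = emTol,
                  parTol = emParTol, mstepIter = mstepIter)
      }
      removals <- lapply(ids, function(id) {
        rs <- Filter(function(r) r@itemId == id, difs)
        removalDecision(rs, esThreshold, minVariables, extentEs, extentMass)
      })
      names(removals) <- ids
      removed <- ids[vapply(removals, `[[`, logical(1), "remove")]

      finalCal <- cal; finalDifs <- list()
      if (length(removed)) {
        keep <- setdiff(ids, removed)
        say("  removing: ", paste(removed, collapse = ", "))
        sub2 <- responseMatrix(responses@codes[, keep, drop = FALSE],
                               responses@nCategories)
        finalCal <- fitGRM(sub2, grid, tol = emTol, parTol = emParTol,
                           standardErrors = standardErrors,
                           mstepIter = mstepIter, scaleName = dim)
        flagged <- unique(vapply(
          Filter(function(r) r@classification != "none", difs),
          function(r) r@itemId, character(1)))
        for (id in intersect(flagged, keep)) {
          vars <- vapply(Filter(function(r)
            r@itemId == id && r@classification != "none", difs),
            function(r) r@variable, character(1))
          for (v in vars)
            finalDifs[[paste(id, v, sep = ".")]] <-
              difTest(sub2, groups[[v]], calibratedScale(finalCal), id, grid,
                      alpha = alphaDif, esGrid = esGrid, variable = v,
                      tol = emTol, parTol = emParTol, mstepIter = mstepIter)
        }
      }
      finalScale <- calibratedScale(finalCal)
      info <- scaleInformation(finalScale, infoTheta, priorIncluded)
      finalSub <- responseMatrix(
        responses@codes[, itemIds(finalScale), drop = FALSE],
        responses@nCategories)
      sep <- subjectSeparation(eapScores(finalSub, finalScale, grid))
      list(initialCalibration = cal, itemFit = fits, dif = difs,
           removals = removals, removedItems = removed,
           finalCalibration = finalCal, finalDif = finalDifs,
           information = info, separation = sep, error = NULL)
    }, error = function(e) {
      warning("dimension '", dim, "' failed: ", conditionMessage(e))
      list(error = conditionMessage(e))
    })
  }
  report <- structure(list(
    dimensions = dimOut,
    removedItems = unlist(lapply(dimOut, function(d)
      if (is.null(d$error)) d$removedItems else character()), use.names = FALSE),
    metadata = list(
      seed = seed, nPersons = nrow(responses@codes),
      difVariables = difVariables, alphaDif = alphaDif, alphaFit = alphaFit,
      esThreshold = esThreshold, minVariables = minVariables,
      extentEs = extentEs, extentMass = extentMass,
      grid = list(points = range(grid@points), n = length(grid@points)),
      packageVersion = as.character(utils::packageVersion("gradedDIF")))),
    class = "PipelineReport")
  if (!is.null(outdir)) writeReport(report, outdir)
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("IRT re-evaluation report (", length(x$dimensions), " dimensions, n = ",
      x$metadata$nPersons, ")\n", sep = "")
  for (dim in names(x$dimensions)) {
    d <- x$dimensions[[dim]]
    if (!is.null(d$error)) { cat("  ", dim, ": FAILED - ", d$error, "\n"); next }
    i <- which.max(d$information@totalInformation)
    cat(sprintf(
      "  %-22s %d items, %d removed; max info %.1f (SE %.2f) at theta %.1f; separation %.2f\n",
      dim, length(d$itemFit), length(d$removedItems),
      d$information@totalInformation[i], d$information@standardError[i],
      d$information@theta[i], d$separation))
  }
  if (length(x$removedItems))
    cat("removed items:", paste(x$removedItems, collapse = ", "), "\n")
  invisible(x)
}

.difTable <- function(difs) {
  do.call(rbind, lapply(difs, function(r) data.frame(
    item_id = r@itemId, variable = r@variable,
    reference = r@groupLabels[1], focal = r@groupLabels[2],
    g2_slope = r@g2Slope, df_slope = r@dfSlope, p_slope = r@pSlope,
    g2_thresholds = r@g2Thresholds, df_thresholds = r@dfThresholds,
    p_thresholds = r@pThresholds, classification = r@classification,
    es_delta_max = r@esDeltaMax, theta_at_max = r@thetaAtMax,
    focal_mean = r@focalMean, focal_sd = r@focalSd, row.names = NULL)))
}

.fitTable <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    item_id = f@itemId, statistic = f@statistic, df = f@df,
    p = f@pValue, misfit = f@misfit, row.names = NULL)))
}

#' Write a pipeline report to files
#'
#' Emits `report.json` plus per-dimension CSV tables: fitted parameters
#' (`params_<dim>.csv`, initial and final), item fit (`fit_<dim>.csv`),
#' DIF results (`dif_<dim>.csv`, both passes), information curves
#' (`info_<dim>.csv`), and a `log.txt` with run metadata and every removal
#' reason.
#'
#' @param report a `PipelineReport` from [runReevaluation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "PipelineReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("gradedDIF %s pipeline run",
                        report$metadata$packageVersion),
                sprintf("seed: %d; persons: %d", report$metadata$seed,
                        report$metadata$nPersons),
                sprintf("DIF variables: %s",
                        paste(report$metadata$difVariables, collapse = ", ")))
  json <- list(metadata = report$metadata,
               removedItems = report$removedItems, dimensions = list())
  for (dim in names(report$dimensions)) {
    d <- report$dimensions[[dim]]
    tag <- gsub("[^A-Za-z0-9]+", "_", tolower(dim))
    if (!is.null(d$error)) {
      json$dimensions[[dim]] <- list(error = d$error)
      logLines <- c(logLines, sprintf("%s: FAILED (%s)", dim, d$error))
      next
    }
    scaleDf <- function(cal) {
      sc <- calibratedScale(cal)
      b <- t(vapply(sc@items, function(i) i@thresholds,
                    numeric(length(sc@items[[1]]@thresholds))))
      colnames(b) <- paste0("b", seq_len(ncol(b)))
      data.frame(item_id = itemIds(sc), slope = unname(slopes(sc)), b,
                 row.names = NULL)
    }
    pInit <- cbind(pass = "initial", scaleDf(d$initialCalibration))
    pFin <- cbind(pass = "final", scaleDf(d$finalCalibration))
    utils::write.csv(rbind(pInit, pFin),
                     file.path(dir, paste0("params_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(.fitTable(d$itemFit),
                     file.path(dir, paste0("fit_", tag, ".csv")),
                     row.names = FALSE)
    difAll <- rbind(
      if (length(d$dif)) cbind(pass = "initial", .difTable(d$dif)),
      if (length(d$finalDif)) cbind(pass = "post-removal", .difTable(d$finalDif)))
    if (!is.null(difAll))
      utils::write.csv(difAll, file.path(dir, paste0("dif_", tag, ".csv")),
                       row.names = FALSE)
    utils::write.csv(informationTable(d$information),
                     file.path(dir, paste0("info_", tag, ".csv")),
                     row.names = FALSE)
    for (rm_ in d$removals)
      if (rm_$remove)
        logLines <- c(logLines, sprintf("%s: removed %s (%s)", dim,
                      rm_$itemId, paste(rm_$reasons, collapse = "; ")))
    json$dimensions[[dim]] <- list(
      logLik = d$initialCalibration@logLik,
      converged = d$initialCalibration@converged,
      removedItems = as.list(d$removedItems),
      removalReasons = lapply(d$removals, `[`, c("remove", "reasons")),
      finalLogLik = d$finalCalibration@logLik,
      separation = d$separation,
      maxInformation = max(d$information@totalInformation),
      itemFit = .fitTable(d$itemFit),
      dif = if (!is.null(difAll)) difAll)
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")
  writeLines(logLines, file.path(dir, "log.txt"))
  invisible(dir)
}
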