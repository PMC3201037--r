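# Plain-text interchange: response CSVs (person id + item codes, empty/NA =
# missing), subgroup CSVs, parameter tables (CSV or JSON), config files.

#' Read an ordinal response matrix from CSV
#'
#' First column: person id; remaining columns: item codes in
#' `0..nCategories-1`. Empty cells and `NA` are missing responses — never
#' code 0. Malformed cells are reported with their row and column.
#'
#' @param path CSV file.
#' @param nCategories number of response categories (default 6).
#' @return a [ResponseMatrix-class].
#' @export
readResponses <- function(path, nCategories = 6L) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("response CSV needs a person-id column plus item columns")
  persons <- df[[1]]
  if (anyDuplicated(persons)) stop("duplicated person ids in ", path)
  items <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(items), nrow(items),
                                 dimnames = dimnames(items)))
  bad <- which((!is.na(items) & is.na(num)) |
               (!is.na(num) & (num != round(num) | num < 0 | num > nCategories - 1)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop(sprintf(
      "invalid code '%s' at row %d (person '%s'), column '%s' of %s: expected integer 0..%d or empty",
      items[b[1], b[2]], b[1] + 1L, persons[b[1]],
      colnames(items)[b[2]], path, nCategories - 1L))
  }
  rownames(num) <- persons
  responseMatrix(num, nCategories)
}

#' @describeIn readResponses write a response matrix as CSV (missing as
#'   empty cells); returns `path` invisibly.
#' @param responses a [ResponseMatrix-class].
#' @export
writeResponses <- function(responses, path) {
  stopifnot(is(responses, "ResponseMatrix"))
  X <- responses@codes
  df <- data.frame(person = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read GRM item parameters from CSV or JSON
#'
#' CSV layout: columns `item_id`, `slope`, `b1..bm` (one row per item).
#' JSON layout: array of objects with `item_id`, `slope`, `thresholds`.
#' The format is chosen by file extension.
#'
#' @param path file path (`.csv` or `.json`).
#' @param scaleName label of the returned scale (default: file base name).
#' @return a [ScaleParameters-class].
#' @export
readItemParameters <- function(path, scaleName = NULL) {
  if (is.null(scaleName))
    scaleName <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
    items <- lapply(seq_len(nrow(rec)), function(i)
      itemParameters(rec$item_id[i], rec$slope[i], unlist(rec$thresholds[i])))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
    if (!all(c("item_id", "slope") %in% names(df)) || !length(bcols))
      stop("parameter CSV needs columns item_id, slope, b1..bm")
    bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
    items <- lapply(seq_len(nrow(df)), function(i)
      itemParameters(df$item_id[i], df$slope[i], as.numeric(df[i, bcols])))
  }
  scaleParameters(scaleName, items)
}

#' @describeIn readItemParameters write a scale's parameters (format by
#'   extension); returns `path` invisibly.
#' @param scale a [ScaleParameters-class].
#' @export
writeItemParameters <- function(scale, path) {
  stopifnot(is(scale, "ScaleParameters"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- lapply(scale@items, function(i)
      list(item_id = i@itemId, slope = i@slope, thresholds = i@thresholds))
    jsonlite::write_json(unname(rec), path, auto_unbox = TRUE, digits = NA)
  } else {
    b <- t(vapply(scale@items, function(i) i@thresholds,
                  numeric(length(scale@items[[1]]@thresholds))))
    colnames(b) <- paste0("b", seq_len(ncol(b)))
    df <- data.frame(item_id = itemIds(scale), slope = unname(slopes(scale)), b)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-person subgroup labels
#'
#' CSV with a person-id first column and one column per subgroup variable;
#' each column must carry exactly two distinct labels. The first label in
#' file order becomes the reference level.
#'
#' @param path CSV file.
#' @return data.frame of factors, rownames = person ids.
#' @export
readGroups <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("groups CSV needs a person-id column plus variable columns")
  out <- df[, -1, drop = FALSE]
  rownames(out) <- df[[1]]
  for (v in names(out)) out[[v]] <- factor(out[[v]], levels = unique(out[[v]]))
  out
}

#' Read a pipeline configuration file
#'
#' JSON always; YAML when the `yaml` package is available. Returns the
#' parsed list unchanged; interpretation is up to [runReevaluation()]'s
#' arguments.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
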