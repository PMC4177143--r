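#' Construct a ClinicalCohort
#'
#' @param observations long-format `data.frame`; see
#'   [ClinicalCohort-class] for the required columns.
#' @param ranges reference ranges covering every panel parameter.
#' @param parameters panel columns, in the fixed order used downstream;
#'   defaults to every range parameter present in `observations`.
#' @return a validated [ClinicalCohort-class] object with per-patient rows
#'   sorted by time.
#' @export
clinicalCohort <- function(observations, ranges = defaultRanges(),
                           parameters = NULL) {
  if (is.null(parameters))
    parameters <- intersect(ranges$parameter, names(observations))
  observations$patient_id <- as.character(observations$patient_id)
  observations$point_index <- as.integer(observations$point_index)
  if (is.null(observations$time_days))
    observations$time_days <- as.numeric(observations$point_index - 1L)
  ord <- order(observations$patient_id, observations$time_days,
               observations$point_index)
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  for (id in unique(observations$patient_id)) {
    sel <- observations$patient_id == id
    tt <- observations$time_days[sel]
    pp <- observations$point_index[sel]
    if (any(diff(tt) <= 0) || any(diff(pp) <= 0))
      snValidationError(sprintf(
        "patient '%s': observations must be strictly increasing in time and point_index",
        id))
  }
  new("ClinicalCohort", observations = observations, ranges = ranges,
      parameters = parameters)
}

#' Read a longitudinal cohort from delimited text
#'
#' Expects a comma-separated UTF-8 file with a header row naming at least
#' `patient_id`, `point_index` and one panel parameter; `time_days` and
#' `state` are optional. When `time_days` is absent, unit spacing (1 day
#' per point step) is assumed. Rows failing validation abort the read with
#' a message naming each offending row; nothing is silently dropped.
#'
#' @param path path to the CSV file.
#' @param ranges reference ranges covering every panel parameter present.
#' @return a [ClinicalCohort-class].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path, ranges = defaultRanges()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  mandatory <- c("patient_id", "point_index")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0L)
    snValidationError(sprintf("%s: missing mandatory column(s): %s",
                              path, paste(miss, collapse = ", ")))
  params <- intersect(ranges$parameter, names(raw))
  if (length(params) == 0L)
    snValidationError(sprintf("%s: no panel parameter column found", path))

  problems <- character()
  numify <- function(col, required = TRUE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & (required | !(is.na(raw[[col]]) |
                                          raw[[col]] %in% c("", "NA"))))
    if (length(bad) > 0L)
      problems <<- c(problems, sprintf(
        "column '%s': non-numeric value in data row(s) %s",
        col, paste(bad, collapse = ", ")))
    v
  }
  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  out$point_index <- numify("point_index")
  out$time_days <- if ("time_days" %in% names(raw)) numify("time_days")
                   else as.numeric(out$point_index - 1)
  for (p in params) out[[p]] <- numify(p)
  if ("state" %in% names(raw)) {
    v <- suppressWarnings(as.integer(raw$state))
    bad <- which(is.na(v) & !(is.na(raw$state) | raw$state %in% c("", "NA")))
    if (length(bad) > 0L)
      problems <- c(problems, sprintf(
        "column 'state': non-integer value in data row(s) %s",
        paste(bad, collapse = ", ")))
    out$state <- v
  }
  dup <- which(duplicated(out[, c("patient_id", "point_index")]))
  if (length(dup) > 0L)
    problems <- c(problems, sprintf(
      "duplicate (patient_id, point_index) in data row(s) %s",
      paste(dup, collapse = ", ")))
  if (length(problems) > 0L)
    snValidationError(paste0(path, ": validation failed\n  - ",
                             paste(problems, collapse = "\n  - ")))
  clinicalCohort(out, ranges, parameters = params)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [readCohort()]: writes the observation table as CSV with the
#' canonical column order. Numeric values use R's full-precision default
#' formatting so a read/write round trip preserves every field.
#'
#' @param cohort a [ClinicalCohort-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  obs <- observations(cohort)
  lead <- c("patient_id", "point_index", "time_days")
  rest <- c(panelParameters(cohort), intersect("state", names(obs)))
  utils::write.csv(obs[, c(lead, rest)], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname ClinicalCohort-class
#' @export
setMethod("observations", "ClinicalCohort", function(object)
  object@observations)

#' @rdname ClinicalCohort-class
#' @export
setMethod("refRanges", "ClinicalCohort", function(object) object@ranges)

#' @rdname ClinicalCohort-class
#' @export
setMethod("panelParameters", "ClinicalCohort", function(object)
  object@parameters)

#' @rdname ClinicalCohort-class
#' @export
setMethod("patientIDs", "ClinicalCohort", function(object)
  unique(object@observations$patient_id))

setMethod("show", "ClinicalCohort", function(object) {
  obs <- object@observations
  cat(sprintf("ClinicalCohort: %d patients, %d observations\n",
              length(unique(obs$patient_id)), nrow(obs)))
  cat("  parameters:", paste(object@parameters, collapse = ", "), "\n")
  cat(sprintf("  observed states: %s\n",
              if ("state" %in% names(obs)) "present" else "absent"))
})

#' Extract one patient's ordered series
#'
#' @param cohort a [ClinicalCohort-class].
#' @param patientID patient identifier.
#' @return `data.frame` of that patient's observations sorted by time, with
#'   the cohort's ranges attached as attribute `"ranges"` and the panel
#'   vocabulary as attribute `"parameters"`.
#' @export
patientSeries <- function(cohort, patientID) {
  obs <- observations(cohort)
  s <- obs[obs$patient_id == patientID, , drop = FALSE]
  if (nrow(s) == 0L)
    snValidationError(sprintf("no such patient: '%s'", patientID))
  rownames(s) <- NULL
  attr(s, "ranges") <- refRanges(cohort)
  attr(s, "parameters") <- panelParameters(cohort)
  s
}

#' Discretize a cohort into mining transactions
#'
#' Builds one transaction per patient from the panel at a chosen temporal
#' point: each analyte contributes a `<PANEL>_<Param>=<CATEGORY>` token and,
#' when the observed state is present, a `STATE=<s>` token is added.
#'
#' @param cohort a [ClinicalCohort-class].
#' @param point which temporal point to discretize; `"last"` (default) uses
#'   each patient's final observation, or an integer point index.
#' @return a [TransactionSet-class] with one transaction per patient.
#' @export
cohortTransactions <- function(cohort, point = "last") {
  ids <- patientIDs(cohort)
  params <- panelParameters(cohort)
  rng <- refRanges(cohort)
  items <- lapply(ids, function(id) {
    s <- patientSeries(cohort, id)
    row <- if (identical(point, "last")) s[nrow(s), , drop = FALSE]
           else s[s$point_index == point, , drop = FALSE]
    if (nrow(row) == 0L)
      snValidationError(sprintf("patient '%s' has no point %s", id, point))
    panel <- stats::setNames(as.numeric(row[1, params]), params)
    cats <- discretizePanel(panel, rng)
    toks <- itemToken(params, cats)
    if ("state" %in% names(row) && !is.na(row$state[1]))
      toks <- c(toks, itemToken("state", row$state[1]))
    sort(toks)
  })
  transactionSet(ids, items)
}
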