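#' End-to-end pipeline: discretize, mine, select parameters, predict
#'
#' Runs the full two-phase analysis on a records file: the cohort's
#' final-point panels are discretized into transactions; frequent itemsets
#' are mined at `minSupport` and rules generated at `minConfidenceFirst`
#' then filtered at `minConfidenceFinal`; the analytes whose HIGH/LOW item
#' appears in the antecedent of a surviving rule with a STATE item in the
#' consequent become the selected parameters; and the SN predictor is run
#' over those parameters for every patient. If fewer than two analytes are
#' implicated with the state (the area statistic needs at least two), the
#' configured `selectedParameters` are used with a warning.
#'
#' @param recordsPath CSV of longitudinal panels (see [readCohort()]).
#' @param outDir directory for `rules.csv`, `predictions.csv` and
#'   `run_log.yaml`; created if needed.
#' @param rangesPath optional YAML of reference ranges ([readRanges()]);
#'   defaults to [defaultRanges()].
#' @param minSupport minimum support (default 0.30).
#' @param minConfidenceFirst first-pass minimum confidence for rule
#'   generation (default 0.50).
#' @param minConfidenceFinal final confidence filter (default 0.85).
#' @param theta decision threshold, or `"calibrate"` to calibrate from the
#'   cohort's observed state transitions.
#' @param selectedParameters fallback analyte order for the SN phase.
#' @param useObserved anchor predictions on observed states where present.
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return invisibly, a list with `rules`, `selected`, `theta`,
#'   `predictions` and the paths written.
#' @export
runPipeline <- function(recordsPath, outDir, rangesPath = NULL,
                        minSupport = 0.30, minConfidenceFirst = 0.50,
                        minConfidenceFinal = 0.85, theta = "calibrate",
                        selectedParameters = c("creatinine", "bun",
                                               "sgot", "sgpt"),
                        useObserved = TRUE, seed = 1L) {
  for (th in c(minSupport, minConfidenceFirst, minConfidenceFinal))
    if (!(th > 0 && th <= 1))
      snConfigError("mining thresholds must be in (0, 1]")
  ranges <- if (is.null(rangesPath)) defaultRanges() else readRanges(rangesPath)
  cohort <- readCohort(recordsPath, ranges)
  set.seed(seed)

  tx <- cohortTransactions(cohort, point = "last")
  freq <- apriori(tx, minSupport)
  rules <- generateRules(freq, tx, minConfidenceFirst)
  rulesFinal <- rules[rules$confidence >= minConfidenceFinal - 1e-9, ,
                      drop = FALSE]

  selected <- selectParameters(rulesFinal, panelParameters(cohort))
  if (length(selected) < 2L) {  # the wedge needs at least two analytes
    warning("fewer than two analytes implicated with STATE by the final ",
            "rules; falling back to configured selected parameters")
    selected <- selectedParameters
  }

  if (identical(theta, "calibrate")) {
    lab <- labelledAreas(cohort, selected)
    if (nrow(lab) == 0L)
      snInsufficientDataError(
        "theta calibration needs observed states over at least one point pair")
    theta <- calibrateThreshold(lab$dA, lab$persisted)
  }
  preds <- predictCohort(cohort, theta, parameters = selected,
                         useObserved = useObserved)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rulesPath <- file.path(outDir, "rules.csv")
  predsPath <- file.path(outDir, "predictions.csv")
  logPath <- file.path(outDir, "run_log.yaml")
  writeRules(rulesFinal, rulesPath)
  utils::write.csv(preds, predsPath, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    package = "temporalSN",
    version = as.character(utils::packageVersion("temporalSN")),
    r_version = as.character(getRversion()),
    seed = seed,
    input = list(records = recordsPath,
                 md5 = unname(tools::md5sum(recordsPath))),
    config = list(min_support = minSupport,
                  min_confidence_first = minConfidenceFirst,
                  min_confidence_final = minConfidenceFinal,
                  theta = theta, selected_parameters = selected,
                  evaluation_mode = useObserved)), logPath)
  invisible(list(rules = rulesFinal, selected = selected, theta = theta,
                 predictions = preds,
                 paths = c(rules = rulesPath, predictions = predsPath,
                           log = logPath)))
}

#' Select analytes implicated with the disease state by the mined rules
#'
#' An analyte is selected when one of its HIGH/LOW items appears in the
#' antecedent of a rule whose consequent contains a STATE item. The
#' returned vector follows the order of `vocabulary`.
#'
#' @param rules a [generateRules()] table.
#' @param vocabulary candidate analyte names.
#' @return character vector of selected analytes (possibly empty).
#' @export
selectParameters <- function(rules, vocabulary) {
  if (nrow(rules) == 0L) return(character())
  hasState <- grepl("(^|;)STATE=", rules$consequent)
  toks <- unique(unlist(strsplit(rules$antecedent[hasState], ";",
                                 fixed = TRUE)))
  hit <- vapply(vocabulary, function(p)
    any(toks %in% itemToken(p, c("HIGH", "LOW"))), logical(1))
  vocabulary[hit]
}

#' Labelled differential areas from observed state transitions
#'
#' Builds the calibration input for [calibrateThreshold()] from a cohort
#' with observed states: every consecutive point pair with both states
#' observed contributes its dA, labelled persisting when the state did not
#' change.
#'
#' @param cohort a [ClinicalCohort-class] with a `state` column.
#' @param parameters selected analytes for the dA computation.
#' @return `data.frame` with `patient_id`, `point_index`, `dA`,
#'   `persisted`.
#' @export
labelledAreas <- function(cohort, parameters) {
  obs <- observations(cohort)
  if (!("state" %in% names(obs))) return(
    data.frame(patient_id = character(), point_index = integer(),
               dA = numeric(), persisted = logical()))
  out <- lapply(patientIDs(cohort), function(id) {
    s <- patientSeries(cohort, id)
    ks <- which(seq_len(nrow(s)) >= 2 & !is.na(s$state) &
                !is.na(c(NA, s$state[-nrow(s)])))
    if (length(ks) == 0L) return(NULL)
    data.frame(
      patient_id = id, point_index = s$point_index[ks],
      dA = vapply(ks, function(k)
        differentialArea(s, k, parameters = parameters)$dA, numeric(1)),
      persisted = s$state[ks] == s$state[ks - 1L])
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(patient_id = character(), point_index = integer(),
                      dA = numeric(), persisted = logical())
  rownames(res) <- NULL
  res
}
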