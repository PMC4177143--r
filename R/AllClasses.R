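#' @import methods
NULL

#' Longitudinal clinical cohort container
#'
#' `ClinicalCohort` holds one long-format table of patient laboratory panels
#' observed at ordered temporal points, together with the reference ranges
#' used for normalization and discretization. One row is one patient at one
#' temporal point; panel analytes (e.g. creatinine, bun, sgot, sgpt,
#' haemoglobin) are columns in clinical units, and an optional integer
#' `state` column carries the observed disease state at that point.
#'
#' @slot observations `data.frame` with columns `patient_id` (character),
#'   `point_index` (integer, >= 1, unique within a patient), `time_days`
#'   (numeric, days since the patient's first observation), one numeric
#'   column per panel parameter, and optionally `state` (integer >= 0,
#'   `NA` allowed for hidden states).
#' @slot ranges `data.frame` of reference ranges, as returned by
#'   [referenceRanges()].
#' @slot parameters character vector naming the panel columns, in the fixed
#'   order used by downstream derivative computations.
#'
#' @seealso [readCohort()], [simulateCohort()], [patientSeries()]
#' @export
setClass("ClinicalCohort",
  representation(
    observations = "data.frame",
    ranges       = "data.frame",
    parameters   = "character"
  )
)

setValidity("ClinicalCohort", function(object) {
  obs <- object@observations
  msgs <- character()
  needed <- c("patient_id", "point_index", "time_days", object@parameters)
  miss <- setdiff(needed, names(obs))
  if (length(miss) > 0L)
    msgs <- c(msgs, paste("missing observation columns:",
                          paste(miss, collapse = ", ")))
  if (length(object@parameters) == 0L)
    msgs <- c(msgs, "at least one panel parameter is required")
  if (length(msgs) == 0L) {
    if (anyDuplicated(obs[, c("patient_id", "point_index")]))
      msgs <- c(msgs, "duplicate (patient_id, point_index) pairs")
    if (any(obs$point_index < 1L))
      msgs <- c(msgs, "point_index must be >= 1")
    for (p in object@parameters) {
      v <- obs[[p]]
      if (!is.numeric(v) || any(!is.finite(v)))
        msgs <- c(msgs, sprintf("parameter '%s' has non-finite values", p))
    }
    rmiss <- setdiff(object@parameters, object@ranges$parameter)
    if (length(rmiss) > 0L)
      msgs <- c(msgs, paste("no reference range for:",
                            paste(rmiss, collapse = ", ")))
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Transaction set for association mining
#'
#' A `TransactionSet` is an ordered collection of transactions, each a set of
#' item tokens such as `KFT_Creatinine=HIGH` or `STATE=1`. Items within a
#' transaction are unique and stored sorted; empty transactions are allowed
#' (they contribute to the support denominator only).
#'
#' @slot ids character vector of transaction identifiers.
#' @slot items list of character vectors, one per transaction.
#'
#' @seealso [transactionSet()], [apriori()], [cohortTransactions()]
#' @export
setClass("TransactionSet",
  representation(ids = "character", items = "list")
)

setValidity("TransactionSet", function(object) {
  msgs <- character()
  if (length(object@ids) != length(object@items))
    msgs <- c(msgs, "ids and items must have equal length")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "transaction ids must be unique")
  bad <- vapply(object@items, function(x) {
    !is.character(x) || anyNA(x) || anyDuplicated(x) > 0L
  }, logical(1))
  if (any(bad))
    msgs <- c(msgs, sprintf("transactions with NA or duplicate items: %s",
                            paste(utils::head(which(bad), 5L), collapse = ", ")))
  if (length(msgs) > 0L) msgs else TRUE
})

#' Synthetic cohort specification
#'
#' Parameters of the synthetic longitudinal cohort generator. All magnitudes
#' are in normalized (reference-range) units: a value of 1 equals half the
#' width of the analyte's reference interval.
#'
#' @slot nPatients integer >= 1, number of patients.
#' @slot nPoints integer >= 2, temporal points per patient.
#' @slot spacingDays numeric > 0, days between consecutive points.
#' @slot noiseSd numeric >= 0, standard deviation of the Gaussian process
#'   noise added to each per-interval increment (normalized units).
#' @slot effectSize numeric >= 0, magnitude of the progression jump applied
#'   coherently to (creatinine, bun, sgot, sgpt) at the transition point,
#'   in a direction orthogonal to the patient's drift (normalized units).
#' @slot progressionFraction fraction in `[0, 1]` of patients that progress.
#' @slot transitionPoint integer in `[2, nPoints]`, the temporal point at
#'   which progressors jump (and their state increments).
#' @slot driftStep numeric >= 0, per-interval drift magnitude along the
#'   patient's trajectory direction (normalized units).
#' @slot baselineSd numeric >= 0, spread of the baseline displacement along
#'   the drift line (normalized units).
#' @slot seed integer random seed.
#'
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nPatients = "integer", nPoints = "integer", spacingDays = "numeric",
    noiseSd = "numeric", effectSize = "numeric",
    progressionFraction = "numeric", transitionPoint = "integer",
    driftStep = "numeric", baselineSd = "numeric", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nPatients < 1L) msgs <- c(msgs, "nPatients must be >= 1")
  if (object@nPoints < 2L) msgs <- c(msgs, "nPoints must be >= 2")
  if (!(object@spacingDays > 0)) msgs <- c(msgs, "spacingDays must be > 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@effectSize < 0) msgs <- c(msgs, "effectSize must be >= 0")
  if (object@progressionFraction < 0 || object@progressionFraction > 1)
    msgs <- c(msgs, "progressionFraction must be in [0, 1]")
  if (object@transitionPoint < 2L || object@transitionPoint > object@nPoints)
    msgs <- c(msgs, "transitionPoint must be in [2, nPoints]")
  if (object@driftStep < 0) msgs <- c(msgs, "driftStep must be >= 0")
  if (object@baselineSd < 0) msgs <- c(msgs, "baselineSd must be >= 0")
  if (length(msgs) > 0L) msgs else TRUE
})
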