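# The SN algorithm: per-temporal-point derivative vectors of the selected
# analytes, a differential-area statistic between consecutive points, and a
# persist/progress decision against a calibrated threshold.
#
# The "Jacobian" J_k at temporal point T_k is concretized as the vector of
# per-parameter finite-difference rates of change over the preceding
# interval, computed on reference-range-normalized values; the baseline
# point (k = 1, no predecessor) uses the normalized deviations from the
# range midpoints themselves with a unit time increment, anchoring the walk
# at the known initial state. The differential area dA for the pair
# (T_{k-1}, T_k) is the parallelogram area spanned by the time-scaled
# derivative vectors dx = J_{k-1} dt_{k-1} and dy = J_k dt_k, i.e. the
# Gram-determinant (wedge) area, which reduces to |dx1 dy2 - dx2 dy1| in
# two dimensions. Collinear trajectories give dA = 0 (state persists);
# a direction change gives dA > 0 and, past the threshold, a progression
# call.

#' Parallelogram (wedge / Gram) area of two vectors
#'
#' `sqrt(|dx|^2 |dy|^2 - (dx . dy)^2)`, the area of the parallelogram
#' spanned by `dx` and `dy` in p-dimensional space. For `p = 2` this equals
#' the absolute value of the 2x2 determinant `|dx1 dy2 - dx2 dy1|`. The
#' area is always >= 0 and is 0 exactly when the vectors are linearly
#' dependent.
#'
#' @param dx,dy numeric vectors of equal length `p >= 2`.
#' @return non-negative scalar area.
#' @examples
#' wedgeArea(c(1, 0), c(0, 1))      # 1
#' wedgeArea(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4))  # 0 (collinear)
#' @export
wedgeArea <- function(dx, dy) {
  if (length(dx) != length(dy))
    snValidationError("dx and dy must have the same dimension")
  if (length(dx) < 2L)
    snValidationError("wedge area needs dimension >= 2")
  dx <- as.numeric(dx); dy <- as.numeric(dy)
  # in the plane the Gram root reduces to the 2x2 determinant, which is
  # also the numerically exact form near collinearity
  if (length(dx) == 2L) return(abs(dx[1] * dy[2] - dx[2] * dy[1]))
  g11 <- sum(dx * dx); g22 <- sum(dy * dy); g12 <- sum(dx * dy)
  sqrt(max(g11 * g22 - g12 * g12, 0))
}

.seriesMatrix <- function(series, ranges = NULL, parameters = NULL) {
  if (is.null(ranges)) ranges <- attr(series, "ranges")
  if (is.null(parameters))
    parameters <- attr(series, "parameters")
  if (is.null(ranges) || is.null(parameters))
    snConfigError("series needs 'ranges' and 'parameters' (attributes or arguments)")
  miss <- setdiff(parameters, names(series))
  if (length(miss) > 0L)
    snValidationError(paste("series lacks parameter column(s):",
                            paste(miss, collapse = ", ")))
  bad <- which(!stats::complete.cases(series[, parameters, drop = FALSE]))
  if (length(bad) > 0L)
    snValidationError(sprintf(
      "temporal point(s) %s unusable: missing selected-parameter values",
      paste(series$point_index[bad], collapse = ", ")))
  X <- t(vapply(seq_len(nrow(series)), function(i) {
    panel <- stats::setNames(as.numeric(series[i, parameters]), parameters)
    normalizePanel(panel, ranges)
  }, numeric(length(parameters))))
  colnames(X) <- parameters
  list(X = X, t = series$time_days)
}

#' Derivative vector at a temporal point
#'
#' For `k >= 2`, the per-parameter finite-difference rate
#' `(P_k - P_{k-1}) / dt` on normalized values, with
#' `dt = t_k - t_{k-1}` in days. For `k = 1` (no predecessor) the
#' components are the normalized panel values themselves — the deviation
#' from the reference midpoints — with `dt = 1`, serving as the baseline
#' anchor carrying the known initial state.
#'
#' @param series one patient's ordered observations as returned by
#'   [patientSeries()] (or any data.frame with `time_days` and parameter
#'   columns plus `ranges`/`parameters` given explicitly).
#' @param k temporal point index into the series rows, `1 <= k <= n`.
#' @param ranges,parameters override the series attributes; `parameters`
#'   fixes the component order.
#' @return list with `point` (k), `components` (named numeric vector) and
#'   `dt` (days).
#' @export
derivativeAt <- function(series, k, ranges = NULL, parameters = NULL) {
  sm <- .seriesMatrix(series, ranges, parameters)
  n <- nrow(sm$X)
  if (k < 1L || k > n)
    snValidationError(sprintf("point index k=%d out of range 1..%d", k, n))
  if (k == 1L)
    return(list(point = 1L, components = sm$X[1L, ], dt = 1))
  dt <- sm$t[k] - sm$t[k - 1L]
  if (dt <= 0)
    snValidationError(sprintf("non-positive time increment at k=%d", k))
  list(point = as.integer(k), components = (sm$X[k, ] - sm$X[k - 1L, ]) / dt,
       dt = dt)
}

#' Differential area between consecutive temporal points
#'
#' The decision statistic of the SN algorithm for the pair
#' `(T_{k-1}, T_k)`: the derivative vectors at the two points are scaled by
#' their time increments (`dx = J_{k-1} dt_{k-1}`, `dy = J_k dt_k`,
#' mirroring `dx = J du`, `dy = J dv`) and `dA` is their parallelogram
#' area, [wedgeArea()]. `dA` is invariant to the time units: rescaling the
#' increments rescales the derivatives inversely.
#'
#' @inheritParams derivativeAt
#' @param k index of the later point of the pair, `k >= 2`.
#' @return list with `pair` (`c(k-1, k)`), `dA`, and the two scaled
#'   vectors `dx`, `dy`.
#' @export
differentialArea <- function(series, k, ranges = NULL, parameters = NULL) {
  if (k < 2L)
    snValidationError("differential area needs k >= 2")
  j1 <- derivativeAt(series, k - 1L, ranges, parameters)
  j2 <- derivativeAt(series, k, ranges, parameters)
  dx <- j1$components * j1$dt
  dy <- j2$components * j2$dt
  list(pair = c(k - 1L, k), dA = wedgeArea(dx, dy), dx = dx, dy = dy)
}

#' Persist/progress decision for one point pair
#'
#' `dA <= theta` reads the trajectory as consistent with the previous
#' segment and keeps the anchor state; `dA > theta` reads it as a
#' direction change and increments the state by one.
#'
#' @param anchorState integer state at the previous temporal point.
#' @param dA non-negative differential area.
#' @param theta non-negative decision threshold (normalized-units squared).
#' @return list with `predicted_state`, `anchor_state`, `dA`, `threshold`.
#' @export
predictState <- function(anchorState, dA, theta) {
  if (theta < 0) snConfigError("theta must be >= 0")
  if (dA < 0) snValidationError("dA must be >= 0")
  list(predicted_state = as.integer(anchorState + (dA > theta)),
       anchor_state = as.integer(anchorState), dA = dA, threshold = theta)
}

#' Calibrate the decision threshold from labelled point pairs
#'
#' Given differential areas labelled persisting (state unchanged) or
#' progressing, picks theta for the rule "persist iff `dA <= theta`".
#' When the classes separate, theta is the midpoint between the largest
#' persisting dA and the smallest progressing dA; with only persisting
#' pairs it is the largest observed dA (everything seen so far persists);
#' with only progressing pairs, half the smallest progressing dA.
#' Otherwise theta minimizes the number of misclassified pairs over all
#' candidate cut points, ties resolved toward the smallest theta.
#'
#' @param dA numeric vector of non-negative differential areas.
#' @param persisted logical vector: `TRUE` when the state did not change
#'   over that pair.
#' @return non-negative scalar theta.
#' @export
calibrateThreshold <- function(dA, persisted) {
  if (length(dA) == 0L)
    snValidationError("threshold calibration needs at least one labelled pair")
  if (length(dA) != length(persisted))
    snValidationError("dA and persisted must have equal length")
  persisted <- as.logical(persisted)
  if (all(persisted)) return(max(dA))
  if (!any(persisted)) return(min(dA) / 2)
  maxP <- max(dA[persisted]); minQ <- min(dA[!persisted])
  if (maxP < minQ) return((maxP + minQ) / 2)
  cand <- sort(unique(c(0, dA)))
  err <- vapply(cand, function(th)
    sum(persisted & dA > th) + sum(!persisted & dA <= th), numeric(1))
  cand[which.min(err)]  # which.min takes the first, i.e. smallest theta
}

#' Sequential state prediction along one patient's series
#'
#' Walks the temporal points in order. The state at the first point is the
#' supplied anchor (the observed initial state); for every `k >= 2` the
#' differential area of the pair `(k-1, k)` is compared against `theta`.
#' In chained mode (default) each prediction anchors on the previous
#' prediction; in evaluation mode (`useObserved = TRUE`, requires a
#' `state` column) each prediction anchors on the previous *observed*
#' state, mirroring a study design where all states but the last are
#' known. Predictions depend only on observations up to the predicted
#' point: truncating the series never changes earlier predictions.
#'
#' @inheritParams derivativeAt
#' @param theta decision threshold, see [calibrateThreshold()].
#' @param anchor integer state at the first temporal point.
#' @param useObserved anchor each step on the observed previous state
#'   rather than the chained prediction.
#' @return `data.frame` with one row per `k >= 2`: `point_index`, `dA`,
#'   `anchor_state`, `predicted_state` and, when present, the observed
#'   `state` at the predicted point.
#' @export
predictSeries <- function(series, theta, anchor, useObserved = FALSE,
                          ranges = NULL, parameters = NULL) {
  n <- nrow(series)
  if (n < 2L)
    snInsufficientDataError("prediction needs a series of at least 2 usable points")
  if (useObserved && !("state" %in% names(series)))
    snValidationError("evaluation mode requires a 'state' column")
  prev <- as.integer(anchor)
  rows <- vector("list", n - 1L)
  for (k in 2:n) {
    da <- differentialArea(series, k, ranges, parameters)
    p <- predictState(prev, da$dA, theta)
    rows[[k - 1L]] <- data.frame(
      point_index = series$point_index[k], dA = da$dA,
      anchor_state = p$anchor_state, predicted_state = p$predicted_state,
      state = if ("state" %in% names(series)) series$state[k] else NA_integer_)
    prev <- if (useObserved && !is.na(series$state[k]))
      as.integer(series$state[k]) else p$predicted_state
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict states for every patient in a cohort
#'
#' Applies [predictSeries()] to each patient, anchoring at the patient's
#' observed first-point state (or `anchor` when states are absent).
#'
#' @param cohort a [ClinicalCohort-class].
#' @param theta decision threshold.
#' @param parameters selected analytes, in fixed order; defaults to the
#'   kidney/liver quartet when present, else all panel parameters.
#' @param useObserved see [predictSeries()].
#' @param anchor fallback first-point state when no observed state exists.
#' @return `data.frame` with `patient_id` plus the [predictSeries()]
#'   columns.
#' @export
predictCohort <- function(cohort, theta, parameters = NULL,
                          useObserved = FALSE, anchor = 1L) {
  if (is.null(parameters)) {
    quartet <- c("creatinine", "bun", "sgot", "sgpt")
    parameters <- if (all(quartet %in% panelParameters(cohort))) quartet
                  else panelParameters(cohort)
  }
  out <- lapply(patientIDs(cohort), function(id) {
    s <- patientSeries(cohort, id)
    a <- if ("state" %in% names(s) && !is.na(s$state[1])) s$state[1] else anchor
    cbind(patient_id = id,
          predictSeries(s, theta, a, useObserved = useObserved,
                        parameters = parameters))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
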