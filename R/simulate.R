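# Synthetic longitudinal cohort generator. Patients move along a straight
# drift line in normalized (reference-range) space; progressing patients
# additionally receive, at the transition point, a jump orthogonal to their
# drift. Because the SN statistic is the parallelogram area of consecutive
# increments, a noiseless stable trajectory is exactly collinear (dA = 0)
# while the orthogonal jump produces dA = driftStep * effectSize.

#' Construct a CohortSpec
#'
#' Defaults describe the study design the package's recovery experiments
#' emulate: 55 brain-tumour patients followed over three temporal points a
#' quarter apart, half of them progressing at the final point with a jump
#' of 2 normalized units against process noise of 0.1.
#'
#' @param nPatients,nPoints,spacingDays,noiseSd,effectSize,progressionFraction,transitionPoint,driftStep,baselineSd,seed
#'   see [CohortSpec-class].
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients = 55L, nPoints = 3L, spacingDays = 90,
                       noiseSd = 0.1, effectSize = 2.0,
                       progressionFraction = 0.5,
                       transitionPoint = nPoints, driftStep = 0.2,
                       baselineSd = 0.5, seed = 1L) {
  new("CohortSpec",
      nPatients = as.integer(nPatients), nPoints = as.integer(nPoints),
      spacingDays = as.numeric(spacingDays), noiseSd = as.numeric(noiseSd),
      effectSize = as.numeric(effectSize),
      progressionFraction = as.numeric(progressionFraction),
      transitionPoint = as.integer(transitionPoint),
      driftStep = as.numeric(driftStep), baselineSd = as.numeric(baselineSd),
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d patients x %d points (%g d apart), noise %g, effect %g,\n",
    object@nPatients, object@nPoints, object@spacingDays, object@noiseSd,
    object@effectSize))
  cat(sprintf("  progression %g at point %d, drift %g, seed %d\n",
              object@progressionFraction, object@transitionPoint,
              object@driftStep, object@seed))
})

.unitVector <- function(p) {
  v <- stats::rnorm(p)
  v / sqrt(sum(v * v))
}

.orthUnitVector <- function(d) {
  repeat {
    u <- stats::rnorm(length(d))
    u <- u - sum(u * d) * d
    nu <- sqrt(sum(u * u))
    if (nu > 1e-8) return(u / nu)
  }
}

#' Simulate a longitudinal cohort with known state dynamics
#'
#' Each patient gets a random unit drift direction `d` in the normalized
#' space of (creatinine, bun, sgot, sgpt); the trajectory starts at
#' `a0 * d` (a0 ~ N(0, baselineSd^2)) and advances by `driftStep * d` plus
#' Gaussian process noise per interval. Progressing patients (a random
#' fraction) additionally jump by `effectSize` in a direction drawn
#' uniformly on the subspace orthogonal to `d` at the transition point,
#' where their state increments from 1 to 2; all other states are 1
#' (disease present throughout). Haemoglobin is simulated as a stationary
#' analyte: a patient level drawn with spread `baselineSd` plus the same
#' per-point noise, so it mostly stays in range. Normalized values are mapped back
#' to clinical units through the reference ranges (floored just above zero
#' for concentrations).
#'
#' @param spec a [CohortSpec-class].
#' @param ranges reference ranges used to de-normalize; must cover the
#'   quartet and haemoglobin.
#' @return list with `cohort` (a [ClinicalCohort-class] whose `state`
#'   column carries the true/observed states) and `truth`, a `data.frame`
#'   per patient (`patient_id`, `progressor`, plus one `state_k` column per
#'   point) with the per-patient drift directions attached as attribute
#'   `"drift"`.
#' @export
simulateCohort <- function(spec, ranges = defaultRanges()) {
  stopifnot(is(spec, "CohortSpec"))
  if (spec@progressionFraction > 0 && spec@effectSize == 0 &&
      spec@noiseSd == 0)
    warning("degenerate spec: progressors with zero effect and zero noise")
  set.seed(spec@seed)
  quartet <- c("creatinine", "bun", "sgot", "sgpt")
  params <- c(quartet, "haemoglobin")
  n <- spec@nPatients; K <- spec@nPoints
  nProg <- round(spec@progressionFraction * n)
  progressor <- rep(FALSE, n)
  progressor[sample.int(n, nProg)] <- TRUE

  mid <- (ranges$low + ranges$high)[match(params, ranges$parameter)] / 2
  hw <- (ranges$high - ranges$low)[match(params, ranges$parameter)] / 2

  obs <- vector("list", n)
  drift <- matrix(NA_real_, n, 4, dimnames = list(NULL, quartet))
  states <- matrix(1L, n, K)
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    d <- .unitVector(4L)
    drift[i, ] <- d
    a0 <- stats::rnorm(1, 0, spec@baselineSd)
    u <- .orthUnitVector(d)
    X <- matrix(NA_real_, K, 4)
    X[1, ] <- a0 * d
    for (k in 2:K) {
      step <- spec@driftStep * d + stats::rnorm(4, 0, spec@noiseSd)
      if (progressor[i] && k == spec@transitionPoint)
        step <- step + spec@effectSize * u
      X[k, ] <- X[k - 1, ] + step
    }
    if (progressor[i])
      states[i, spec@transitionPoint:K] <- 2L
    h0 <- stats::rnorm(1, 0, spec@baselineSd)
    hb <- h0 + stats::rnorm(K, 0, spec@noiseSd)
    Z <- cbind(X, hb)
    V <- sweep(sweep(Z, 2, hw, `*`), 2, mid, `+`)
    V <- pmax(V, 1e-3)  # concentrations stay positive
    df <- data.frame(patient_id = ids[i], point_index = seq_len(K),
                     time_days = (seq_len(K) - 1) * spec@spacingDays)
    for (j in seq_along(params)) df[[params[j]]] <- V[, j]
    df$state <- states[i, ]
    obs[[i]] <- df
  }
  cohort <- clinicalCohort(do.call(rbind, obs), ranges, parameters = params)
  truth <- data.frame(patient_id = ids, progressor = progressor,
                      stringsAsFactors = FALSE)
  for (k in seq_len(K)) truth[[paste0("state_", k)]] <- states[, k]
  attr(truth, "drift") <- drift
  list(cohort = cohort, truth = truth)
}

#' Simulate mining transactions
#'
#' Simulates a cohort and discretizes each patient's final-point panel into
#' LOW/NORMAL/HIGH item tokens plus the `STATE=<s>` item, yielding one
#' transaction per patient for the mining phase.
#'
#' @inheritParams simulateCohort
#' @return a [TransactionSet-class] of `nPatients` transactions.
#' @export
simulateTransactions <- function(spec, ranges = defaultRanges()) {
  sim <- simulateCohort(spec, ranges)
  cohortTransactions(sim$cohort, point = "last")
}

#' Calibrated recovery experiment on synthetic cohorts
#'
#' The package's end-to-end evaluation of the SN predictor under known
#' ground truth. A fully labelled calibration cohort is simulated from the
#' same specification (seed offset by `calibOffset`), the decision
#' threshold is calibrated on its final-point differential areas, and the
#' evaluation cohort's final-point states — treated as hidden — are then
#' predicted with all earlier states observed, mirroring a study whose
#' last follow-up awaits imaging confirmation.
#'
#' @param spec a [CohortSpec-class] describing both cohorts.
#' @param ranges reference ranges.
#' @param calibOffset seed offset for the calibration cohort.
#' @return list with `theta`, `accuracy` (fraction of hidden final-point
#'   states recovered), `n` (patients scored) and the per-patient
#'   `predictions` table.
#' @export
snRecoveryExperiment <- function(spec, ranges = defaultRanges(),
                                 calibOffset = 500000L) {
  quartet <- c("creatinine", "bun", "sgot", "sgpt")
  K <- spec@nPoints
  calibSpec <- spec
  calibSpec@seed <- spec@seed + as.integer(calibOffset)
  calib <- simulateCohort(calibSpec, ranges)
  da <- vapply(patientIDs(calib$cohort), function(id) {
    differentialArea(patientSeries(calib$cohort, id), K,
                     parameters = quartet)$dA
  }, numeric(1))
  persisted <- calib$truth[[paste0("state_", K)]] ==
    calib$truth[[paste0("state_", K - 1L)]]
  theta <- calibrateThreshold(da, persisted)

  ev <- simulateCohort(spec, ranges)
  preds <- predictCohort(ev$cohort, theta, parameters = quartet,
                         useObserved = TRUE)
  last <- preds[ave(seq_len(nrow(preds)), preds$patient_id,
                    FUN = max) == seq_len(nrow(preds)), , drop = FALSE]
  truthK <- ev$truth[[paste0("state_", K)]][
    match(last$patient_id, ev$truth$patient_id)]
  list(theta = theta,
       accuracy = mean(last$predicted_state == truthK),
       n = nrow(last), predictions = preds)
}
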