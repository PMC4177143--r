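test_that("simulation is seed-deterministic and shape-correct", {
  s1 <- simulateCohort(cohortSpec(nPatients = 8, seed = 4))
  s2 <- simulateCohort(cohortSpec(nPatients = 8, seed = 4))
  expect_identical(observations(s1$cohort), observations(s2$cohort))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateCohort(cohortSpec(nPatients = 8, seed = 5))
  expect_false(identical(observations(s1$cohort), observations(s3$cohort)))
  tx <- simulateTransactions(cohortSpec(nPatients = 12, seed = 1))
  expect_length(tx, 12)
})

test_that("noiseless stable cohorts are exactly collinear (dA ~ 0)", {
  sim <- simulateCohort(cohortSpec(nPatients = 15, noiseSd = 0,
                                   progressionFraction = 0, seed = 31),
                        ranges = wideRanges())
  for (id in patientIDs(sim$cohort)) {
    s <- patientSeries(sim$cohort, id)
    for (k in 2:3)  # exact collinearity up to float cancellation in the Gram root
      expect_lt(differentialArea(s, k, parameters = snQuartet)$dA, 1e-7)
  }
})

test_that("noiseless progressor dA equals driftStep * effectSize analytically", {
  spec <- cohortSpec(nPatients = 15, noiseSd = 0, progressionFraction = 1,
                     effectSize = 1.7, driftStep = 0.25, seed = 13)
  sim <- simulateCohort(spec, ranges = wideRanges())
  for (id in patientIDs(sim$cohort)) {
    s <- patientSeries(sim$cohort, id)
    expect_equal(differentialArea(s, 3, parameters = snQuartet)$dA,
                 0.25 * 1.7, tolerance = 1e-9)
  }
})

test_that("states start at 1 and increment at the transition point", {
  spec <- cohortSpec(nPatients = 30, transitionPoint = 2, nPoints = 4,
                     seed = 6)
  sim <- simulateCohort(spec)
  tr <- sim$truth
  expect_true(all(tr$state_1 == 1L))
  expect_true(all(tr$state_2[tr$progressor] == 2L))
  expect_true(all(tr$state_4[tr$progressor] == 2L))
  expect_true(all(tr$state_4[!tr$progressor] == 1L))
  obs <- observations(sim$cohort)
  expect_true(all(obs$state %in% c(1L, 2L)))
  # panel values are positive clinical concentrations
  for (p in panelParameters(sim$cohort)) expect_true(all(obs[[p]] > 0))
})

test_that("mean normalized drift per interval matches the configured step", {
  spec <- cohortSpec(nPatients = 1000, nPoints = 3, noiseSd = 0.1,
                     progressionFraction = 0, seed = 20)
  sim <- simulateCohort(spec, ranges = wideRanges())
  drift <- attr(sim$truth, "drift")
  obs <- observations(sim$cohort)
  proj <- numeric(0)
  mid <- 200; hw <- 100  # wideRanges geometry
  for (i in seq_len(spec@nPatients)) {
    rows <- obs[obs$patient_id == sim$truth$patient_id[i], snQuartet]
    X <- (as.matrix(rows) - mid) / hw
    inc <- diff(X)
    proj <- c(proj, as.numeric(inc %*% drift[i, ]))
  }
  se <- sd(proj) / sqrt(length(proj))
  expect_lt(abs(mean(proj) - spec@driftStep), 3 * se)
})

test_that("discretized simulations behave at the extremes", {
  # tight, centred, noiseless cohort: every analyte item NORMAL
  spec <- cohortSpec(nPatients = 10, noiseSd = 0, baselineSd = 0,
                     driftStep = 0.05, progressionFraction = 0, seed = 2)
  tx <- simulateTransactions(spec)
  for (items in transactionItems(tx)) {
    labs <- grep("^STATE=", items, value = TRUE, invert = TRUE)
    expect_true(all(grepl("=NORMAL$", labs)))
  }
  # large effect: progressing patients leave the reference interval, so
  # STATE=2 transactions carry at least one non-NORMAL analyte item
  spec2 <- cohortSpec(nPatients = 20, noiseSd = 0, effectSize = 5,
                      progressionFraction = 1, seed = 2)
  tx2 <- simulateTransactions(spec2)
  for (items in transactionItems(tx2)) {
    expect_true("STATE=2" %in% items)
    labs <- grep("^STATE=", items, value = TRUE, invert = TRUE)
    expect_true(any(!grepl("=NORMAL$", labs)))
  }
})
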