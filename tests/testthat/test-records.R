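test_that("normalization is the stated affine map onto reference units", {
  rng <- defaultRanges()
  # hand arithmetic: (1.8 - 0.9) / 0.3 = 3.0
  expect_equal(unname(normalizePanel(c(creatinine = 1.8), rng)), 3.0)
  # interval endpoints map to -1 / +1, midpoint to 0
  expect_equal(unname(normalizePanel(c(bun = 20), rng)), 1)
  expect_equal(unname(normalizePanel(c(bun = 7), rng)), -1)
  expect_equal(unname(normalizePanel(c(bun = 13.5), rng)), 0)
  # affine and order-preserving per parameter
  v <- sort(runif(25, 0, 200))
  z <- vapply(v, function(x) normalizePanel(c(sgot = x), rng)[[1]], numeric(1))
  expect_true(all(diff(z) > 0))
  fit <- lm(z ~ v)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("discretization uses the closed-interval NORMAL convention and matches normalization", {
  rng <- defaultRanges()
  expect_equal(unname(discretizePanel(c(creatinine = 0.6), rng)), "NORMAL")
  expect_equal(unname(discretizePanel(c(creatinine = 1.2), rng)), "NORMAL")
  expect_equal(unname(discretizePanel(c(creatinine = 1.8), rng)), "HIGH")
  panel <- c(creatinine = 0.9, bun = 12, sgot = 30, sgpt = 25,
             haemoglobin = 14)
  expect_true(all(discretizePanel(panel, rng) == "NORMAL"))
  # consistency: HIGH <=> normalized > 1, LOW <=> normalized < -1
  set.seed(42)
  for (i in 1:200) {
    p <- c(creatinine = runif(1, 0, 3), bun = runif(1, 0, 50),
           sgpt = runif(1, 0, 150))
    z <- normalizePanel(p, rng); d <- discretizePanel(p, rng)
    expect_identical(unname(d == "HIGH"), unname(z > 1))
    expect_identical(unname(d == "LOW"), unname(z < -1))
  }
  expect_error(normalizePanel(c(unknown = 1), rng), "no reference range")
})

test_that("cohort read/write round trip preserves every field", {
  sim <- simulateCohort(cohortSpec(nPatients = 6, seed = 9))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeCohort(sim$cohort, f1)
  back <- readCohort(f1, refRanges(sim$cohort))
  writeCohort(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(observations(back)$creatinine,
               observations(sim$cohort)$creatinine, tolerance = 1e-12)
  # simulated 55 x 3 manifest: 55 series, each of length 3
  big <- simulateCohort(cohortSpec(seed = 2))$cohort
  expect_length(patientIDs(big), 55)
  expect_true(all(table(observations(big)$patient_id) == 3))
})

test_that("validation reports offending rows and columns instead of dropping them", {
  rng <- defaultRanges()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,point_index,creatinine",
               "P1,1,0.9", "P1,2,NA", "P1,3,1.0"), f)
  expect_error(readCohort(f, rng), "row\\(s\\) 2")
  writeLines(c("patient_id,point_index,creatinine",
               "P1,1,0.9", "P1,1,1.0"), f)
  expect_error(readCohort(f, rng), "duplicate \\(patient_id, point_index\\)")
  writeLines(c("patient_id,creatinine", "P1,0.9"), f)
  expect_error(readCohort(f, rng), "missing mandatory column")
  # unit time spacing assumed when time_days is absent
  writeLines(c("patient_id,point_index,creatinine",
               "P1,1,0.9", "P1,2,1.0", "P1,3,1.1"), f)
  co <- readCohort(f, rng)
  expect_equal(observations(co)$time_days, c(0, 1, 2))
})
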