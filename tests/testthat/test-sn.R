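test_that("wedge area matches its closed-form special cases", {
  expect_equal(wedgeArea(c(1, 0), c(0, 1)), 1)
  expect_equal(wedgeArea(c(1, 2, 3, 4), 3 * c(1, 2, 3, 4)), 0)
  # p = 2: absolute 2x2 determinant
  set.seed(3)
  for (i in 1:100) {
    dx <- rnorm(2); dy <- rnorm(2)
    expect_equal(wedgeArea(dx, dy), abs(dx[1] * dy[2] - dx[2] * dy[1]),
                 tolerance = 1e-12)
  }
  # symmetry and sign-flip invariance
  dx <- rnorm(4); dy <- rnorm(4)
  expect_equal(wedgeArea(dx, dy), wedgeArea(dy, dx))
  expect_equal(wedgeArea(-dx, -dy), wedgeArea(dx, dy))
  expect_error(wedgeArea(c(1, 2), c(1, 2, 3)), "same dimension")
  expect_error(wedgeArea(1, 2), "dimension >= 2")
})

test_that("derivative vectors are finite differences with a baseline anchor", {
  X <- rbind(c(0.5, 0.2, 0.1, 0.0),
             c(1.1, 0.2, 0.3, 0.4),
             c(1.1, 0.2, 0.3, 0.4))
  s <- makeSeries(X, times = c(0, 30, 60))
  # k = 1: normalized values themselves, dt = 1
  j1 <- derivativeAt(s, 1)
  expect_equal(unname(j1$components), X[1, ])
  expect_equal(j1$dt, 1)
  # k = 2: (1.1 - 0.5) / 30 = 0.02 on the first analyte
  j2 <- derivativeAt(s, 2)
  expect_equal(unname(j2$components[1]), 0.02)
  expect_equal(j2$dt, 30)
  # constant panel across points -> zero vector
  expect_equal(unname(derivativeAt(s, 3)$components), rep(0, 4))
  # midpoint baseline normalizes to the zero vector
  s0 <- makeSeries(rbind(rep(0, 4), rep(0.1, 4)))
  expect_equal(unname(derivativeAt(s0, 1)$components), rep(0, 4))
  expect_error(derivativeAt(s, 5), "out of range")
  bad <- makeSeries(X, times = c(0, 30, 30))
  expect_error(derivativeAt(bad, 3), "non-positive time increment")
})

test_that("differential area detects direction change, not speed or time units", {
  # identical trend over both intervals -> collinear -> dA = 0
  X <- rbind(c(0.1, 0.1, 0.1, 0.1), c(0.2, 0.2, 0.2, 0.2),
             c(0.3, 0.3, 0.3, 0.3))
  expect_equal(differentialArea(makeSeries(X), 3)$dA, 0)
  # orthogonal two-parameter jump: dA is the product of the change sizes
  Y <- rbind(c(0, 0), c(0.4, 0), c(0.4, 0.7))
  expect_equal(differentialArea(makeSeries(Y), 3)$dA, 0.4 * 0.7)
  # doubling both time increments with fixed raw changes leaves dA unchanged
  a <- differentialArea(makeSeries(Y, times = c(0, 10, 20)), 3)$dA
  b <- differentialArea(makeSeries(Y, times = c(0, 20, 40)), 3)$dA
  expect_equal(a, b)
  # p = 4 random pairs agree with the Gram-determinant oracle
  set.seed(21)
  for (i in 1:100) {
    dx <- rnorm(4); dy <- rnorm(4)
    expect_equal(wedgeArea(dx, dy), oracleGramArea(dx, dy),
                 tolerance = 1e-12)
  }
})

test_that("state decision persists below threshold and progresses above", {
  expect_equal(predictState(1L, 0, 0.5)$predicted_state, 1L)
  expect_equal(predictState(2L, 0.50, 0.5)$predicted_state, 2L)  # boundary persists
  expect_equal(predictState(1L, 0.51, 0.5)$predicted_state, 2L)
  expect_error(predictState(1L, 0.1, -1), "theta")
})

test_that("threshold calibration: midpoint when separable, minimal error otherwise", {
  expect_equal(calibrateThreshold(c(0.1, 0.2, 0.8), c(TRUE, TRUE, FALSE)), 0.5)
  expect_equal(calibrateThreshold(c(0.1, 0.3), c(TRUE, TRUE)), 0.3)
  set.seed(99)
  for (i in 1:50) {
    dA <- runif(sample(3:25, 1))
    persisted <- runif(length(dA)) < 0.6
    if (all(persisted) || !any(persisted)) next
    th <- calibrateThreshold(dA, persisted)
    err <- function(t) sum(persisted & dA > t) + sum(!persisted & dA <= t)
    expect_equal(err(th), err(oracleCutpoint(dA, persisted)))
    # ties break toward the smallest theta among observed cut points
    # (the separable case instead takes the class-gap midpoint)
    if (max(dA[persisted]) >= min(dA[!persisted]))
      expect_lte(th, oracleCutpoint(dA, persisted) + 1e-9)
  }
  expect_error(calibrateThreshold(numeric(), logical()), "at least one")
})

test_that("series prediction follows the anchor-and-walk contract", {
  flat <- makeSeries(rbind(c(0.1, 0.1, 0.1, 0.1), c(0.2, 0.2, 0.2, 0.2),
                           c(0.3, 0.3, 0.3, 0.3)))
  p <- predictSeries(flat, theta = 0.05, anchor = 1L)
  expect_equal(p$predicted_state, c(1L, 1L))
  # two-point series -> exactly one prediction, for point 2
  two <- makeSeries(rbind(c(0, 0, 0, 0), c(0.5, 0, 0, 0)))
  p2 <- predictSeries(two, theta = 0, anchor = 2L)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$point_index, 2L)
  expect_error(predictSeries(two[1, , drop = FALSE], 0.1, 1L),
               "at least 2")
  # theta at or above the max dA makes every prediction persist
  set.seed(5)
  X <- matrix(rnorm(20, sd = 0.3), 5, 4)
  s <- makeSeries(X)
  das <- vapply(2:5, function(k) differentialArea(s, k)$dA, numeric(1))
  pAll <- predictSeries(s, theta = max(das), anchor = 1L)
  expect_true(all(pAll$predicted_state == 1L))
})

test_that("predictions are causal and shrink monotonically with theta", {
  set.seed(17)
  for (rep in 1:10) {
    X <- matrix(rnorm(6 * 4, sd = 0.4), 6, 4)
    s <- makeSeries(X)
    full <- predictSeries(s, theta = 0.2, anchor = 1L)
    # prefix property: truncating the series never changes earlier predictions
    for (m in 2:5) {
      head_m <- predictSeries(s[seq_len(m), , drop = FALSE], 0.2, 1L)
      expect_equal(head_m, full[seq_len(m - 1L), , drop = FALSE],
                   ignore_attr = TRUE)
    }
    # progression calls weakly shrink as theta grows
    thetas <- sort(runif(5, 0, 1))
    calls <- vapply(thetas, function(th)
      sum(diff(c(1L, predictSeries(s, th, 1L)$predicted_state)) > 0),
      numeric(1))
    expect_true(all(diff(calls) <= 0))
  }
})
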