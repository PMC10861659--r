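test_that("superposed oral curve matches a numerically integrated ODE", {
  p <- PKParameters(ka = 1.0, ke = 0.1, vOverF = 1, fAbs = 1,
                    fUrine = 0.5, fFaeces = 0.2,
                    incorporationCoeff = 0, bsvSigma = 0)
  ## independent oracle: gut/central two-state ODE, D/V = 1000 ng/mL
  ode <- deSolve::lsoda(
    y = c(gut = 1000, central = 0),
    times = c(0, 2, 5, 12),
    func = function(t, y, parms)
      list(c(-1.0 * y["gut"], 1.0 * y["gut"] - 0.1 * y["central"])))
  for (i in 2:4) {
    t <- ode[i, "time"]
    expect_equal(plasmaConcentration(p, 1, 0, t),
                 unname(ode[i, "central"]), tolerance = 1e-3)
  }
  expect_equal(plasmaConcentration(p, 1, doseTimesH = 10, tH = 5), 0)
  expect_error(plasmaConcentration(
    PKParameters(ka = 0.2, ke = 0.1), 1, 0, 1) , NA)
  p2 <- p; p2@ka <- p2@ke
  expect_error(plasmaConcentration(p2, 1, 0, 1), "degenerate")
})

test_that("day-7 curve is positive and unimodal over the dense grid", {
  p <- PKParameters(ka = 1.2, ke = 0.25, vOverF = 2)
  doses <- 24 * (1:7)
  tau <- c(0.5, 0.75, 1, 1.5, 3, 6, 9, 12)
  cc <- plasmaConcentration(p, 2, doses, 168 + tau)
  expect_true(all(cc > 0))
  d <- diff(cc)
  expect_lte(sum(diff(sign(d)) != 0), 1)  # at most one turning point
})

test_that("noise-free curves scale exactly with dose", {
  p <- PKParameters(ka = 1.2, ke = 0.25, vOverF = 2)
  doses <- 24 * (1:7)
  t <- 168 + c(0.5, 3, 12)
  expect_equal(plasmaConcentration(p, 2, doses, t),
               2 * plasmaConcentration(p, 1, doses, t))
  expect_equal(plasmaConcentration(p, 4, doses, t),
               4 * plasmaConcentration(p, 1, doses, t))
})

test_that("interval excretion matches quadrature of the elimination flux", {
  p <- PKParameters(ka = 1.2, ke = 0.1, vOverF = 2, fAbs = 0.6,
                    fUrine = 0.3, fFaeces = 0.3)
  D <- 5e5  # ng
  ## before any dose
  expect_equal(excretionInterval(p, 24, D, c(0, 12), "urine"), 0)
  ## single dose, infinite horizon: conservation
  expect_equal(excretionInterval(p, 0, D, c(0, 1e7), "urine"),
               0.3 * 0.6 * D, tolerance = 1e-9)
  ## (0, 24): against the stated closed form and against quadrature
  amt <- excretionInterval(p, 0, D, c(0, 24), "urine")
  expect_equal(amt, 0.3 * 0.6 * D * (1 - exp(-2.4)), tolerance = 1e-12)
  quad <- integrate(function(t) 0.3 * 0.1 * 0.6 * D * exp(-0.1 * t),
                    0, 24)$value
  expect_equal(amt, quad, tolerance = 1e-6)
  expect_error(excretionInterval(p, 0, D, c(5, 5), "urine"), "a < b")
})

test_that("faeces receives the lagged unabsorbed fraction", {
  p <- PKParameters(ka = 1.2, ke = 0.1, vOverF = 2, fAbs = 0.6,
                    fUrine = 0.3, fFaeces = 0.3)
  D <- 1e5
  ## dose at t = 10; transit lag 24 h puts the unabsorbed 40% into the
  ## interval whose (a-24, b-24] window covers t = 10
  with_lag <- excretionInterval(p, 10, D, c(24, 48), "faeces")
  eliminated <- excretionInterval(p, 10, D, c(24, 48), "urine")
  expect_equal(with_lag - eliminated, 0.4 * D, tolerance = 1e-9)
})

test_that("mass balance closes over an infinite horizon", {
  p <- PKParameters(ka = 1.2, ke = 0.15, vOverF = 2, fAbs = 0.6,
                    fUrine = 0.3, fFaeces = 0.3)
  D <- 1e6
  doses <- 24 * (1:7)
  horizon <- c(0, 5000)
  total <- excretionInterval(p, doses, D, horizon, "urine") +
    excretionInterval(p, doses, D, horizon, "faeces")
  expect_equal(total,
               7 * D * (0.6 * (0.3 + 0.3) + (1 - 0.6)),
               tolerance = 0.005)
})

test_that("hair deposition is mean-one lognormal around coeff * AUC", {
  p0 <- PKParameters(incorporationCoeff = 0.42, bsvSigma = 0)
  expect_equal(simulateHair(p0, 0), 0)
  expect_equal(simulateHair(p0, 100), 42)
  p <- PKParameters(incorporationCoeff = 0.42, bsvSigma = 0.2)
  set.seed(99)
  draws <- simulateHair(p, rep(100, 1e4)) / 100
  se <- sd(draws) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 0.42), 3 * se)
})

test_that("simulated studies are reproducible and degrade gracefully", {
  panel <- modelPanel()["anastrozole", , drop = FALSE]
  design <- StudyDesign(groupSizes = c(vehicle = 2L, half = 2L,
                                       one = 2L, two = 2L))
  a <- simulateStudy(panel, design, seed = 42)
  b <- simulateStudy(panel, design, seed = 42)
  expect_identical(concentrations(a), concentrations(b))
  expect_identical(calibrationSamples(a), calibrationSamples(b))

  ## near-noise-free settings: measured plasma tracks the model curve
  quiet <- MeasurementModel(proportionalCV = 0, calibrationCV = 0,
                            blankSD = 1e-9)
  s <- simulateStudy(panel, design, meas = quiet, seed = 1)
  cc <- concentrations(s)
  pl <- cc[cc$matrix == "plasma" & cc$group == "two" & !cc$censored, ]
  expect_equal(pl$value, pl$true_value, tolerance = 1e-6)

  ## vehicle group is blank noise only
  veh <- concentrations(a)[concentrations(a)$group == "vehicle", ]
  expect_true(all(veh$true_value == 0))
  expect_true(all(abs(veh$response) < 6 * a@measurement@blankSD))

  ## calibration design: 15 levels spanning 0.01-500 per matrix
  cal <- calibrationSamples(a)
  lv <- sort(unique(cal$nominal[cal$role == "calibrator"]))
  expect_length(lv, 15L)
  expect_equal(range(lv), c(0.01, 500))

  expect_error(simulateStudy(panel, design, pkMap = list()),
               "no PKParameters")
})
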