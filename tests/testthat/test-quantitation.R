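test_that("an exact line is fitted exactly", {
  s <- data.frame(nominal = 1:8, response = 2 * (1:8) + 0.1)
  cv <- fitCalibration(s)
  expect_equal(cv@slope, 2)
  expect_equal(cv@intercept, 0.1)
  expect_equal(cv@rSquared, 1)
  expect_true(cv@accepted)
  expect_error(fitCalibration(s[1:5, ]), "six")
  z <- data.frame(nominal = rep(2, 8), response = rnorm(8, 4, 0.1))
  expect_error(fitCalibration(z), "zero variance")
})

test_that("LOD follows the S/N >= 3 rule and is monotone in blank SD", {
  blanks <- c(-0.01, 0.01, 0.005, -0.005, 0.008, -0.008)  # SD ~ 0.01
  lv <- data.frame(nominal = c(0.1, 1), meanResponse = c(0.005, 0.05))
  expect_equal(as.numeric(estimateLOD(blanks, lv)), 1)
  ## nothing qualifies -> Inf sentinel with flag
  weak <- data.frame(nominal = c(0.1, 1),
                     meanResponse = c(0.001, 0.002))
  lod <- estimateLOD(blanks, weak)
  expect_identical(as.numeric(lod), Inf)
  expect_false(attr(lod, "detectable"))
  expect_error(estimateLOD(blanks[1:2], lv), "3 blank")

  ## doubling the blank noise never lowers the LOD
  set.seed(5)
  for (i in 1:20) {
    lvs <- data.frame(nominal = sort(runif(8, 0.01, 10)),
                      meanResponse = sort(runif(8, 0, 0.2)))
    b <- rnorm(6, 0, 0.01)
    expect_gte(as.numeric(estimateLOD(2 * b, lvs)),
               as.numeric(estimateLOD(b, lvs)))
  }
})

test_that("back-calculation inverts the fit and honours boundaries", {
  s <- data.frame(nominal = exp(seq(log(0.01), log(500), length.out = 15)))
  s$response <- 2 * s$nominal
  cv <- fitCalibration(s)
  set.seed(7)
  conc <- runif(20, 0.01, 500)
  bc <- backCalculate(cv, 2 * conc)
  expect_equal(bc$conc, conc, tolerance = 1e-9)
  expect_false(any(bc$extrapolated))
  ## exactly at the top of the range: not extrapolated; just above: is
  expect_false(backCalculate(cv, 2 * 500)$extrapolated)
  expect_true(backCalculate(cv, 2 * 501)$extrapolated)
  ## at the intercept: zero, censored
  at0 <- backCalculate(cv, 0)
  expect_equal(at0$conc, 0)
  expect_true(at0$censored)
  neg <- backCalculate(cv, -1)
  expect_equal(neg$conc, 0)
  expect_true(neg$censored)
})

test_that("blank-aware fitting drops sub-LOD levels and flags poor r2", {
  set.seed(21)
  s <- syntheticCalSamples(slope = 0.02, cv = 0.05, blankSD = 5e-4)
  cv <- fitCalibration(s)
  expect_gte(cv@nLevelsUsed, 6L)
  expect_equal(cv@linearRange[1], cv@lod)
  expect_equal(cv@linearRange[2], 500)
  expect_true(all(cv@levels$nominal >= cv@lod))

  ## gross curvature trips the linearity flag
  bad <- data.frame(nominal = 1:10, response = (1:10)^2)
  expect_false(fitCalibration(bad)@accepted)
})

test_that("quantification censors consistently and idempotently", {
  st <- recoveryStudy(0.42, seed = 31)
  q <- quantifyStudy(st)
  cc <- concentrations(q)
  expect_true(all(cc$value[cc$censored] == 0))
  expect_true(all(cc$value >= 0))
  ## records censored at measurement stay censored after quantification
  raw <- concentrations(st)
  expect_true(all(cc$censored[raw$censored]))
  ## every curve used at least six levels and a positive slope
  for (curve in calibrationCurves(q)) {
    expect_gte(curve@nLevelsUsed, 6L)
    expect_gt(curve@slope, 0)
  }
})
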