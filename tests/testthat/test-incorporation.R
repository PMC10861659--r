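test_that("the degree is hair over AUC, undefined when either is missing", {
  expect_equal(computeDegree(4.2, 10), 0.42)
  expect_true(is.na(computeDegree(4.2, 10, hairCensored = TRUE)))
  expect_true(is.na(computeDegree(4.2, NA)))
  expect_true(is.na(computeDegree(4.2, 0)))       # AUC must be positive
  expect_true(is.na(computeDegree(4.2, 10, aucMissing = TRUE)))
  ## boundary: hair exactly at LOD still yields a value
  expect_equal(computeDegree(0.15, 1), 0.15)
  ## vectorized with mixed validity
  v <- computeDegree(c(1, 2, 3), c(10, 0, 10),
                     hairCensored = c(FALSE, FALSE, TRUE))
  expect_equal(v, c(0.1, NA, NA))
})

test_that("group summaries use the sample SD over sqrt(n)", {
  gs <- groupSummary(c(2, 4))
  expect_equal(gs$mean, 3)
  expect_equal(gs$sem, 1)
  expect_equal(gs$n, 2L)
  one <- groupSummary(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sem))
  expect_error(groupSummary(c(NA_real_, NA_real_)), "no calculable")
})

test_that("degrees are dose-independent under linear kinetics", {
  ## noise-free: every animal in every dose group recovers the same degree
  quiet <- MeasurementModel(proportionalCV = 0, calibrationCV = 0,
                            blankSD = 1e-9)
  pk <- list(furosemide = PKParameters(ka = 1.2, ke = 0.25, vOverF = 2,
                                       fAbs = 0.6, fUrine = 0.3,
                                       fFaeces = 0.3,
                                       incorporationCoeff = 0.42,
                                       bsvSigma = 0))
  design <- StudyDesign(groupSizes = c(vehicle = 0L, half = 3L,
                                       one = 3L, two = 3L))
  st <- simulateStudy(modelPanel()["furosemide", , drop = FALSE],
                      design, pk, meas = quiet, seed = 3)
  inc <- incorporationResults(quantifyStudy(st))
  expect_equal(inc$mean_half, inc$mean_one, tolerance = 1e-6)
  expect_equal(inc$mean_one, inc$mean_two, tolerance = 1e-6)
  expect_equal(inc$mean, 0.42, tolerance = 1e-6)
  ## pooled mean equals mean of group means at equal group sizes
  expect_equal(inc$mean,
               mean(c(inc$mean_half, inc$mean_one, inc$mean_two)),
               tolerance = 1e-9)
})

test_that("n reports animals actually used", {
  st <- recoveryStudy(0.42, seed = 13)
  q <- quantifyStudy(st)
  inc <- incorporationResults(q)
  cc <- concentrations(q)
  hairOK <- cc[cc$matrix == "hair" & cc$day == 28 &
               cc$group != "vehicle" & !cc$censored, ]
  expect_lte(inc$n, nrow(hairOK))
  expect_gte(inc$n, 1L)
})

test_that("detection grids shrink monotonically as LODs rise", {
  st <- simulateStudy(modelPanel()[c("furosemide", "terbutaline"), ],
                      StudyDesign(groupSizes = c(vehicle = 1L, half = 2L,
                                                 one = 2L, two = 2L)),
                      seed = 23)
  q <- quantifyStudy(st)
  g0 <- buildDetectionGrid(q)
  ## hair-negative substance (coeff 0) never appears in hair
  expect_false(g0$grid$detected[g0$grid$substance == "terbutaline" &
                                g0$grid$matrix == "hair"])
  lowered <- g0$counts
  raised <- buildDetectionGrid(q, lods = c(plasma = 1e6, urine = 1e6,
                                           faeces = 1e6, hair = 1e6))
  expect_true(all(raised$counts <= lowered))
  expect_true(all(raised$counts == 0))
  ## all-censored study: zero counts
  cc <- concentrations(q)
  cc$censored <- TRUE; cc$value <- 0
  expect_true(all(buildDetectionGrid(cc)$counts == 0))
})
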