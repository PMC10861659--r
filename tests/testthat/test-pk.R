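## closed-form AUC of the superposed one-compartment curve over
## (start, start + width), written independently of the package
closedFormAUC <- function(ka, ke, scale, doseTimes, start, width) {
  sum(vapply(doseTimes[doseTimes <= start], function(ti) {
    a <- start - ti; b <- a + width
    scale * ((exp(-ke * a) - exp(-ke * b)) / ke -
             (exp(-ka * a) - exp(-ka * b)) / ka)
  }, numeric(1)))
}

test_that("trapezoidal AUC is exact for constants and near-exact on the day-7 grid", {
  expect_equal(aucTrapezoid(c(0, 12), c(5, 5)), 60)
  expect_error(aucTrapezoid(0, 1), "two points")
  expect_error(aucTrapezoid(c(2, 1), c(1, 1)), "increasing")

  p <- PKParameters(ka = 1.2, ke = 0.25, vOverF = 2)
  doses <- 24 * (1:7)
  grid <- c(0, 0.5, 0.75, 1, 1.5, 3, 6, 9, 12)
  cc <- plasmaConcentration(p, 2, doses, 168 + grid)
  est <- aucTrapezoid(grid, cc)
  truth <- closedFormAUC(1.2, 0.25, 1000 * 2 * 1.2 / (2 * (1.2 - 0.25)),
                         doses, 168, 12)
  expect_equal(est, truth, tolerance = 0.05)

  ## refining the grid 10x shrinks the error
  fine <- seq(0, 12, length.out = 10 * length(grid))
  estFine <- aucTrapezoid(fine, plasmaConcentration(p, 2, doses, 168 + fine))
  expect_lt(abs(estFine - truth), abs(est - truth))

  ## additivity over contiguous intervals
  t1 <- grid[grid <= 3]; t2 <- grid[grid >= 3]
  expect_equal(aucTrapezoid(t1, cc[grid <= 3]) +
               aucTrapezoid(t2, cc[grid >= 3]), est)

  ## censored points contribute zero
  cens <- rep(FALSE, length(grid)); cens[length(grid)] <- TRUE
  expect_lt(aucTrapezoid(grid, cc, cens), est)
})

test_that("detection windows report the last detectable collection day", {
  expect_identical(detectionWindow(c(0, 7, 10), c(0, 0, 0),
                                   rep(TRUE, 3), 1), NA_integer_)
  expect_identical(detectionWindow(c(0, 7, 10, 14), c(0, 5, 2, 0),
                                   c(TRUE, FALSE, FALSE, TRUE), 1), 10L)
  ## monotone in elimination rate: slower clearance, window at least as long
  design <- StudyDesign(groupSizes = c(vehicle = 0L, half = 0L,
                                       one = 5L, two = 0L))
  panel <- modelPanel()["clenbuterol", , drop = FALSE]
  win <- sapply(c(slow = 0.02, fast = 0.3), function(ke) {
    pk <- list(clenbuterol = PKParameters(ka = 1.2, ke = ke, vOverF = 2,
                                          incorporationCoeff = 0.11,
                                          bsvSigma = 0))
    q <- quantifyStudy(simulateStudy(panel, design, pk, seed = 8))
    g <- buildDetectionGrid(q)
    g$grid$last_detected_day[g$grid$matrix == "plasma"]
  })
  expect_gte(win["slow"], win["fast"])
})

test_that("dose linearity recovers the power slope", {
  fit <- doseLinearity(c(1, 2, 4), c(10, 20, 40))
  expect_equal(fit$power_slope, 1, tolerance = 1e-12)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  flat <- doseLinearity(c(1, 2, 4), c(7, 7, 7))
  expect_equal(flat$power_slope, 0, tolerance = 1e-12)
  degen <- doseLinearity(c(1, 2, 4), c(0, 10, 20))
  expect_true(degen$flagged)
  expect_true(is.na(degen$power_slope))
  expect_error(doseLinearity(c(1, 2), c(1, 2)), ">= 3")
})

test_that("simulated plasma AUC is dose-linear through the pipeline", {
  ## 40 replicate studies would be slow; one moderate study suffices to
  ## check the slope is near 1 on group-mean AUCs
  st <- recoveryStudy(0.42, seed = 17)
  q <- quantifyStudy(st)
  pk <- pkSummaries(q)
  gm <- tapply(pk$auc_0_12, pk$dose_group, mean, na.rm = TRUE)
  fit <- doseLinearity(c(1, 2, 4), as.numeric(gm[c("half", "one", "two")]))
  expect_equal(fit$power_slope, 1, tolerance = 0.15)
  expect_gt(fit$pearson_r, 0.99)
})
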