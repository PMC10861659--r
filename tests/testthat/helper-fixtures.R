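## Shared fixture builders. Everything is generated in code; no files.

## single-substance recovery study: 3 treated dose groups of 10
recoveryStudy <- function(coeff, ke = 0.25, seed = 1,
                          meas = MeasurementModel(), bsvSigma = 0.2) {
  panel <- modelPanel()["furosemide", , drop = FALSE]
  pk <- list(furosemide = PKParameters(
    ka = 1.2, ke = ke, vOverF = 2, fAbs = 0.6, fUrine = 0.3,
    fFaeces = 0.3, incorporationCoeff = coeff, bsvSigma = bsvSigma))
  design <- StudyDesign(groupSizes = c(vehicle = 0L, half = 10L,
                                       one = 10L, two = 10L))
  simulateStudy(panel, design, pk, meas = meas, seed = seed)
}

recoveredMean <- function(coeff, ke = 0.25, seed = 1,
                          meas = MeasurementModel()) {
  st <- recoveryStudy(coeff, ke, seed, meas)
  incorporationResults(quantifyStudy(st))$mean[1]
}

## 15-level calibration samples with proportional noise, plus blanks
syntheticCalSamples <- function(slope = 0.02, cv = 0.05, blankSD = 1e-4,
                                nBlanks = 6) {
  lv <- exp(seq(log(0.01), log(500), length.out = 15))
  data.frame(
    nominal = c(lv, rep(0, nBlanks)),
    response = c(slope * lv * (1 + cv * rnorm(15)),
                 rnorm(nBlanks, 0, blankSD)),
    role = c(rep("calibrator", 15), rep("blank", nBlanks)))
}

## tiny linearly separated toy set for forest sanity checks
toyDescriptors <- function(n = 8) {
  x <- data.frame(f1 = c(seq(1, 4, length.out = n / 2),
                         seq(7, 10, length.out = n / 2)),
                  f2 = rep(c(0, 1), each = n / 2))
  rownames(x) <- paste0("s", seq_len(n))
  x
}
toyLabels <- function(n = 8)
  setNames(rep(c("negative", "positive"), each = n / 2),
           paste0("s", seq_len(n)))
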