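## Constructors, accessors and show methods.

#' Construct a StudyDesign
#'
#' Defaults reproduce the repeated oral-dose rodent design the package
#' emulates: four groups of ten animals (vehicle plus 1, 2 and 4 mg/kg),
#' one gavage every 24 h for 7 days, dense plasma sampling on day 7 at
#' 0.5, 0.75, 1, 1.5, 3, 6, 9 and 12 h post-dose (plus the pre-dose
#' trough), 24-h urine/faeces collections on days 0, 7, 10, 14 and 28,
#' and hair shaved on days 0 and 28.
#'
#' @param doseLevels Named numeric, mg/kg per treated group.
#' @param dosingIntervalH Hours between doses.
#' @param nDoses Number of administrations.
#' @param groupSizes Named integer vector of animals per group.
#' @param plasmaTimesDay7 Hours post-dose for the day-7 plasma grid.
#' @param collectionDays Named list of integer study days per matrix.
#' @param hairHarvestDay Hair harvest study day.
#' @param gavageVolume Gavage volume, mL/kg.
#' @return A \code{\linkS4class{StudyDesign}}.
#' @examples
#' defaultStudyDesign()
#' @export
StudyDesign <- function(doseLevels = c(half = 1, one = 2, two = 4),
                        dosingIntervalH = 24,
                        nDoses = 7L,
                        groupSizes = c(vehicle = 10L, half = 10L,
                                       one = 10L, two = 10L),
                        plasmaTimesDay7 = c(0, 0.5, 0.75, 1, 1.5, 3, 6, 9, 12),
                        collectionDays = list(
                          plasma = c(0L, 7L, 10L, 14L, 28L),
                          urine  = c(0L, 7L, 10L, 14L, 28L),
                          faeces = c(0L, 7L, 10L, 14L, 28L),
                          hair   = c(0L, 28L)),
                        hairHarvestDay = 28L,
                        gavageVolume = 5) {
  new("StudyDesign", doseLevels = doseLevels,
      dosingIntervalH = dosingIntervalH, nDoses = as.integer(nDoses),
      groupSizes = vapply(groupSizes, as.integer, integer(1)),
      plasmaTimesDay7 = plasmaTimesDay7,
      collectionDays = lapply(collectionDays, as.integer),
      hairHarvestDay = as.integer(hairHarvestDay),
      gavageVolume = gavageVolume)
}

#' @rdname StudyDesign
#' @export
defaultStudyDesign <- function() StudyDesign()

#' Construct PKParameters
#'
#' @param ka,ke Absorption and elimination rates, 1/h (ka > ke > 0).
#' @param vOverF Apparent volume V/F, L/kg.
#' @param fAbs Absorbed fraction of the dose.
#' @param fUrine,fFaeces Fractions of the absorbed dose excreted in urine
#'   and faeces.
#' @param incorporationCoeff Hair deposition per unit plasma exposure,
#'   (pg/mg)/(ng·h/mL).
#' @param bsvSigma Between-subject lognormal SD (mean-one) on
#'   incorporation and clearance.
#' @return A \code{\linkS4class{PKParameters}}.
#' @examples
#' PKParameters(ka = 1.2, ke = 0.1, incorporationCoeff = 0.42)
#' @export
PKParameters <- function(ka = 1.2, ke = 0.25, vOverF = 2, fAbs = 0.6,
                         fUrine = 0.3, fFaeces = 0.3,
                         incorporationCoeff = 0.2, bsvSigma = 0.2) {
  new("PKParameters", ka = ka, ke = ke, vOverF = vOverF, fAbs = fAbs,
      fUrine = fUrine, fFaeces = fFaeces,
      incorporationCoeff = incorporationCoeff, bsvSigma = bsvSigma)
}

#' Construct a MeasurementModel
#'
#' @param proportionalCV Proportional CV of study-sample responses.
#' @param calibrationCV Proportional CV of calibrator responses.
#' @param blankSD SD of blank response ratios.
#' @param responseSlope True response ratio per concentration unit.
#' @param lodTruth Generator-side censoring concentration; defaults to
#'   the concentration whose noise-free response equals 3 blank SDs.
#' @param calReplicates Replicate calibrator responses per level.
#' @return A \code{\linkS4class{MeasurementModel}}.
#' @examples
#' MeasurementModel()
#' @export
MeasurementModel <- function(proportionalCV = 0.20, calibrationCV = 0.05,
                             blankSD = 0.001, responseSlope = 0.02,
                             lodTruth = 3 * blankSD / responseSlope,
                             calReplicates = 5L) {
  new("MeasurementModel", proportionalCV = proportionalCV,
      calibrationCV = calibrationCV, blankSD = blankSD,
      responseSlope = responseSlope, lodTruth = lodTruth,
      calReplicates = as.integer(calReplicates))
}

## --- accessors -------------------------------------------------------

#' @describeIn StudyDesign Dose levels (mg/kg) of the treated groups.
#' @param object A StudyDesign.
#' @export
setGeneric("doseLevels", function(object) standardGeneric("doseLevels"))

#' @rdname StudyDesign
#' @export
setMethod("doseLevels", "StudyDesign", function(object) object@doseLevels)

#' @describeIn StudyDesign Collection days per matrix.
#' @export
setGeneric("collectionDays", function(object) standardGeneric("collectionDays"))

#' @rdname StudyDesign
#' @export
setMethod("collectionDays", "StudyDesign",
          function(object) object@collectionDays)

#' Concentration table of a simulated or quantified study
#'
#' @param object A \code{SyntheticStudy} or \code{QuantifiedStudy}.
#' @return Long-format data.frame in the concentration schema.
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))

#' @rdname concentrations
#' @export
setMethod("concentrations", "SyntheticStudy",
          function(object) object@concentrations)

#' @rdname concentrations
#' @export
setMethod("concentrations", "QuantifiedStudy",
          function(object) object@concentrations)

#' Calibration samples emitted by a simulated study
#'
#' @param object A \code{SyntheticStudy}.
#' @return data.frame with columns matrix, analyte, role, nominal,
#'   replicate, response.
#' @export
setGeneric("calibrationSamples",
           function(object) standardGeneric("calibrationSamples"))

#' @rdname calibrationSamples
#' @export
setMethod("calibrationSamples", "SyntheticStudy",
          function(object) object@calibration)

#' Fitted calibration curves of a quantified study
#'
#' @param object A \code{QuantifiedStudy}.
#' @return Named list of \code{CalibrationCurve} objects
#'   ("analyte|matrix").
#' @export
setGeneric("calibrationCurves",
           function(object) standardGeneric("calibrationCurves"))

#' @rdname calibrationCurves
#' @export
setMethod("calibrationCurves", "QuantifiedStudy",
          function(object) object@curves)

#' @describeIn QSARModel Features retained by the variance filter.
#' @param object A QSARModel.
#' @export
setGeneric("retainedFeatures",
           function(object) standardGeneric("retainedFeatures"))

#' @rdname QSARModel
#' @export
setMethod("retainedFeatures", "QSARModel",
          function(object) object@retainedFeatures)

#' @describeIn QSARModel Per-feature applicability-domain ranges.
#' @export
setGeneric("adRanges", function(object) standardGeneric("adRanges"))

#' @rdname QSARModel
#' @export
setMethod("adRanges", "QSARModel", function(object) object@adRanges)

#' @describeIn QSARModel Training-set re-prediction accuracy.
#' @export
setGeneric("trainingAccuracy",
           function(object) standardGeneric("trainingAccuracy"))

#' @rdname QSARModel
#' @export
setMethod("trainingAccuracy", "QSARModel",
          function(object) object@trainingAccuracy)

## --- show methods ----------------------------------------------------

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nDoses, "doses every",
      object@dosingIntervalH, "h\n")
  cat("  dose levels (mg/kg):",
      paste(names(object@doseLevels), object@doseLevels,
            sep = "=", collapse = ", "), "\n")
  cat("  group sizes:",
      paste(names(object@groupSizes), object@groupSizes,
            sep = "=", collapse = ", "), "\n")
  cat("  day-7 plasma grid (h):",
      paste(object@plasmaTimesDay7, collapse = ", "), "\n")
  cat("  hair harvest day:", object@hairHarvestDay, "\n")
})

setMethod("show", "PKParameters", function(object) {
  cat(sprintf(
    "PKParameters: ka=%.3g/h ke=%.3g/h V/F=%.3g L/kg fAbs=%.2f\n",
    object@ka, object@ke, object@vOverF, object@fAbs))
  cat(sprintf("  fUrine=%.2f fFaeces=%.2f coeff=%.3g bsvSigma=%.2f\n",
              object@fUrine, object@fFaeces,
              object@incorporationCoeff, object@bsvSigma))
})

setMethod("show", "MeasurementModel", function(object) {
  cat(sprintf(
    "MeasurementModel: sample CV=%.0f%% cal CV=%.0f%% (x%d reps), slope=%.3g, blank SD=%.3g, LOD(truth)=%.3g\n",
    100 * object@proportionalCV, 100 * object@calibrationCV,
    object@calReplicates, object@responseSlope, object@blankSD,
    object@lodTruth))
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve %s in %s: y = %.4g x + %.4g (r2 = %.4f)%s\n",
    object@analyte, object@matrix, object@slope, object@intercept,
    object@rSquared, if (object@accepted) "" else " [flagged r2 < 0.99]"))
  cat(sprintf("  %d levels, LOD = %.3g, linear range [%.3g, %.3g]\n",
              object@nLevelsUsed, object@lod,
              object@linearRange[1], object@linearRange[2]))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", nrow(object@panel), "substances,",
      sum(object@design@groupSizes), "animals, seed", object@seed, "\n")
  cat("  concentration rows:", nrow(object@concentrations),
      "| calibration rows:", nrow(object@calibration), "\n")
})

setMethod("show", "QuantifiedStudy", function(object) {
  cat("QuantifiedStudy:", nrow(object@concentrations), "rows,",
      length(object@curves), "calibration curves\n")
  cat("  censored fraction:",
      round(mean(object@concentrations$censored), 3), "\n")
})

setMethod("show", "QSARModel", function(object) {
  cat("QSARModel:", length(object@retainedFeatures), "features,",
      object@forestSpec$nTrees, "trees (seed",
      paste0(object@forestSpec$seed, ")"), "\n")
  tab <- table(object@trainingLabels)
  cat("  training:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "| accuracy", round(object@trainingAccuracy, 4), "\n")
})
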