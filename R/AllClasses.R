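## Central S4 containers. Long-format measurement tables are plain
## data.frames following the documented concentration schema (see
## `concentrationSchema()`); the classes below hold structured study
## metadata, fitted calibration curves and trained screening models.

#' StudyDesign: the animal study layout
#'
#' Describes a repeated oral-dose study: dose groups, dosing schedule,
#' the dense plasma sampling grid on the last dosing day, per-matrix
#' collection days and the hair harvest day.
#'
#' @slot doseLevels Named numeric, mg/kg per treated group, strictly
#'   increasing (default 1, 2, 4 for groups \code{half}, \code{one},
#'   \code{two}).
#' @slot dosingIntervalH Hours between doses (default 24).
#' @slot nDoses Number of administrations (default 7).
#' @slot groupSizes Named integer, animals per group including
#'   \code{vehicle}.
#' @slot plasmaTimesDay7 Hours post-dose for the dense plasma grid on the
#'   final dosing day; includes 0 (the pre-dose trough).
#' @slot collectionDays Named list of integer study days per matrix.
#' @slot hairHarvestDay Study day on which hair is shaved.
#' @slot gavageVolume Gavage volume, mL/kg.
#' @exportClass StudyDesign
setClass("StudyDesign", slots = c(
  doseLevels      = "numeric",
  dosingIntervalH = "numeric",
  nDoses          = "integer",
  groupSizes      = "integer",
  plasmaTimesDay7 = "numeric",
  collectionDays  = "list",
  hairHarvestDay  = "integer",
  gavageVolume    = "numeric"
))

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@doseLevels) < 1L || any(object@doseLevels <= 0))
    msg <- c(msg, "doseLevels must be positive")
  if (is.unsorted(object@doseLevels, strictly = TRUE))
    msg <- c(msg, "doseLevels must be strictly increasing")
  if (object@dosingIntervalH <= 0)
    msg <- c(msg, "dosingIntervalH must be > 0")
  if (object@nDoses < 1L)
    msg <- c(msg, "nDoses must be >= 1")
  if (any(object@plasmaTimesDay7 < 0) ||
      is.unsorted(object@plasmaTimesDay7, strictly = TRUE))
    msg <- c(msg, "plasmaTimesDay7 must be non-negative and sorted")
  if (is.null(names(object@collectionDays)) ||
      !all(vapply(object@collectionDays,
                  function(d) all(d >= 0) && !is.unsorted(d), logical(1))))
    msg <- c(msg, "collectionDays must be named, non-negative, sorted")
  if (any(object@groupSizes < 0))
    msg <- c(msg, "groupSizes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' PKParameters: per-substance disposition parameters for the simulator
#'
#' One-compartment first-order absorption parameters plus excretion
#' fractions and the hair-deposition coefficient used by the synthetic
#' study generator.
#'
#' @slot ka First-order absorption rate, 1/h (must exceed \code{ke}).
#' @slot ke First-order elimination rate, 1/h.
#' @slot vOverF Apparent distribution volume V/F, L/kg.
#' @slot fAbs Fraction of the dose absorbed (used for excretion mass
#'   balance; the unabsorbed remainder transits to faeces).
#' @slot fUrine Fraction of the absorbed dose excreted unchanged in urine.
#' @slot fFaeces Fraction of the absorbed dose excreted in faeces.
#' @slot incorporationCoeff Hair deposition per unit plasma exposure,
#'   (pg/mg) per (ng·h/mL); the generating analogue of the hair
#'   incorporation degree.
#' @slot bsvSigma Between-subject lognormal SD applied (mean-one) to hair
#'   incorporation and to apparent clearance.
#' @exportClass PKParameters
setClass("PKParameters", slots = c(
  ka = "numeric", ke = "numeric", vOverF = "numeric", fAbs = "numeric",
  fUrine = "numeric", fFaeces = "numeric",
  incorporationCoeff = "numeric", bsvSigma = "numeric"
))

setValidity("PKParameters", function(object) {
  msg <- character()
  if (!(object@ka > object@ke && object@ke > 0))
    msg <- c(msg, "require ka > ke > 0")
  if (object@vOverF <= 0) msg <- c(msg, "vOverF must be > 0")
  if (object@fAbs < 0 || object@fAbs > 1) msg <- c(msg, "fAbs in [0,1]")
  if (object@fUrine < 0 || object@fFaeces < 0 ||
      object@fUrine + object@fFaeces > 1)
    msg <- c(msg, "require 0 <= fUrine + fFaeces <= 1")
  if (object@incorporationCoeff < 0)
    msg <- c(msg, "incorporationCoeff must be >= 0")
  if (object@bsvSigma < 0) msg <- c(msg, "bsvSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MeasurementModel: LC-MS-like response and censoring model
#'
#' Operates at the internal-standard response-ratio level: measured
#' response = slope * concentration * (1 + cv * Z) + blank noise. Spiked
#' calibrators in pooled blank matrix carry their own, smaller,
#' proportional CV than biological study samples, and the matrix-matched
#' curve is run once per analytical sequence so levels are averaged over
#' \code{calReplicates} replicate responses.
#'
#' @slot proportionalCV Proportional CV of study-sample responses
#'   (fraction; default 0.20).
#' @slot calibrationCV Proportional CV of calibrator responses (default
#'   0.05).
#' @slot blankSD SD of the blank response ratio (response units).
#' @slot responseSlope True response ratio per concentration unit.
#' @slot lodTruth Generator-side censoring concentration; observed values
#'   below it are flagged censored at simulation time.
#' @slot calReplicates Replicate calibrator responses per level (one per
#'   analytical sequence; default 5).
#' @exportClass MeasurementModel
setClass("MeasurementModel", slots = c(
  proportionalCV = "numeric", calibrationCV = "numeric",
  blankSD = "numeric", responseSlope = "numeric",
  lodTruth = "numeric", calReplicates = "integer"
))

setValidity("MeasurementModel", function(object) {
  msg <- character()
  if (object@proportionalCV < 0 || object@calibrationCV < 0)
    msg <- c(msg, "CVs must be >= 0")
  if (object@blankSD <= 0) msg <- c(msg, "blankSD must be > 0")
  if (object@responseSlope <= 0) msg <- c(msg, "responseSlope must be > 0")
  if (object@lodTruth < 0) msg <- c(msg, "lodTruth must be >= 0")
  if (object@calReplicates < 1L) msg <- c(msg, "calReplicates >= 1")
  if (length(msg)) msg else TRUE
})

#' CalibrationCurve: fitted matrix-matched calibration line
#'
#' Ordinary least squares of mean internal-standard response ratio on
#' nominal concentration, with the signal-to-noise based limit of
#' detection and the accepted linear range.
#'
#' @slot analyte Analyte name.
#' @slot matrix Matrix name (plasma, urine, faeces, hair).
#' @slot levels data.frame with columns \code{nominal} and
#'   \code{meanResponse}, one row per calibrator level used.
#' @slot slope,intercept OLS coefficients.
#' @slot rSquared Coefficient of determination.
#' @slot lod Limit of detection (lowest level with S/N >= 3); \code{Inf}
#'   when no level qualifies.
#' @slot linearRange Numeric length-2, lowest accepted calibrator to the
#'   top calibrator.
#' @slot nLevelsUsed Number of levels entering the fit (>= 6).
#' @slot accepted TRUE when rSquared >= the linearity threshold (soft
#'   flag; curves are never silently discarded).
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", slots = c(
  analyte = "character", matrix = "character", levels = "data.frame",
  slope = "numeric", intercept = "numeric", rSquared = "numeric",
  lod = "numeric", linearRange = "numeric", nLevelsUsed = "integer",
  accepted = "logical"
))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@nLevelsUsed < 6L)
    msg <- c(msg, "calibration requires at least six levels")
  if (length(object@linearRange) != 2L ||
      object@linearRange[1] > object@linearRange[2])
    msg <- c(msg, "linearRange must be (low, high) with low <= high")
  if (is.finite(object@lod) && object@linearRange[1] < object@lod)
    msg <- c(msg, "linearRange low must be >= lod")
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: one simulated multi-matrix animal study
#'
#' Output of \code{\link{simulateStudy}}: the substance panel, design,
#' generating parameters, the long-format concentration table (true
#' values, measured responses, instrument-naive values and censoring
#' flags) and matrix-matched calibration sample sets.
#'
#' @slot panel data.frame of simulated substances (modelPanel schema).
#' @slot design StudyDesign.
#' @slot pkMap Named list of PKParameters, one per panel substance.
#' @slot measurement MeasurementModel.
#' @slot concentrations Long-format data.frame (concentration schema plus
#'   \code{true_value} and \code{response} columns).
#' @slot calibration data.frame of calibration samples with a \code{role}
#'   column (blank | calibrator).
#' @slot seed Integer seed the study was generated from.
#' @exportClass SyntheticStudy
setClass("SyntheticStudy", slots = c(
  panel = "data.frame", design = "StudyDesign", pkMap = "list",
  measurement = "MeasurementModel", concentrations = "data.frame",
  calibration = "data.frame", seed = "integer"
))

#' QuantifiedStudy: study after calibration-based back-calculation
#'
#' @slot concentrations Concentration table with \code{value} replaced by
#'   the calibration back-calculated concentration and \code{censored}
#'   re-derived from the curve LOD.
#' @slot curves Named list of \code{CalibrationCurve} ("analyte|matrix").
#' @slot design StudyDesign carried over from the input study.
#' @slot panel Substance panel carried over from the input study.
#' @exportClass QuantifiedStudy
setClass("QuantifiedStudy", slots = c(
  concentrations = "data.frame", curves = "list",
  design = "StudyDesign", panel = "data.frame"
))

#' QSARModel: random-forest hair-detectability classifier
#'
#' Trained forest plus the per-feature min/max box that defines the
#' range-based applicability domain over the training set.
#'
#' @slot retainedFeatures Features surviving the variance filter, in
#'   table order.
#' @slot adRanges 2 x p numeric matrix, rows \code{min} and \code{max},
#'   columns exactly \code{retainedFeatures}.
#' @slot forest The fitted \code{randomForest} object.
#' @slot forestSpec List: \code{nTrees}, \code{mtry}, \code{seed}.
#' @slot trainingLabels Named factor (positive/negative) per training
#'   substance.
#' @slot trainingAccuracy Fraction of training rows re-predicted
#'   correctly.
#' @exportClass QSARModel
setClass("QSARModel", slots = c(
  retainedFeatures = "character", adRanges = "matrix", forest = "ANY",
  forestSpec = "list", trainingLabels = "factor",
  trainingAccuracy = "numeric"
))

setValidity("QSARModel", function(object) {
  msg <- character()
  if (!identical(colnames(object@adRanges), object@retainedFeatures))
    msg <- c(msg, "adRanges must be keyed exactly by retainedFeatures")
  if (object@trainingAccuracy < 0 || object@trainingAccuracy > 1)
    msg <- c(msg, "trainingAccuracy must lie in [0, 1]")
  if (nlevels(object@trainingLabels) < 2L)
    msg <- c(msg, "training labels must contain two classes")
  if (length(msg)) msg else TRUE
})
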