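## Matrix-matched calibration, signal-to-noise LOD, and back-calculation
## of concentrations from internal-standard response ratios.

#' Limit of detection from blank and calibrator responses
#'
#' The S/N >= 3 rule operationalized at the response-ratio level: the
#' LOD is the lowest calibrator level whose mean response ratio is at
#' least three times the SD of the blank response ratios.
#'
#' @param blankResponses Numeric, >= 3 blank response ratios.
#' @param levels data.frame with columns \code{nominal} and
#'   \code{meanResponse} (one row per level).
#' @return The LOD concentration, or \code{Inf} (with attribute
#'   \code{detectable = FALSE}) when no level qualifies.
#' @examples
#' lv <- data.frame(nominal = c(0.01, 0.1), meanResponse = c(0.005, 0.05))
#' estimateLOD(rnorm(6, 0, 0.01), lv)
#' @export
estimateLOD <- function(blankResponses, levels) {
  if (length(blankResponses) < 3L)
    stop("need at least 3 blank replicates")
  stopifnot(all(c("nominal", "meanResponse") %in% names(levels)))
  thr <- 3 * stats::sd(blankResponses)
  ok <- levels$nominal[levels$meanResponse >= thr]
  if (!length(ok)) return(structure(Inf, detectable = FALSE))
  structure(min(ok), detectable = TRUE)
}

#' Fit a matrix-matched calibration curve
#'
#' Replicate calibrator responses are averaged per level (one curve per
#' analytical sequence, fit on mean response ratios); when blanks are
#' supplied, levels below the S/N >= 3 LOD are excluded before the fit.
#' The line is unweighted ordinary least squares of mean response ratio
#' on nominal concentration; 1/x^2 weighting is available but off by
#' default. Curves with r-squared below \code{r2Threshold} are flagged,
#' not rejected.
#'
#' @param samples data.frame with columns \code{nominal} and
#'   \code{response} (replicates allowed), or with a \code{role} column
#'   in which case rows with \code{role == "blank"} supply the blanks.
#' @param blanks Optional numeric blank response ratios (overrides any
#'   \code{role} column).
#' @param analyte,matrix Labels stored on the curve.
#' @param r2Threshold Linearity flag threshold (default 0.99).
#' @param weighting \code{"none"} (default) or \code{"1/x2"}.
#' @return A \code{\linkS4class{CalibrationCurve}}.
#' @examples
#' s <- data.frame(nominal = 1:8, response = 2 * (1:8) + 0.1)
#' fitCalibration(s)
#' @export
fitCalibration <- function(samples, blanks = NULL,
                           analyte = "analyte", matrix = "matrix",
                           r2Threshold = 0.99,
                           weighting = c("none", "1/x2")) {
  weighting <- match.arg(weighting)
  if (is.null(blanks) && "role" %in% names(samples)) {
    blanks <- samples$response[samples$role == "blank"]
    samples <- samples[samples$role != "blank", , drop = FALSE]
  }
  stopifnot(all(c("nominal", "response") %in% names(samples)))
  agg <- stats::aggregate(response ~ nominal, data = samples, FUN = mean)
  names(agg) <- c("nominal", "meanResponse")
  agg <- agg[order(agg$nominal), , drop = FALSE]

  lod <- NA_real_
  if (!is.null(blanks) && length(blanks) >= 3L) {
    lod <- estimateLOD(blanks, agg)
    agg <- agg[agg$nominal >= lod, , drop = FALSE]
  }
  if (nrow(agg) == 1L)
    stop("zero variance in nominal concentrations")
  if (nrow(agg) < 6L)
    stop("calibration requires at least six usable levels, got ",
         nrow(agg))

  w <- if (weighting == "1/x2") 1 / agg$nominal^2 else NULL
  fit <- stats::lm(meanResponse ~ nominal, data = agg, weights = w)
  ## suppressed: summary.lm warns on noise-free (exact) fits
  r2 <- suppressWarnings(summary(fit)$r.squared)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("non-positive calibration slope")

  new("CalibrationCurve", analyte = analyte, matrix = matrix,
      levels = agg, slope = slope,
      intercept = unname(stats::coef(fit)[1]), rSquared = r2,
      lod = if (is.na(lod)) min(agg$nominal) else as.numeric(lod),
      linearRange = c(min(agg$nominal), max(agg$nominal)),
      nLevelsUsed = nrow(agg), accepted = r2 >= r2Threshold)
}

#' Back-calculate concentrations from response ratios
#'
#' \code{conc = (ratio - intercept) / slope}. Values outside the curve's
#' linear range (exclusive) are estimated by extrapolation and flagged;
#' negative back-calculations clamp to 0 with the censored flag set.
#'
#' @param curve A \code{\linkS4class{CalibrationCurve}}.
#' @param responseRatio Numeric vector of response ratios.
#' @return data.frame with columns \code{conc}, \code{extrapolated},
#'   \code{censored}.
#' @export
backCalculate <- function(curve, responseRatio) {
  if (curve@slope <= 0) stop("curve slope must be positive")
  conc <- (responseRatio - curve@intercept) / curve@slope
  ## the range is inclusive; a relative guard keeps values that land on
  ## a boundary only through floating-point noise from being flagged
  tol <- 1e-9 * max(1, curve@linearRange[2])
  extrapolated <- conc < curve@linearRange[1] - tol |
    conc > curve@linearRange[2] + tol
  censored <- conc <= tol
  conc[censored] <- 0
  extrapolated[censored] <- FALSE
  data.frame(conc = conc, extrapolated = extrapolated,
             censored = censored)
}

#' Quantify a simulated study through its calibration sets
#'
#' Fits one calibration curve per analyte and matrix from the study's
#' calibration samples, back-calculates every sample response, and
#' re-derives the censoring flag from the curve's LOD (back-calculated
#' concentrations below the LOD are reported as 0, censored). Censoring
#' is idempotent: a record censored at measurement time stays censored.
#'
#' @param study A \code{\linkS4class{SyntheticStudy}}.
#' @param r2Threshold Linearity flag threshold passed to
#'   \code{\link{fitCalibration}}.
#' @return A \code{\linkS4class{QuantifiedStudy}}.
#' @examples
#' st <- simulateStudy(modelPanel()["furosemide", ], seed = 3)
#' quantifyStudy(st)
#' @export
quantifyStudy <- function(study, r2Threshold = 0.99) {
  stopifnot(is(study, "SyntheticStudy"))
  conc <- study@concentrations
  cal <- study@calibration
  curves <- list()
  for (m in unique(conc$matrix)) {
    for (s in unique(conc$substance)) {
      cs <- cal[cal$matrix == m & cal$analyte == s, , drop = FALSE]
      if (!nrow(cs)) stop("no calibration set for ", s, " in ", m)
      curve <- fitCalibration(
        cs[, c("nominal", "response", "role")],
        analyte = s, matrix = m, r2Threshold = r2Threshold)
      curves[[paste(s, m, sep = "|")]] <- curve
      idx <- conc$matrix == m & conc$substance == s
      bc <- backCalculate(curve, conc$response[idx])
      v <- bc$conc
      cens <- bc$censored | v < curve@lod | conc$censored[idx]
      v[cens] <- 0
      conc$value[idx] <- v
      conc$censored[idx] <- cens
    }
  }
  new("QuantifiedStudy", concentrations = conc, curves = curves,
      design = study@design, panel = study@panel)
}
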