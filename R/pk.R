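## Non-compartmental summaries on quantified series: trapezoidal AUC,
## Cmax/Tmax, detection windows, dose linearity.

#' Linear trapezoidal AUC
#'
#' Censored points contribute 0 at their timestamp (conservative
#' "not detected" semantics); no extrapolation beyond the sampled
#' interval.
#'
#' @param timesH Sorted, strictly increasing sampling times, hours.
#' @param concs Non-negative concentrations.
#' @param censored Optional logical; censored points are set to 0.
#' @return AUC in conc·h units.
#' @examples
#' aucTrapezoid(c(0, 12), c(5, 5))  # 60
#' @export
aucTrapezoid <- function(timesH, concs, censored = NULL) {
  n <- length(timesH)
  if (n < 2L) stop("need at least two points")
  if (length(concs) != n) stop("times and concs differ in length")
  if (is.unsorted(timesH, strictly = TRUE))
    stop("times must be strictly increasing")
  if (!is.null(censored)) concs[censored] <- 0
  if (any(concs < 0)) stop("concentrations must be non-negative")
  sum(diff(timesH) * (concs[-n] + concs[-1]) / 2)
}

#' Per-animal PK summaries from a quantified study
#'
#' Computes, for every treated animal and substance, the day-7
#' AUC(0-12 h) by the linear trapezoidal rule on the design grid, plus
#' Cmax and Tmax over the grid. An AUC is reported as \code{NA} when
#' every point on the grid is censored.
#'
#' @param quantified A \code{\linkS4class{QuantifiedStudy}}.
#' @return data.frame: substance, animal_id, dose_group, auc_0_12,
#'   cmax, tmax, n_detected.
#' @export
pkSummaries <- function(quantified) {
  stopifnot(is(quantified, "QuantifiedStudy"))
  conc <- quantified@concentrations
  lastDay <- max(quantified@design@collectionDays$plasma[
    quantified@design@collectionDays$plasma <=
      quantified@design@nDoses])
  d7 <- conc[conc$matrix == "plasma" & conc$day == lastDay &
             conc$group != "vehicle", , drop = FALSE]
  if (!nrow(d7)) stop("no treated day-7 plasma samples")
  out <- do.call(rbind, lapply(
    split(d7, list(d7$substance, d7$animal_id), drop = TRUE),
    function(x) {
      x <- x[order(x$time_h), ]
      det <- sum(!x$censored)
      data.frame(substance = x$substance[1], animal_id = x$animal_id[1],
                 dose_group = x$group[1],
                 auc_0_12 = if (det > 0)
                   aucTrapezoid(x$time_h, x$value, x$censored) else
                   NA_real_,
                 cmax = max(x$value),
                 tmax = x$time_h[which.max(x$value)],
                 n_detected = det)
    }))
  rownames(out) <- NULL
  out[order(out$substance, out$animal_id), ]
}

#' Last collection day with a detectable value
#'
#' @param days Integer collection days.
#' @param values Concentrations on those days.
#' @param censored Logical below-LOD flags.
#' @param lod Limit of detection the values are compared against.
#' @return The maximum day with a non-censored value >= lod, or
#'   \code{NA_integer_} if never detected.
#' @examples
#' detectionWindow(c(0, 7, 10), c(0, 5, 2), c(TRUE, FALSE, FALSE), 1)
#' @export
detectionWindow <- function(days, values, censored, lod = 0) {
  hit <- !censored & values >= lod
  if (!any(hit)) return(NA_integer_)
  as.integer(max(days[hit]))
}

#' Dose linearity of group summary statistics
#'
#' Fits the power model \code{log(stat) = a + b log(dose)} by OLS and
#' reports the slope together with the raw-scale Pearson correlation.
#' A slope of 1 indicates dose-proportional behaviour.
#'
#' @param doses Numeric dose levels (>= 3).
#' @param stats_ Group summary statistic per dose (e.g. mean AUC).
#' @return list: \code{power_slope}, \code{pearson_r}, \code{flagged}
#'   (TRUE when non-positive means forced a raw-scale-only analysis,
#'   leaving the slope \code{NA}).
#' @examples
#' doseLinearity(c(1, 2, 4), c(10, 20, 40))  # slope 1, r 1
#' @export
doseLinearity <- function(doses, stats_) {
  if (length(doses) < 3L || length(stats_) != length(doses))
    stop("need >= 3 dose levels with matching statistics")
  ## correlation is undefined for a constant statistic
  r <- if (stats::sd(stats_) == 0) NA_real_ else stats::cor(doses, stats_)
  if (any(stats_ <= 0))
    return(list(power_slope = NA_real_, pearson_r = r, flagged = TRUE))
  slope <- unname(stats::coef(
    stats::lm(log(stats_) ~ log(doses)))[2])
  list(power_slope = slope, pearson_r = r, flagged = FALSE)
}
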