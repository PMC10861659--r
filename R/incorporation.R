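## The headline statistic: hair incorporation degree (hair concentration
## divided by plasma AUC) with group summaries, plus the cross-matrix
## detection grid.

#' Hair incorporation degree
#'
#' \code{degree = hair concentration / plasma AUC}, in the fixed unit
#' convention (pg/mg) per (ng·h/mL). The degree is only defined when the
#' substance was detected in both matrices: a censored hair value or a
#' missing/non-positive AUC yields \code{NA} (incalculable), never 0.
#'
#' @param hairConc Hair concentration, pg/mg (vectorized).
#' @param plasmaAuc Plasma AUC, ng·h/mL.
#' @param hairCensored Logical, hair value below LOD.
#' @param aucMissing Logical, AUC unavailable (all plasma censored).
#' @return Numeric degrees with \code{NA} where incalculable.
#' @examples
#' computeDegree(4.2, 10)  # 0.42
#' computeDegree(4.2, 10, hairCensored = TRUE)  # NA
#' @export
computeDegree <- function(hairConc, plasmaAuc, hairCensored = FALSE,
                          aucMissing = FALSE) {
  n <- max(length(hairConc), length(plasmaAuc))
  hairConc <- rep_len(hairConc, n)
  plasmaAuc <- rep_len(plasmaAuc, n)
  hairCensored <- rep_len(hairCensored, n)
  aucMissing <- rep_len(aucMissing, n)
  bad <- hairCensored | aucMissing | is.na(plasmaAuc) | plasmaAuc <= 0
  out <- rep(NA_real_, n)
  out[!bad] <- hairConc[!bad] / plasmaAuc[!bad]
  out
}

#' Mean and standard error of a set of degrees
#'
#' @param degrees Numeric vector; \code{NA} (incalculable) entries are
#'   dropped and reported via \code{n}.
#' @return list: \code{mean}, \code{sem} (sample SD / sqrt(n);
#'   \code{NA} when n = 1), \code{n}.
#' @examples
#' groupSummary(c(2, 4))  # mean 3, sem 1
#' @export
groupSummary <- function(degrees) {
  degrees <- degrees[!is.na(degrees)]
  if (!length(degrees)) stop("no calculable degrees")
  n <- length(degrees)
  list(mean = mean(degrees),
       sem = if (n > 1L) stats::sd(degrees) / sqrt(n) else NA_real_,
       n = n)
}

#' Incorporation degrees for every substance of a quantified study
#'
#' Per treated animal, divides the harvest-day hair concentration by the
#' day-7 plasma AUC(0-12 h); animals with a censored hair value or no
#' calculable AUC are excluded and \code{n} reports the animals actually
#' used. Degrees are pooled across the treated dose groups (the model is
#' dose-linear, so the degree is dose-independent); per-dose means are
#' also reported.
#'
#' @param quantified A \code{\linkS4class{QuantifiedStudy}}.
#' @param pk Optional precomputed \code{\link{pkSummaries}} table.
#' @return data.frame: substance, n, mean, sem, and one
#'   \code{mean_<group>} column per treated dose group (\code{NA} where
#'   incalculable).
#' @export
incorporationResults <- function(quantified, pk = pkSummaries(quantified)) {
  conc <- quantified@concentrations
  hair <- conc[conc$matrix == "hair" &
               conc$day == quantified@design@hairHarvestDay &
               conc$group != "vehicle", , drop = FALSE]
  groups <- setdiff(names(quantified@design@groupSizes), "vehicle")
  out <- lapply(unique(conc$substance), function(s) {
    h <- hair[hair$substance == s, ]
    p <- pk[pk$substance == s, ]
    m <- merge(h, p, by = "animal_id")
    deg <- computeDegree(m$value, m$auc_0_12,
                         hairCensored = m$censored,
                         aucMissing = is.na(m$auc_0_12))
    row <- data.frame(substance = s, n = sum(!is.na(deg)),
                      mean = NA_real_, sem = NA_real_)
    if (row$n > 0) {
      gs <- groupSummary(deg)
      row$mean <- gs$mean; row$sem <- gs$sem
    }
    for (g in groups) {
      dg <- deg[m$group == g & !is.na(deg)]
      row[[paste0("mean_", g)]] <-
        if (length(dg)) mean(dg) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-matrix detection grid
#'
#' A substance is detected in a matrix iff any treated animal has a
#' non-censored value at or above the matrix LOD at any collection; the
#' last such collection day is the detection window. Raising any LOD can
#' only shrink the grid.
#'
#' @param conc Concentration table (quantified), or a
#'   \code{QuantifiedStudy}.
#' @param lods Named numeric, LOD per matrix (default 0: the censored
#'   flag alone decides).
#' @return list: \code{grid} (substance, matrix, detected,
#'   last_detected_day) and \code{counts} (detected substances per
#'   matrix).
#' @export
buildDetectionGrid <- function(conc, lods = NULL) {
  if (is(conc, "QuantifiedStudy")) conc <- conc@concentrations
  conc <- conc[conc$group != "vehicle", , drop = FALSE]
  combos <- unique(conc[, c("substance", "matrix")])
  grid <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$substance[i]; m <- combos$matrix[i]
    x <- conc[conc$substance == s & conc$matrix == m, ]
    lod <- if (!is.null(lods) && m %in% names(lods)) lods[[m]] else 0
    d <- detectionWindow(x$day, x$value, x$censored, lod)
    data.frame(substance = s, matrix = m, detected = !is.na(d),
               last_detected_day = d)
  }))
  rownames(grid) <- NULL
  counts <- tapply(grid$detected, grid$matrix, sum)
  list(grid = grid, counts = counts)
}
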