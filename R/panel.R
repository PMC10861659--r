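## Embedded study fixtures: the 17-compound doping-control model panel
## with hair/plasma detection labels, and the segmental human-hair
## profiles from the proof-of-concept diuretics study.

.panelMatrices <- c("plasma", "urine", "faeces", "hair")

#' The 17-compound doping-control model panel
#'
#' Seventeen substances prohibited at all times in sport, spanning four
#' classes: S1 anabolic agents (S1.1 stanozolol, methyltestosterone,
#' testosterone; S1.2 clenbuterol), S3 beta-2 agonists (terbutaline,
#' salbutamol), S4 hormone and metabolic modulators (tamoxifen,
#' clomifene, anastrozole, GW1516, letrozole, trimetazidine) and S5
#' diuretics and masking agents (furosemide, hydrochlorothiazide,
#' canrenone, chlorothiazide, probenecid).
#'
#' Hair/plasma detection labels reflect the animal-study outcome: 14 of
#' 17 were detectable in hair (all but terbutaline, salbutamol and
#' chlorothiazide); of those, methyltestosterone, testosterone,
#' hydrochlorothiazide and canrenone were not detectable in plasma,
#' leaving 10 substances with both matrices positive. Per-substance
#' urine and faeces statuses are stored as \code{NA}: only their totals
#' were reported numerically, and the fixture does not encode
#' figure-derived pseudo-data.
#'
#' \code{logp} is an octanol-water partition estimate computed with the
#' Open Babel logP predictor from the embedded structures; \code{vehicle}
#' applies \code{\link{assignVehicle}} to it.
#'
#' @return data.frame with one row per substance and columns
#'   \code{name}, \code{wada_class}, \code{smiles}, \code{logp},
#'   \code{hair_label} (positive/negative), \code{hair}, \code{plasma}
#'   (logical), \code{urine}, \code{faeces} (logical, \code{NA}),
#'   \code{vehicle}.
#' @examples
#' panel <- modelPanel()
#' sum(panel$hair)                 # 14 hair-positives
#' sum(panel$hair & panel$plasma)  # 10 with both matrices
#' @export
modelPanel <- function() {
  p <- data.frame(
    name = c("stanozolol", "methyltestosterone", "testosterone",
             "clenbuterol", "terbutaline", "salbutamol",
             "tamoxifen", "clomifene", "anastrozole", "GW1516",
             "letrozole", "trimetazidine",
             "furosemide", "hydrochlorothiazide", "canrenone",
             "chlorothiazide", "probenecid"),
    wada_class = c("S1.1", "S1.1", "S1.1", "S1.2", "S3", "S3",
                   "S4", "S4", "S4", "S4", "S4", "S4",
                   "S5", "S5", "S5", "S5", "S5"),
    smiles = c(
      "CC12CCC3C(CCC4CC5=C(CC34C)NN=C5)C1CCC2(C)O",
      "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2(C)O",
      "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
      "CC(C)(C)NCC(O)c1cc(Cl)c(N)c(Cl)c1",
      "CC(C)(C)NCC(O)c1cc(O)cc(O)c1",
      "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
      "CC/C(=C(\\c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1",
      "CCN(CC)CCOc1ccc(cc1)C(=C(/Cl)c1ccccc1)c1ccccc1",
      "CC(C)(C#N)c1cc(Cn2cncn2)cc(c1)C(C)(C)C#N",
      "Cc1cc(SCc2sc(nc2C)-c2ccc(cc2)C(F)(F)F)ccc1OCC(=O)O",
      "N#Cc1ccc(cc1)C(n1cncn1)c1ccc(cc1)C#N",
      "COc1ccc(CN2CCNCC2)c(OC)c1OC",
      "NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl",
      "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",
      "CC12CCC3C(C=CC4=CC(=O)CCC34C)C1CCC21CCC(=O)O1",
      "NS(=O)(=O)c1cc2c(cc1Cl)N=CNS2(=O)=O",
      "CCCN(CCC)S(=O)(=O)c1ccc(cc1)C(=O)O"),
    logp = c(4.118, 4.269, 3.879, 3.969, 1.910, 1.697,
             5.996, 6.563, 2.929, 6.201, 2.659, 1.384,
             3.745, 2.977, 4.370, 2.565, 3.276),
    stringsAsFactors = FALSE)
  hairNeg   <- c("terbutaline", "salbutamol", "chlorothiazide")
  plasmaNeg <- c(hairNeg, "methyltestosterone", "testosterone",
                 "hydrochlorothiazide", "canrenone")
  p$hair_label <- ifelse(p$name %in% hairNeg, "negative", "positive")
  p$hair    <- !(p$name %in% hairNeg)
  p$plasma  <- !(p$name %in% plasmaNeg)
  p$urine   <- NA
  p$faeces  <- NA
  p$vehicle <- vapply(p$logp, assignVehicle, character(1))
  rownames(p) <- p$name
  p
}

#' Vehicle assignment for the gavage mixture
#'
#' Substances with logP below 3.25 are dissolved in dimethyl sulfoxide;
#' the rest in corn oil (the mixture's final diluent, which also takes
#' the boundary value).
#'
#' @param logp Finite numeric octanol-water logP estimate.
#' @return \code{"dmso"} or \code{"corn_oil"}.
#' @examples
#' assignVehicle(1.0)   # dmso
#' assignVehicle(5.0)   # corn_oil
#' assignVehicle(3.25)  # corn_oil (boundary goes to the diluent)
#' @export
assignVehicle <- function(logp) {
  if (length(logp) != 1L || !is.numeric(logp) || !is.finite(logp))
    stop("logp must be a single finite number")
  if (logp < 3.25) "dmso" else "corn_oil"
}

#' Validate a substance panel
#'
#' Checks the invariants of the panel schema: unique names, known WADA
#' classes, hair label consistent with the hair detection flag, and
#' parseable structures where present.
#'
#' @param panel data.frame in the \code{\link{modelPanel}} schema.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validatePanel <- function(panel) {
  req <- c("name", "wada_class", "smiles", "logp", "hair_label",
           "hair", "plasma")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$name))
    stop("substance names must be unique within a panel")
  if (!all(panel$wada_class %in% c("S1.1", "S1.2", "S3", "S4", "S5")))
    stop("unknown wada_class value")
  if (!all(panel$hair_label %in% c("positive", "negative", "unknown")))
    stop("unknown hair_label value")
  both <- panel$hair_label != "unknown"
  if (any(both & (panel$hair_label == "positive") != panel$hair))
    stop("hair_label inconsistent with hair detection flag")
  invisible(TRUE)
}

#' Segmental human-hair profiles from the diuretics proof-of-concept
#'
#' Per-subject 2-cm hair-segment concentrations for volunteers on
#' chronic diuretic/masking-agent (and one aromatase-inhibitor)
#' therapy. Only values printed as text are embedded: subject F1
#' (letrozole; permed and dyed hair) at 1608, 950 and 507 pg/mg over
#' 0-2, 2-4 and 4-6 cm; subject F6 (hydrochlorothiazide, 5 weeks) at
#' 93 pg/mg over 0-2 cm; and the all-censored profiles of subjects F3
#' and M1, whose drug use lasted under 5 weeks (their
#' \code{use_duration_weeks} is stored as the placeholder 4, the report
#' only states "less than 5 weeks").
#'
#' @return list with \code{subjects} (subject_id, drug,
#'   use_duration_weeks, cosmetic_treatment) and \code{segments}
#'   (subject_id, proximal_cm, distal_cm, concentration pg/mg,
#'   censored).
#' @examples
#' humanSegmentProfiles()$segments
#' @export
humanSegmentProfiles <- function() {
  subjects <- data.frame(
    subject_id = c("F1", "F3", "M1", "F6"),
    drug = c("letrozole", "furosemide", "furosemide",
             "hydrochlorothiazide"),
    use_duration_weeks = c(NA, 4, 4, 5),
    cosmetic_treatment = c("perm+dye", "", "", "perm+dye"),
    stringsAsFactors = FALSE)
  segments <- data.frame(
    subject_id = c("F1", "F1", "F1", "F3", "F3", "F3",
                   "M1", "M1", "M1", "F6"),
    proximal_cm = c(0, 2, 4, 0, 2, 4, 0, 2, 4, 0),
    distal_cm   = c(2, 4, 6, 2, 4, 6, 2, 4, 6, 2),
    concentration = c(1608, 950, 507, 0, 0, 0, 0, 0, 0, 93),
    censored = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                 TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  list(subjects = subjects, segments = segments)
}
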