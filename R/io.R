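## CSV readers/writers for the shared concentration schema and for
## external descriptor tables. Readers validate; they never coerce
## silently.

#' The concentration table schema
#'
#' All pipeline stages exchange long-format concentration tables with
#' these columns. A copy of the schema ships as
#' \code{system.file("extdata", "concentration-schema.csv", package =
#' "trichoScreen")}.
#'
#' @return data.frame describing each column (name, type, description).
#' @export
concentrationSchema <- function() {
  data.frame(
    column = c("substance", "matrix", "animal_id", "group", "day",
               "time_h", "value", "censored"),
    type = c("character", "character", "character", "character",
             "integer", "numeric", "numeric", "logical"),
    description = c(
      "analyte name",
      "one of plasma, urine, faeces, hair",
      "animal identifier, unique within group",
      "dose group: vehicle, half, one, two",
      "study day of collection (0 = pre-dose)",
      "hours post-dose within the day (0 outside the day-7 grid)",
      "concentration, ng/mL (liquids) or pg/mg (solids); 0 when censored",
      "TRUE when below the limit of detection"),
    stringsAsFactors = FALSE)
}

.requiredConcCols <- c("substance", "matrix", "animal_id", "group",
                       "day", "time_h", "value", "censored")

#' Validate a concentration table against the schema
#'
#' @param x data.frame candidate.
#' @return Invisibly \code{TRUE}; errors on missing columns, unknown
#'   matrices, non-numeric values, inconsistent censoring, or duplicated
#'   (substance, matrix, animal, day, time) keys.
#' @export
validateConcentrationTable <- function(x) {
  miss <- setdiff(.requiredConcCols, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(TRUE))
  if (!all(x$matrix %in% .panelMatrices))
    stop("unknown matrix name(s): ",
         paste(unique(setdiff(x$matrix, .panelMatrices)), collapse = ", "))
  if (!is.numeric(x$value) || anyNA(x$value))
    stop("'value' must be numeric with no missing entries")
  if (!is.logical(x$censored) || anyNA(x$censored))
    stop("'censored' must be logical with no missing entries")
  if (any(x$value[x$censored] != 0))
    stop("censored rows must carry value 0")
  if (any(x$value < 0)) stop("'value' must be non-negative")
  key <- paste(x$substance, x$matrix, x$animal_id, x$day, x$time_h,
               sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (substance, matrix, animal, day, time) key")
  invisible(TRUE)
}

#' Read / write concentration tables
#'
#' Plain-CSV serialization of the concentration schema. Reading
#' validates; writing validates then serializes at full double
#' precision, so \code{readConcentrationTable(writeConcentrationTable(x))}
#' round-trips values to at least 12 significant digits.
#'
#' @param path File path.
#' @param x Concentration table to write.
#' @return \code{readConcentrationTable}: validated data.frame sorted by
#'   (substance, matrix, animal_id, day, time_h).
#' @export
readConcentrationTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(value = "character"))
  miss <- setdiff(.requiredConcCols, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  val <- suppressWarnings(as.numeric(x$value))
  if (anyNA(val) & nrow(x) > 0)
    stop("non-numeric entries in 'value'")
  x$value <- val
  if (is.character(x$censored)) x$censored <- as.logical(x$censored)
  x$day <- as.integer(x$day)
  validateConcentrationTable(x)
  x[order(x$substance, x$matrix, x$animal_id, x$day, x$time_h), ,
    drop = FALSE]
}

#' @rdname readConcentrationTable
#' @export
writeConcentrationTable <- function(x, path) {
  validateConcentrationTable(x)
  x <- x[order(x$substance, x$matrix, x$animal_id, x$day, x$time_h),
         .requiredConcCols, drop = FALSE]
  x$value <- formatC(x$value, digits = 15, format = "g")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an external descriptor table
#'
#' One row per substance (first column or row names), remaining columns
#' numeric or categorical features. Values are passed through
#' bit-exactly; no imputation happens here.
#'
#' @param path CSV path.
#' @return data.frame with substance row names and feature columns.
#' @export
readDescriptorTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!ncol(x)) stop("descriptor table has no columns")
  first <- names(x)[1]
  if (first %in% c("substance", "name")) {
    if (anyDuplicated(x[[first]])) stop("duplicated substance names")
    rownames(x) <- x[[first]]
    x[[first]] <- NULL
  }
  if (anyDuplicated(names(x))) stop("feature names must be unique")
  x
}
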