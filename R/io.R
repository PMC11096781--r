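## Dataset reader/writer in the NONMEM-style long format.
##
## Column contract (mg, h, mg/L, mL/min):
##   ID    subject identifier
##   TIME  h since first-dose start
##   EVID  1 = dose event, 0 = observation
##   AMT   dose amount, mg (dose rows)
##   RATE  infusion rate, mg/h (dose rows; duration = AMT/RATE)
##   DV    observed concentration, mg/L (observation rows)
##   MDV   1 = not used in the likelihood (dose rows, BLQ, missing)
##   BLQ   1 = below the limit of quantification
## plus constant-within-subject covariate columns
##   AGE SEX WT BMI SCR CCR ALB SOFA APACHE CRRT ECMO

DATASET_REQUIRED <- c("ID", "TIME", "EVID", "AMT", "RATE", "DV", "MDV")

#' Validate a study dataset
#'
#' Checks the column contract, per-subject structure (at least one dose
#' row, observations not before the first dose, non-decreasing times) and
#' value ranges; flags observations below the LLOQ as BLQ with `MDV = 1`.
#' Errors name the offending column or row numbers.
#'
#' @param x data.frame
#' @param lloq lower limit of quantification, mg/L
#' @return the validated dataset (class `study_dataset`), with `BLQ`/`MDV`
#'   set from the LLOQ rule
#' @export
validate_dataset <- function(x, lloq = DAPTO_LLOQ) {
  miss <- setdiff(DATASET_REQUIRED, names(x))
  if (length(miss)) {
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!"BLQ" %in% names(x)) x$BLQ <- 0L
  obs <- x$EVID == 0
  bad <- which(obs & !is.na(x$DV) & x$DV < lloq & x$BLQ != 1)
  if (length(bad)) {
    x$BLQ[bad] <- 1L
    x$MDV[bad] <- 1L
  }
  neg <- which(obs & x$MDV == 0 & (is.na(x$DV) | x$DV < 0))
  if (length(neg)) {
    stop("observation rows with DV missing or negative but MDV = 0: row(s) ",
         paste(utils::head(neg, 5), collapse = ", "))
  }
  for (id in unique(x$ID)) {
    sel <- which(x$ID == id)
    d <- x[sel, ]
    if (!any(d$EVID == 1)) stop("subject ", id, " has no dose row")
    if (is.unsorted(d$TIME)) {
      stop("non-monotone TIME within subject ", id, ": row(s) ",
           paste(utils::head(sel[which(diff(d$TIME) < 0) + 1L], 5), collapse = ", "))
    }
    first_dose <- min(d$TIME[d$EVID == 1])
    early <- sel[d$EVID == 0 & d$TIME < first_dose]
    if (length(early)) {
      stop("observation before first dose for subject ", id, ": row(s) ",
           paste(utils::head(early, 5), collapse = ", "))
    }
    dr <- d[d$EVID == 1, ]
    if (any(is.na(dr$AMT) | dr$AMT <= 0 | is.na(dr$RATE) | dr$RATE <= 0)) {
      stop("dose rows of subject ", id, " must have positive AMT and RATE")
    }
    covcols <- intersect(c("AGE", "SEX", "WT", "BMI", "SCR", "CCR", "ALB",
                           "SOFA", "APACHE", "CRRT", "ECMO"), names(x))
    for (cc in covcols) {
      v <- d[[cc]]
      if (length(unique(v[!is.na(v)])) > 1L) {
        stop("covariate ", cc, " varies within subject ", id)
      }
    }
  }
  class(x) <- unique(c("study_dataset", class(x)))
  x
}

#' Read a study dataset from CSV
#'
#' @param path CSV file with the documented column contract
#' @param lloq lower limit of quantification, mg/L
#' @return a validated `study_dataset`
#' @export
read_dataset <- function(path, lloq = DAPTO_LLOQ) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(x, lloq)
}

#' Write a study dataset to CSV
#'
#' Numeric values are written with full precision so that
#' `read_dataset(write_dataset(x, f))` is value-identical.
#'
#' @param x a `study_dataset`
#' @param path output file
#' @param truth_path optional path for the generating-truth side table
#'   (`attr(x, "truth")`, written when present)
#' @return `path`, invisibly
#' @export
write_dataset <- function(x, path, truth_path = NULL) {
  df <- as.data.frame(x)
  for (cc in names(df)) {
    if (is.numeric(df[[cc]]) && !is.integer(df[[cc]])) {
      df[[cc]] <- sprintf("%.17g", df[[cc]])
      df[[cc]][df[[cc]] %in% c("NA", "NaN")] <- NA
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  tr <- attr(x, "truth")
  if (!is.null(truth_path)) {
    if (is.null(tr)) stop("write_dataset: no truth attribute to write")
    utils::write.csv(tr, truth_path, row.names = FALSE)
  }
  invisible(path)
}
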