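# Canonical clinical columns. Missing values are first-class (NA): a case is
# excluded only from computations that need the missing value.
CLINICAL_COLUMNS <- c("case_id", "nihssa", "nihss7", "infarct_volume_cm3",
                      "mrs7", "mrs30", "mrs90", "mrs180", "mrs360",
                      "bi30", "bi90", "bi180", "bi360")

MRS_DAYS <- c(7L, 30L, 90L, 180L, 360L)
BI_DAYS <- c(30L, 90L, 180L, 360L)

#' Names of the nine predictable outcome parameters
#'
#' mRS at days 7/30/90/180/360 and the Barthel Index at days 30/90/180/360.
#' @return character vector of length 9.
#' @export
outcome_parameters <- function() {
  c(paste0("mRS", MRS_DAYS), paste0("BI", BI_DAYS))
}

#' Map a parameter name to its clinical-table column
#'
#' Accepts the display names `"mRS90"`, `"BI180"`, `"NIHSSa"`, `"NIHSS7"`
#' (case-insensitive) as well as the raw column names.
#' @param parameter scalar character.
#' @return the clinical column name.
#' @export
parameter_column <- function(parameter) {
  p <- tolower(as.character(parameter))
  if (p == "nihssa") p <- "nihssa"
  if (!p %in% CLINICAL_COLUMNS || p %in% c("case_id"))
    stop(sprintf("unknown parameter '%s'", parameter))
  p
}

# Cohort-level mean of each parameter in the 128-case reference cohort;
# used to center synthetic ground-truth fields so generated outcome
# distributions match the reference cohort rather than the range midpoint.
parameter_center <- function(parameter) {
  p <- parameter_column(parameter)
  centers <- c(mrs7 = 2.9, mrs30 = 2.4, mrs90 = 2.04, mrs180 = 2.02,
               mrs360 = 2.2, bi30 = 73.0, bi90 = 83.8, bi180 = 86.8,
               bi360 = 87.0, nihssa = 8.3, nihss7 = 6.9)
  if (p %in% names(centers)) unname(centers[p]) else mean(parameter_range(p))
}

parameter_range <- function(parameter) {
  p <- parameter_column(parameter)
  if (grepl("^mrs", p)) return(c(0, 6))
  if (grepl("^bi", p)) return(c(0, 100))
  if (grepl("^nihss", p)) return(c(0, 42))
  c(0, Inf) # infarct volume
}

#' Construct and validate one clinical case record
#'
#' @param case_id identifier.
#' @param nihssa,nihss7 NIH Stroke Scale at admission / day 7, integer 0-42
#'   or NA.
#' @param infarct_volume_cm3 infarct volume in cm^3 (> 0) or NA.
#' @param mrs named or positional numeric of length 5 (days 7,30,90,180,360),
#'   each 0-6 or NA.
#' @param bi numeric length 4 (days 30,90,180,360), each 0-100 or NA.
#' @return one-row data.frame with the canonical clinical columns.
#' @export
case_record <- function(case_id, nihssa = NA, nihss7 = NA,
                        infarct_volume_cm3 = NA,
                        mrs = rep(NA_real_, 5), bi = rep(NA_real_, 4)) {
  row <- data.frame(case_id = as.character(case_id),
                    nihssa = as.numeric(nihssa), nihss7 = as.numeric(nihss7),
                    infarct_volume_cm3 = as.numeric(infarct_volume_cm3),
                    stringsAsFactors = FALSE)
  stopifnot(length(mrs) == 5, length(bi) == 4)
  for (i in seq_along(MRS_DAYS)) row[[paste0("mrs", MRS_DAYS[i])]] <- as.numeric(mrs[i])
  for (i in seq_along(BI_DAYS)) row[[paste0("bi", BI_DAYS[i])]] <- as.numeric(bi[i])
  validate_clinical(row)
  row
}

validate_clinical <- function(df) {
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("clinical table: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$case_id))
    stop(sprintf("clinical table: duplicate case id(s): %s",
                 paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", ")))
  check_range <- function(col, lo, hi, integerish = TRUE) {
    v <- df[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi |
                                (integerish & v != round(v))))
    if (length(bad))
      stop(sprintf("clinical table: row %d, column '%s': value %s outside %s",
                   bad[1], col, format(v[bad[1]]),
                   sprintf("[%s-%s]%s", lo, hi,
                           if (integerish) " (integer)" else "")))
  }
  check_range("nihssa", 0, 42); check_range("nihss7", 0, 42)
  for (d in MRS_DAYS) check_range(paste0("mrs", d), 0, 6)
  for (d in BI_DAYS) check_range(paste0("bi", d), 0, 100)
  v <- df$infarct_volume_cm3
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad))
    stop(sprintf("clinical table: row %d, column 'infarct_volume_cm3': value %s must be > 0",
                 bad[1], format(v[bad[1]])))
  invisible(df)
}

#' Read a clinical table from CSV
#'
#' One row per case, columns `case_id, nihssa, nihss7, infarct_volume_cm3,
#' mrs7, mrs30, mrs90, mrs180, mrs360, bi30, bi90, bi180, bi360`. Empty
#' cells become NA (missing). Out-of-range values are rejected with
#' row-addressed messages.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(case_id = "character"))
  names(df) <- tolower(names(df))
  validate_clinical(df)
  for (col in setdiff(CLINICAL_COLUMNS, "case_id"))
    df[[col]] <- as.numeric(df[[col]])
  df[, CLINICAL_COLUMNS]
}

#' Write a clinical table to CSV
#' @param cases clinical data.frame.
#' @param path output path.
#' @export
write_clinical_table <- function(cases, path) {
  validate_clinical(cases)
  utils::write.csv(cases[, CLINICAL_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}
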