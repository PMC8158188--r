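# Tabular schemas shared by all modules.
#
# cohort:   patient_id, index_date, side, age_at_surgery, indication,
#           censor_date, censor_reason
# contacts: patient_id, contact_id, admit_date, discharge_date, specialty,
#           admission_type, setting, side, dx_codes, dx_positions,
#           proc_codes, proc_dates   (multi-valued fields ";"-delimited,
#           positionally aligned)
# truth:    patient_id, event_id, event_date
#
# Dates are ISO-8601 calendar days throughout.

SIDES <- c("left", "right")
CONTACT_SIDES <- c("left", "right", "unknown")
INDICATIONS <- c("primary_OA", "other")
CENSOR_REASONS <- c("revision", "death", "emigration", "none")
ADMISSION_TYPES <- c("acute", "elective")
SETTINGS <- c("inpatient", "outpatient_er", "outpatient_clinic")
SPECIALTIES <- c("orthopedic", "other")

# follow-up is the closed-open window [index, index + 730d) further cut at
# the censoring date (censoring day itself stays inside the window)
FOLLOW_UP_DAYS <- 730L

check_levels <- function(x, levels, what) {
  bad <- !x %in% levels
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
}

#' Validate a THA cohort table
#'
#' Checks the column set and types of a one-row-per-THA table and its
#' invariants: a censoring date, when present, is on or after the index
#' date, and `censor_reason` is `"none"` exactly when `censor_date` is
#' missing.
#'
#' @param x a data frame with the cohort schema.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_tha_table <- function(x) {
  need <- c("patient_id", "index_date", "side", "age_at_surgery",
            "indication", "censor_date", "censor_reason")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("cohort table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as_tibble(x)
  x$index_date <- as.Date(x$index_date)
  x$censor_date <- as.Date(x$censor_date)
  check_levels(x$side, SIDES, "side")
  check_levels(x$indication, INDICATIONS, "indication")
  check_levels(x$censor_reason, CENSOR_REASONS, "censor_reason")
  cens <- !is.na(x$censor_date)
  if (any(cens & x$censor_date < x$index_date)) {
    stop("censor_date before index_date", call. = FALSE)
  }
  if (any(cens != (x$censor_reason != "none"))) {
    stop("censor_date and censor_reason are inconsistent", call. = FALSE)
  }
  x
}

#' Validate a hospital-contact table
#'
#' Checks the contact schema, date ordering (discharge on or after
#' admission) and normalizes every diagnosis/procedure code in the
#' semicolon-delimited multi-valued fields.
#'
#' @param x a data frame with the contacts schema.
#' @return `x` as a tibble with normalized codes.
#' @export
validate_contact_table <- function(x) {
  need <- c("patient_id", "contact_id", "admit_date", "discharge_date",
            "specialty", "admission_type", "setting", "side",
            "dx_codes", "dx_positions", "proc_codes", "proc_dates")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("contact table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as_tibble(x)
  x$admit_date <- as.Date(x$admit_date)
  x$discharge_date <- as.Date(x$discharge_date)
  if (any(x$discharge_date < x$admit_date)) {
    stop("discharge_date before admit_date", call. = FALSE)
  }
  check_levels(x$side, CONTACT_SIDES, "contact side")
  check_levels(x$admission_type, ADMISSION_TYPES, "admission_type")
  check_levels(x$setting, SETTINGS, "setting")
  check_levels(x$specialty, SPECIALTIES, "specialty")
  x$dx_codes <- normalize_multivalue(x$dx_codes)
  x$proc_codes <- normalize_multivalue(x$proc_codes)
  if (anyDuplicated(x$contact_id)) stop("duplicate contact_id", call. = FALSE)
  x
}

# normalize each element of a ";"-joined code list, keeping empties empty
normalize_multivalue <- function(s) {
  s[is.na(s)] <- ""
  nonempty <- s != ""
  if (any(nonempty)) {
    parts <- strsplit(s[nonempty], ";", fixed = TRUE)
    s[nonempty] <- vapply(
      parts, function(p) paste(normalize_code(p), collapse = ";"), character(1)
    )
  }
  s
}

#' Validate a dislocation truth table
#'
#' One row per verified dislocation event (the chart-review gold standard or
#' the synthetic oracle).
#'
#' @param x a data frame with columns `patient_id`, `event_id`, `event_date`.
#' @return `x` as a tibble.
#' @export
validate_truth_table <- function(x) {
  need <- c("patient_id", "event_id", "event_date")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("truth table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as_tibble(x)
  x$event_date <- as.Date(x$event_date)
  if (anyDuplicated(x$event_id)) stop("duplicate event_id", call. = FALSE)
  x
}

#' Last calendar day of each patient's follow-up window
#'
#' Follow-up covers the closed-open interval of 730 days starting at the
#' index surgery, ended early by revision, death or emigration; the
#' censoring day itself remains inside the window.
#'
#' @param cohort a validated THA table.
#' @return a `Date` vector, one element per row of `cohort`.
#' @export
follow_up_end <- function(cohort) {
  end <- cohort$index_date + (FOLLOW_UP_DAYS - 1L)
  cens <- !is.na(cohort$censor_date)
  end[cens] <- pmin(end[cens], cohort$censor_date[cens])
  end
}

#' Read and write the package's CSV schemas
#'
#' Comma-separated files with a header row and ISO-8601 dates; the
#' multi-valued contact fields are semicolon-delimited. Missing censoring
#' dates are empty fields.
#'
#' @param path a CSV file path.
#' @return a validated tibble.
#' @export
read_cohort_csv <- function(path) {
  x <- read.csv(path, colClasses = "character", na.strings = character(0))
  x$censor_date[x$censor_date == ""] <- NA
  x$age_at_surgery <- as.integer(x$age_at_surgery)
  validate_tha_table(x)
}

#' @rdname read_cohort_csv
#' @export
read_contacts_csv <- function(path) {
  x <- read.csv(path, colClasses = "character", na.strings = character(0))
  validate_contact_table(x)
}

#' @rdname read_cohort_csv
#' @export
read_truth_csv <- function(path) {
  x <- read.csv(path, colClasses = "character", na.strings = character(0))
  validate_truth_table(x)
}

#' @rdname read_cohort_csv
#' @param x a table conforming to one of the schemas.
#' @export
write_registry_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) {
    if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
  }
  write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
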