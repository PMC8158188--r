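#' Apply the study's inclusion and exclusion rules to a raw THA table
#'
#' Retains one primary THA per patient: THAs for indications other than
#' primary osteoarthritis are excluded, as are patients younger than 40 at
#' surgery; when a patient has more than one remaining THA in the inclusion
#' period only the earliest is kept and the contralateral procedure is
#' logged as excluded, avoiding dependent observations.
#'
#' @param raw_records a data frame with the cohort schema (see
#'   [validate_tha_table()]); may contain several THAs per patient.
#' @return an object of class `tha_cohort`: a list with `records` (the
#'   retained tibble) and `exclusion_log` (tibble of `patient_id`,
#'   `reason`). Every input row lands in exactly one of the two.
#' @examples
#' raw <- tibble::tibble(
#'   patient_id = c("a", "b", "b"),
#'   index_date = as.Date(c("2011-05-01", "2011-03-01", "2013-09-01")),
#'   side = c("left", "left", "right"),
#'   age_at_surgery = c(71L, 64L, 66L),
#'   indication = "primary_OA",
#'   censor_date = as.Date(NA),
#'   censor_reason = "none"
#' )
#' build_cohort(raw)
#' @export
build_cohort <- function(raw_records) {
  x <- validate_tha_table(raw_records)
  if (anyDuplicated(x[c("patient_id", "index_date", "side")])) {
    stop("duplicate (patient_id, index_date, side) rows in THA table",
         call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(x))
  reason[x$indication != "primary_OA"] <- "indication"
  reason[is.na(reason) & x$age_at_surgery < 40L] <- "age<40"
  # among remaining rows, keep the chronologically first THA per patient
  keep <- is.na(reason)
  if (any(keep)) {
    ord <- order(x$patient_id, x$index_date, x$side)
    first <- !duplicated(x$patient_id[ord])
    contralateral <- ord[!first & keep[ord]]
    reason[contralateral] <- "contralateral"
  }
  retained <- is.na(reason)
  structure(
    list(
      records = x[retained, , drop = FALSE],
      exclusion_log = tibble(
        patient_id = x$patient_id[!retained],
        reason = reason[!retained]
      )
    ),
    class = "tha_cohort"
  )
}

#' @export
print.tha_cohort <- function(x, ...) {
  cat(sprintf("<tha_cohort> %d THAs retained, %d excluded\n",
              nrow(x$records), nrow(x$exclusion_log)))
  if (nrow(x$exclusion_log)) {
    print(table(x$exclusion_log$reason))
  }
  invisible(x)
}

#' Restrict hospital contacts to each patient's follow-up window
#'
#' Keeps only contacts admitted between the index surgery (day 0 included —
#' in-admission dislocations exist) and the end of follow-up: two years, or
#' earlier censoring by revision, death or emigration, whichever comes
#' first. Contacts of patients outside the cohort are dropped.
#'
#' @param cohort a `tha_cohort` from [build_cohort()].
#' @param contacts a data frame with the contacts schema.
#' @return a tibble of windowed contacts, ordered by patient, admission
#'   date and contact id (invariant to the input order).
#' @export
window_contacts <- function(cohort, contacts) {
  stopifnot(inherits(cohort, "tha_cohort"))
  contacts <- validate_contact_table(contacts)
  rec <- cohort$records
  win <- tibble(
    patient_id = rec$patient_id,
    .index = rec$index_date,
    .fu_end = follow_up_end(rec)
  )
  out <- inner_join(contacts, win, by = "patient_id")
  out <- out[out$admit_date >= out$.index & out$admit_date <= out$.fu_end, ,
             drop = FALSE]
  out$.index <- NULL
  out$.fu_end <- NULL
  out[order(out$patient_id, out$admit_date, out$contact_id), , drop = FALSE]
}
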