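#' Assign each hospital contact to a diagnostic code group
#'
#' The algorithm sorts contacts into five groups of code combinations,
#' evaluated in order so the lowest-numbered applicable group wins:
#'
#' * group 1 — correct dislocation diagnosis (`DT840`, subcodes included)
#'   together with the correct closed-reduction procedure (`KNFH20`), contact
#'   laterality matching the operated side;
#' * group 2 — correct procedure code alone (any diagnosis), side matching;
#' * group 3 — alternative diagnosis (`DS730`) or alternative procedures
#'   (`KNFH00/02/21/22`), side matching;
#' * group 4 — any group 1–3 code criterion but contact laterality unknown;
#' * group 5 — correct diagnosis alone (no correct procedure), side
#'   matching, restricted to acute admissions or emergency-room contacts.
#'
#' Contacts whose recorded side is opposite to the operated hip never
#' qualify. Diagnoses in either primary or secondary position count.
#'
#' @param contacts windowed contacts (see [window_contacts()]).
#' @param cohort a `tha_cohort`; supplies each patient's operated side.
#' @param codes a [code_set()].
#' @return a tibble `contact_id`, `patient_id`, `group` where `group` is an
#'   integer 1–5 or `NA` for contacts matching no group.
#' @export
assign_groups <- function(contacts, cohort, codes = code_set()) {
  stopifnot(inherits(cohort, "tha_cohort"), inherits(codes, "code_set"))
  contacts <- as_tibble(contacts)
  tha <- tibble(patient_id = cohort$records$patient_id,
                .tha_side = cohort$records$side)
  x <- inner_join(contacts, tha, by = "patient_id")
  if (nrow(x) < nrow(contacts)) {
    stop("contacts include patients outside the cohort; window them first",
         call. = FALSE)
  }

  dx_flags <- code_flags(x$dx_codes, codes[c("correct_dx", "alt_dx")])
  pr_flags <- code_flags(x$proc_codes, codes[c("correct_proc", "alt_proc")])
  has_cdx <- dx_flags$correct_dx
  has_adx <- dx_flags$alt_dx
  has_cpr <- pr_flags$correct_proc
  has_apr <- pr_flags$alt_proc

  side_match <- x$side == x$.tha_side
  side_unknown <- x$side == "unknown"
  acute_or_er <- x$admission_type == "acute" | x$setting == "outpatient_er"
  crit123 <- has_cpr | has_adx | has_apr  # any group 1-3 code criterion

  group <- rep(NA_integer_, nrow(x))
  group[side_match & has_cdx & !has_cpr & acute_or_er] <- 5L
  group[side_unknown & crit123] <- 4L
  group[side_match & (has_adx | has_apr)] <- 3L
  group[side_match & has_cpr] <- 2L
  group[side_match & has_cdx & has_cpr] <- 1L

  tibble(contact_id = x$contact_id, patient_id = x$patient_id, group = group)
}

# per-row "any code in the ;-list matches any prefix of each set"
code_flags <- function(codelists, sets) {
  n <- length(codelists)
  out <- lapply(sets, function(s) rep(FALSE, n))
  nonempty <- which(codelists != "")
  if (!length(nonempty)) return(out)
  parts <- strsplit(codelists[nonempty], ";", fixed = TRUE)
  lens <- lengths(parts)
  row <- rep(nonempty, lens)
  code <- unlist(parts, use.names = FALSE)
  for (nm in names(sets)) {
    hit <- match_any_prefix(code, sets[[nm]])
    if (any(hit)) {
      idx <- unique(row[hit])
      out[[nm]][idx] <- TRUE
    }
  }
  out
}

#' Classify cohort patients by cumulative algorithm step
#'
#' Step k flags a patient when any of their windowed contacts belongs to a
#' group numbered k or lower: step 1 uses group 1 alone, step 2 adds group
#' 2, and so on to step 5. Review-adjusted steps 4A and 5A start as copies
#' of steps 4 and 5; [review_adjust()] applies the chart-review correction.
#'
#' @inheritParams assign_groups
#' @return a `step_classification` tibble with one row per cohort patient:
#'   `patient_id`, `first_step` (lowest qualifying group, `NA` when never
#'   flagged) and logical columns `step1`–`step5`, `step4A`, `step5A`. The
#'   per-contact group assignments are attached as attribute `"qualifying"`.
#' @export
classify_patients <- function(cohort, contacts, codes = code_set()) {
  ga <- assign_groups(contacts, cohort, codes)
  qual <- ga[!is.na(ga$group), , drop = FALSE]
  best <- qual %>%
    group_by(patient_id) %>%
    summarise(first_step = min(group), .groups = "drop")
  out <- tibble(patient_id = cohort$records$patient_id) %>%
    left_join(best, by = "patient_id")
  for (k in 1:5) out[[paste0("step", k)]] <- !is.na(out$first_step) & out$first_step <= k
  out$step4A <- out$step4
  out$step5A <- out$step5
  structure(out,
            qualifying = qual,
            review = character(0),
            class = c("step_classification", class(out)))
}

truth_positive_ids <- function(truth) unique(validate_truth_table(truth)$patient_id)

#' Apply the chart-review adjustment to steps 4A / 5A
#'
#' Steps 4 and 5 admit code combinations weak enough that the published
#' procedure reviews the flagged patient files and discards false
#' positives. Step 4A removes patients flagged solely by unknown-laterality
#' (group 4) contacts who have no verified dislocation; step 5A additionally
#' removes patients flagged solely by group 4 or 5 contacts without a
#' verified event. Review never changes a true positive, so sensitivity is
#' untouched and the adjustment can only raise PPV. Step 5A presupposes the
#' step-4 review, so `scope = "5A"` requires `"4A"` to have been applied.
#'
#' @param classifications a `step_classification`.
#' @param truth the gold-standard event table (real chart review or the
#'   synthetic oracle).
#' @param scope `"4A"` or `"5A"`.
#' @return the adjusted `step_classification`.
#' @export
review_adjust <- function(classifications, truth, scope = c("4A", "5A")) {
  scope <- match.arg(scope)
  stopifnot(inherits(classifications, "step_classification"))
  applied <- attr(classifications, "review")
  if (scope == "5A" && !"4A" %in% applied) {
    stop("review_adjust: scope \"5A\" requires the \"4A\" adjustment first",
         call. = FALSE)
  }
  pos <- truth_positive_ids(truth)
  is_tp <- classifications$patient_id %in% pos
  fs <- classifications$first_step
  if (scope == "4A") {
    drop <- !is_tp & !is.na(fs) & fs == 4L
    classifications$step4A[drop] <- FALSE
  } else {
    drop <- !is_tp & !is.na(fs) & fs >= 4L
    classifications$step5A[drop] <- FALSE
  }
  attr(classifications, "review") <- union(applied, scope)
  classifications
}

#' Event-level detection of individual dislocations
#'
#' The patient-level algorithm targets the risk of dislocation (at least one
#' episode); clinical studies may instead need every episode. Here each
#' verified event is matched to qualifying contacts of the same patient
#' admitted within one day of the event; each contact can confirm at most
#' one event (nearest admission date; for equidistant events the earlier
#' event wins). An event is detected at step k when a matched contact has
#' group k or lower.
#'
#' @param truth the gold-standard event table.
#' @param classifications a `step_classification` (supplies the per-contact
#'   group assignments).
#' @param contacts the windowed contacts used for classification.
#' @return a tibble with one row per truth event: `event_id`, `patient_id`,
#'   `event_date`, `first_step` and logical `step1`–`step5`.
#' @export
classify_events <- function(truth, classifications, contacts) {
  stopifnot(inherits(classifications, "step_classification"))
  truth <- validate_truth_table(truth)
  qual <- attr(classifications, "qualifying")
  dates <- as_tibble(contacts)[, c("contact_id", "admit_date")]
  qual <- inner_join(qual, dates, by = "contact_id")

  pairs <- inner_join(qual, truth, by = "patient_id",
                      relationship = "many-to-many")
  pairs$dist <- abs(as.integer(pairs$admit_date - pairs$event_date))
  pairs <- pairs[pairs$dist <= 1L, , drop = FALSE]
  # one event per contact: nearest date, earlier event breaks ties
  pairs <- pairs[order(pairs$contact_id, pairs$dist, pairs$event_date), ,
                 drop = FALSE]
  pairs <- pairs[!duplicated(pairs$contact_id), , drop = FALSE]

  best <- pairs %>%
    group_by(event_id) %>%
    summarise(first_step = min(group), .groups = "drop")
  out <- truth %>% left_join(best, by = "event_id")
  for (k in 1:5) out[[paste0("step", k)]] <- !is.na(out$first_step) & out$first_step <= k
  out
}
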