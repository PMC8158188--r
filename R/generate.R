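# code pools for generated contacts; none may collide with the default
# code_set prefixes (DT840, KNFH20, DS730, KNFH00/02/21/22)
WRONG_DX_POOL <- c("DS320", "DM2416", "DZ965")        # miscoded dislocations
NUISANCE_DX_POOL <- c("DM160", "DM161", "DM2455", "DR296", "DZ965")
NUISANCE_PROC_POOL <- c("KNGB20", "KWEA00")
ALT_PROC_POOL <- c("KNFH00", "KNFH02", "KNFH21", "KNFH22")

INCLUSION_START <- as.Date("2010-01-01")
INCLUSION_DAYS <- 1825L  # through 2014-12-31

#' Generate a linked synthetic THA registry
#'
#' Emits a cohort table, a hospital-contact table and a truth table whose
#' coding-error structure follows a [calibration_profile()]: each
#' dislocator's episodes receive same-day contacts coded so that the
#' patient's best (lowest-group) qualifying contact corresponds exactly to
#' their assigned detection category; false-positive patients receive one
#' contact of the corresponding group and no true event; the remaining
#' patients get 0-2 contacts with irrelevant codes (including a small
#' fraction of correctly coded contralateral-side contacts, which the
#' laterality rule must ignore). When the profile carries
#' `event_detection_counts`, coding categories are assigned per episode
#' instead of per patient.
#'
#' In `"quota"` mode every category count is hit exactly, making the
#' downstream accuracy table deterministic; in `"sampling"` mode patient
#' categories are drawn multinomially with the corresponding proportions.
#' Output is fully determined by `(profile, seed, mode)`.
#'
#' @param profile a `calibration_profile`.
#' @param seed integer seed for all randomness.
#' @param mode `"quota"` or `"sampling"`.
#' @param out_dir optional directory; when given, `cohort.csv`,
#'   `contacts.csv` and `truth.csv` are written there.
#' @return an object of class `synthetic_registry`: list with tibbles
#'   `cohort`, `contacts`, `truth`, plus `profile`, `seed`, `mode`.
#' @export
generate_registry <- function(profile, seed = 42L, mode = c("quota", "sampling"),
                              out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "calibration_profile"))
  set.seed(as.integer(seed))

  n <- profile$cohort_size
  pid <- sprintf("P%06d", seq_len(n))
  index_date <- INCLUSION_START + sample(0:INCLUSION_DAYS, n, replace = TRUE)
  tha_side <- sample(SIDES, n, replace = TRUE)
  age <- sample(40:94, n, replace = TRUE)

  cens <- runif(n) < profile$censor_fraction
  censor_offset <- rep(NA_integer_, n)
  censor_offset[cens] <- sample(30:729, sum(cens), replace = TRUE)
  censor_reason <- rep("none", n)
  censor_reason[cens] <- sample(c("revision", "death", "emigration"),
                                sum(cens), replace = TRUE)
  censor_date <- as.Date(rep(NA, n))
  censor_date[cens] <- index_date[cens] + censor_offset[cens]
  fu_days <- ifelse(cens, pmin(censor_offset, 729L), 729L)

  cohort <- tibble(
    patient_id = pid, index_date = index_date, side = tha_side,
    age_at_surgery = age, indication = "primary_OA",
    censor_date = censor_date, censor_reason = censor_reason
  )

  # patient statuses: detection categories for dislocators, fp groups,
  # plain negatives
  det_labels <- c(paste0("cat", 1:5), "never")
  fp_labels <- paste0("fp", 1:5)
  det_counts <- unname(profile$detection_category_counts)
  fp_counts <- unname(profile$fp_increment_counts)
  status <- rep("neg", n)
  if (mode == "quota") {
    perm <- sample.int(n)
    take <- sum(det_counts) + sum(fp_counts)
    status[perm[seq_len(take)]] <- rep(c(det_labels, fp_labels),
                                       c(det_counts, fp_counts))
  } else {
    probs <- c(det_counts, fp_counts, n - sum(det_counts) - sum(fp_counts)) / n
    status <- sample(c(det_labels, fp_labels, "neg"), n, replace = TRUE,
                     prob = probs)
  }

  pos_idx <- which(status %in% det_labels)
  npos <- length(pos_idx)

  # episodes per dislocator: truncated shifted geometric; quota mode nudges
  # the draw so the episode total is hit exactly
  mm <- profile$multiplicity$max
  pmf <- trunc_geom_pmf(profile$multiplicity$prob, mm)
  mult <- if (npos) sample(seq_len(mm), npos, replace = TRUE, prob = pmf) else integer(0)
  if (mode == "quota" && npos) {
    delta <- profile$total_events - sum(mult)
    while (delta != 0) {
      if (delta > 0) {
        room <- which(mult < mm)
        pick <- room[sample.int(length(room), min(delta, length(room)))]
        mult[pick] <- mult[pick] + 1L
      } else {
        room <- which(mult > 1L)
        pick <- room[sample.int(length(room), min(-delta, length(room)))]
        mult[pick] <- mult[pick] - 1L
      }
      delta <- profile$total_events - sum(mult)
    }
  }

  ev_patient <- rep(pos_idx, mult)
  ev_day <- unlist(lapply(seq_len(npos), function(j) {
    sort(sample.int(fu_days[pos_idx[j]], mult[j]))
  }), use.names = FALSE)
  if (is.null(ev_day)) ev_day <- integer(0)
  n_events <- length(ev_patient)

  # per-episode coding category
  if (is.null(profile$event_detection_counts)) {
    ev_cat <- status[ev_patient]
  } else {
    inc <- diff(c(0L, unname(profile$event_detection_counts)))
    nev <- profile$total_events - sum(inc)
    if (mode == "quota") {
      ev_cat <- sample(rep(det_labels, c(inc, nev)))
    } else {
      ev_cat <- sample(det_labels, n_events, replace = TRUE,
                       prob = c(inc, nev) / profile$total_events)
    }
  }

  ev_payload <- contact_payload(ev_cat, tha_side[ev_patient])
  ev_contacts <- tibble(
    patient_id = pid[ev_patient],
    admit_date = index_date[ev_patient] + ev_day,
    specialty = "orthopedic",
    dx_positions = "primary",
    ev_payload
  )

  # false-positive patients: one qualifying contact, no true event
  fp_idx <- which(status %in% fp_labels)
  fp_cat <- sub("^fp", "cat", status[fp_idx])
  fp_day <- 1L + floor(runif(length(fp_idx)) * fu_days[fp_idx])
  fp_payload <- contact_payload(fp_cat, tha_side[fp_idx])
  fp_contacts <- tibble(
    patient_id = pid[fp_idx],
    admit_date = index_date[fp_idx] + fp_day,
    specialty = "orthopedic",
    dx_positions = "primary",
    fp_payload
  )

  # nuisance contacts for the remaining negatives
  neg_idx <- which(status == "neg")
  k <- sample(0:2, length(neg_idx), replace = TRUE, prob = c(0.45, 0.35, 0.20))
  nu_idx <- rep(neg_idx, k)
  nn <- length(nu_idx)
  nu_day <- 1L + floor(runif(nn) * fu_days[nu_idx])
  decoy <- runif(nn) < 0.02  # correct codes on the contralateral side
  nu_side <- ifelse(runif(nn) < profile$unknown_side_fraction, "unknown",
                    sample(SIDES, nn, replace = TRUE))
  nu_side[decoy] <- ifelse(tha_side[nu_idx[decoy]] == "left", "right", "left")
  nu_dx <- sample(NUISANCE_DX_POOL, nn, replace = TRUE)
  nu_proc <- sample(c("", "", NUISANCE_PROC_POOL), nn, replace = TRUE)
  nu_dx[decoy] <- "DT840"
  nu_proc[decoy] <- "KNFH20"
  nu_adm <- ifelse(runif(nn) < profile$acute_fraction | decoy,
                   "acute", "elective")
  nu_set <- ifelse(nu_adm == "acute",
                   sample(c("inpatient", "outpatient_er"), nn, replace = TRUE),
                   "outpatient_clinic")
  nu_contacts <- tibble(
    patient_id = pid[nu_idx],
    admit_date = index_date[nu_idx] + nu_day,
    specialty = sample(SPECIALTIES, nn, replace = TRUE, prob = c(0.7, 0.3)),
    dx_positions = sample(c("primary", "secondary"), nn, replace = TRUE),
    dx_codes = nu_dx, proc_codes = nu_proc, side = nu_side,
    admission_type = nu_adm, setting = nu_set
  )

  contacts <- bind_rows(ev_contacts, fp_contacts, nu_contacts)
  stay <- ifelse(contacts$setting == "inpatient",
                 sample(0:3, nrow(contacts), replace = TRUE), 0L)
  contacts$discharge_date <- contacts$admit_date + stay
  contacts$proc_dates <- ifelse(contacts$proc_codes == "",
                                "", format(contacts$admit_date, "%Y-%m-%d"))
  ord <- order(contacts$patient_id, contacts$admit_date,
               contacts$dx_codes, contacts$proc_codes)
  contacts <- contacts[ord, , drop = FALSE]
  contacts$contact_id <- sprintf("C%06d", seq_len(nrow(contacts)))
  contacts <- contacts[, c("patient_id", "contact_id", "admit_date",
                           "discharge_date", "specialty", "admission_type",
                           "setting", "side", "dx_codes", "dx_positions",
                           "proc_codes", "proc_dates")]

  truth <- tibble(patient_id = pid[ev_patient],
                  event_date = index_date[ev_patient] + ev_day)
  truth <- truth[order(truth$patient_id, truth$event_date), , drop = FALSE]
  truth$event_id <- sprintf("E%05d", seq_len(nrow(truth)))
  truth <- truth[, c("patient_id", "event_id", "event_date")]

  out <- structure(
    list(cohort = cohort, contacts = contacts, truth = truth,
         profile = profile, seed = as.integer(seed), mode = mode),
    class = "synthetic_registry"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_registry_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_registry_csv(contacts, file.path(out_dir, "contacts.csv"))
    write_registry_csv(truth, file.path(out_dir, "truth.csv"))
  }
  out
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf(
    "<synthetic_registry> %s mode, seed %d: %d THAs, %d contacts, %d events\n",
    x$mode, x$seed, nrow(x$cohort), nrow(x$contacts), nrow(x$truth)))
  invisible(x)
}

# coded fields of an event / false-positive contact for each detection
# category; the category is the lowest group the contact must realize
contact_payload <- function(cat, tha_side) {
  m <- length(cat)
  dx <- character(m)
  proc <- rep("", m)
  side <- tha_side
  adm <- rep("acute", m)
  set <- rep("inpatient", m)

  i <- cat == "cat1"
  dx[i] <- sample(c("DT840", "DT840A"), sum(i), replace = TRUE, prob = c(0.7, 0.3))
  proc[i] <- "KNFH20"

  i <- cat == "cat2"  # correct procedure, wrong diagnosis
  dx[i] <- sample(WRONG_DX_POOL, sum(i), replace = TRUE)
  proc[i] <- "KNFH20"

  i <- cat == "cat3"  # alternative diagnosis or alternative procedure
  v <- runif(sum(i)) < 0.5
  dx[i] <- ifelse(v, "DS730", sample(WRONG_DX_POOL, sum(i), replace = TRUE))
  proc[i] <- ifelse(v, "", sample(ALT_PROC_POOL, sum(i), replace = TRUE))

  i <- cat == "cat4"  # group 1-3 codes, laterality not recorded
  side[i] <- "unknown"
  sub <- sample(3L, sum(i), replace = TRUE)
  dx[i] <- c("DT840", "DS320", "DS730")[sub]
  proc[i] <- c("KNFH20", "KNFH20", "")[sub]

  i <- cat == "cat5"  # correct diagnosis alone, acute / emergency room
  dx[i] <- sample(c("DT840", "DT840A"), sum(i), replace = TRUE, prob = c(0.7, 0.3))
  set[i] <- sample(c("inpatient", "outpatient_er"), sum(i), replace = TRUE)

  i <- cat == "never"  # episode whose contact never received usable codes
  dx[i] <- sample(NUISANCE_DX_POOL, sum(i), replace = TRUE)
  adm[i] <- "elective"
  set[i] <- "outpatient_clinic"

  tibble(dx_codes = dx, proc_codes = proc, side = side,
         admission_type = adm, setting = set)
}
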