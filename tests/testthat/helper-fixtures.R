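# in-code fixtures: tiny builders with sensible defaults

make_tha <- function(patient_id = "p1", index_date = "2011-06-01",
                     side = "left", age_at_surgery = 70L,
                     indication = "primary_OA", censor_date = NA,
                     censor_reason = "none") {
  tibble::tibble(
    patient_id = patient_id, index_date = as.Date(index_date), side = side,
    age_at_surgery = as.integer(age_at_surgery), indication = indication,
    censor_date = as.Date(censor_date), censor_reason = censor_reason
  )
}

make_contact <- function(patient_id = "p1", contact_id = "c1",
                         admit_date = "2011-07-01", discharge_date = NULL,
                         specialty = "orthopedic", admission_type = "acute",
                         setting = "inpatient", side = "left",
                         dx_codes = "", dx_positions = "",
                         proc_codes = "", proc_dates = "") {
  tibble::tibble(
    patient_id = patient_id, contact_id = contact_id,
    admit_date = as.Date(admit_date),
    discharge_date = as.Date(discharge_date %||% admit_date),
    specialty = specialty, admission_type = admission_type,
    setting = setting, side = side, dx_codes = dx_codes,
    dx_positions = dx_positions, proc_codes = proc_codes,
    proc_dates = proc_dates
  )
}

make_truth <- function(patient_id = "p1", event_id = NULL,
                       event_date = "2011-07-01") {
  n <- max(length(patient_id), length(event_date))
  tibble::tibble(
    patient_id = patient_id,
    event_id = event_id %||% sprintf("e%02d", seq_len(n)),
    event_date = as.Date(event_date)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a one-contact classification for a single-patient cohort, used by the
# group-assignment tests
single_contact_group <- function(contact, tha = make_tha(),
                                 codes = code_set()) {
  cohort <- build_cohort(tha)
  assign_groups(contact, cohort, codes)$group
}

# randomized small registry with messy coding, used by property tests:
# contacts carry arbitrary mixes of qualifying and irrelevant codes
random_small_registry <- function(seed, n_patients = 25, n_contacts = 40) {
  set.seed(seed)
  pid <- sprintf("p%02d", seq_len(n_patients))
  cohort_tbl <- tibble::tibble(
    patient_id = pid,
    index_date = as.Date("2011-01-01") + sample(0:300, n_patients, TRUE),
    side = sample(c("left", "right"), n_patients, TRUE),
    age_at_surgery = sample(40:90, n_patients, TRUE),
    indication = "primary_OA",
    censor_date = as.Date(NA), censor_reason = "none"
  )
  dx_pool <- c("DT840", "DT840A", "DS730", "DS320", "DM160", "DZ965", "")
  proc_pool <- c("KNFH20", "KNFH00", "KNFH21", "KNGB20", "", "")
  row <- sample(n_patients, n_contacts, TRUE)
  contacts <- tibble::tibble(
    patient_id = pid[row],
    contact_id = sprintf("c%03d", seq_len(n_contacts)),
    admit_date = cohort_tbl$index_date[row] + sample(0:700, n_contacts, TRUE),
    specialty = sample(c("orthopedic", "other"), n_contacts, TRUE),
    admission_type = sample(c("acute", "elective"), n_contacts, TRUE),
    setting = sample(c("inpatient", "outpatient_er", "outpatient_clinic"),
                     n_contacts, TRUE),
    side = sample(c("left", "right", "unknown"), n_contacts, TRUE),
    dx_codes = sample(dx_pool, n_contacts, TRUE),
    dx_positions = "primary",
    proc_codes = sample(proc_pool, n_contacts, TRUE),
    proc_dates = ""
  )
  contacts$discharge_date <- contacts$admit_date
  n_pos <- sample(0:8, 1)
  pos <- sample(pid, n_pos)
  truth <- if (n_pos) {
    idx <- match(pos, pid)
    tibble::tibble(
      patient_id = pos,
      event_id = sprintf("e%02d", seq_len(n_pos)),
      event_date = cohort_tbl$index_date[idx] + sample(1:700, n_pos, TRUE)
    )
  } else {
    make_truth(character(0), character(0), as.Date(character(0)))
  }
  list(cohort = build_cohort(cohort_tbl), contacts = contacts, truth = truth)
}

# small calibration profile for fast generator tests
small_profile <- function(cohort_size = 500, positives = 40,
                          total_events = 70,
                          det = c(step1 = 14, step2 = 8, step3 = 6,
                                  step4 = 5, step5 = 4, never = 3),
                          fpi = c(step1 = 2, step2 = 2, step3 = 1,
                                  step4 = 3, step5 = 5), ...) {
  calibration_profile(
    cohort_size = cohort_size, positives = positives,
    total_events = total_events,
    detection_category_counts = det, fp_increment_counts = fpi, ...
  )
}
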