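test_that("contacts are assigned to the five code groups as defined", {
  # correct diagnosis + correct procedure, matching side
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DT840A", proc_codes = "KNFH20")), 1L)
  # correct procedure with an unrelated diagnosis
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DS320", proc_codes = "KNFH20")), 2L)
  # alternative diagnosis, side recorded
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DS730")), 3L)
  # alternative procedure alone also qualifies for group 3
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DM160", proc_codes = "KNFH21")), 3L)
  # group 1-3 codes with unknown laterality fall to group 4
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DS730", side = "unknown")), 4L)
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DT840", proc_codes = "KNFH20",
                 side = "unknown")), 4L)
  # correct diagnosis alone: only acute admissions / ER contacts
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DT840", admission_type = "acute")), 5L)
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DT840", admission_type = "elective",
                 setting = "outpatient_er")), 5L)
  expect_true(is.na(single_contact_group(
    make_contact(dx_codes = "DT840", admission_type = "elective",
                 setting = "outpatient_clinic"))))
  # no qualifying codes
  expect_true(is.na(single_contact_group(
    make_contact(dx_codes = "DM160", proc_codes = "KNGB20"))))
  # opposite-side contacts never qualify, even with perfect codes
  expect_true(is.na(single_contact_group(
    make_contact(dx_codes = "DT840", proc_codes = "KNFH20",
                 side = "right"))))
  # unknown-side DT840-alone contact is not group 4 (not a group 1-3 criterion)
  expect_true(is.na(single_contact_group(
    make_contact(dx_codes = "DT840", side = "unknown"))))
  # secondary-position diagnoses qualify too
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DM160;DT840", dx_positions = "primary;secondary",
                 proc_codes = "KNFH20")), 1L)
})

test_that("each contact gets exactly one group and the lowest applicable wins", {
  # satisfies groups 1, 2, 3 and 5 simultaneously -> group 1
  expect_equal(single_contact_group(
    make_contact(dx_codes = "DT840;DS730", dx_positions = "primary;secondary",
                 proc_codes = "KNFH20;KNFH21")), 1L)
  ga <- assign_groups(
    dplyr::bind_rows(
      make_contact(contact_id = "c1", dx_codes = "DT840", proc_codes = "KNFH20"),
      make_contact(contact_id = "c2", dx_codes = "DS730", proc_codes = "KNFH20")
    ),
    build_cohort(make_tha()))
  expect_equal(nrow(ga), 2)           # a partition: one label per contact
  expect_equal(ga$group, c(1L, 2L))
})

test_that("cumulative step flags follow the lowest qualifying group", {
  cohort <- build_cohort(dplyr::bind_rows(
    make_tha("g3"), make_tha("none"), make_tha("g1")))
  contacts <- dplyr::bind_rows(
    make_contact("g3", "c1", dx_codes = "DS730"),
    make_contact("g1", "c2", dx_codes = "DT840", proc_codes = "KNFH20")
  )
  cls <- classify_patients(cohort, contacts)
  g3 <- cls[cls$patient_id == "g3", ]
  expect_false(g3$step1 || g3$step2)
  expect_true(g3$step3 && g3$step4 && g3$step5)
  expect_true(all(cls[cls$patient_id == "g1",
                      paste0("step", 1:5)] == TRUE))
  expect_true(all(cls[cls$patient_id == "none",
                      paste0("step", 1:5)] == FALSE))
  # 4A/5A start as copies of 4/5
  expect_identical(cls$step4A, cls$step4)
  expect_identical(cls$step5A, cls$step5)
})

test_that("detection is monotone over steps on arbitrary messy registries", {
  for (seed in 1:8) {
    reg <- random_small_registry(seed)
    win <- window_contacts(reg$cohort, reg$contacts)
    cls <- classify_patients(reg$cohort, win)
    for (k in 2:5) {
      expect_true(all(cls[[paste0("step", k - 1)]] <= cls[[paste0("step", k)]]),
                  info = paste("seed", seed, "step", k))
    }
  }
})

test_that("review adjustment discards only group-4/5-solely false positives", {
  cohort <- build_cohort(dplyr::bind_rows(
    make_tha("fp4"), make_tha("tp4"), make_tha("fp2"), make_tha("fp5")))
  contacts <- dplyr::bind_rows(
    make_contact("fp4", "c1", dx_codes = "DS730", side = "unknown"),
    make_contact("tp4", "c2", dx_codes = "DS730", side = "unknown"),
    make_contact("fp2", "c3", dx_codes = "DS320", proc_codes = "KNFH20"),
    make_contact("fp5", "c4", dx_codes = "DT840", admission_type = "acute")
  )
  truth <- make_truth("tp4", event_date = "2011-07-01")
  cls <- classify_patients(cohort, contacts)
  expect_error(review_adjust(cls, truth, "5A"), "4A")

  adj <- review_adjust(cls, truth, "4A")
  row <- function(x, p) x[x$patient_id == p, ]
  expect_false(row(adj, "fp4")$step4A)   # false positive discarded
  expect_true(row(adj, "fp4")$step4)     # unreviewed step untouched
  expect_true(row(adj, "tp4")$step4A)    # true positives never removed
  expect_true(row(adj, "fp2")$step4A)    # outside review scope
  adj <- review_adjust(adj, truth, "5A")
  expect_false(row(adj, "fp4")$step5A)
  expect_false(row(adj, "fp5")$step5A)
  expect_true(row(adj, "fp2")$step5A)
})

test_that("review adjustment never changes sensitivity and never lowers PPV", {
  for (seed in 11:16) {
    reg <- random_small_registry(seed)
    if (nrow(reg$truth) == 0) next
    win <- window_contacts(reg$cohort, reg$contacts)
    cls <- classify_patients(reg$cohort, win)
    adj <- review_adjust(review_adjust(cls, reg$truth, "4A"),
                         reg$truth, "5A")
    for (s in c("4A", "5A")) {
      base <- confusion(cls, reg$truth, sub("A", "", s))
      rev <- confusion(adj, reg$truth, s)
      expect_equal(rev$tp, base$tp, info = paste("seed", seed, s))
      expect_lte(rev$fp, base$fp)
      if (base$tp + base$fp > 0 && rev$tp + rev$fp > 0) {
        expect_gte(rev$tp / (rev$tp + rev$fp), base$tp / (base$tp + base$fp))
      }
    }
  }
})

test_that("events are matched to contacts within one day, one event per contact", {
  cohort <- build_cohort(make_tha())
  idx <- as.Date("2011-06-01")
  contacts <- dplyr::bind_rows(
    make_contact(contact_id = "same_day", admit_date = idx + 10,
                 dx_codes = "DT840", proc_codes = "KNFH20"),
    make_contact(contact_id = "far", admit_date = idx + 60,
                 dx_codes = "DT840", proc_codes = "KNFH20")
  )
  truth <- make_truth(rep("p1", 3), event_date = idx + c(10, 30, 50))
  cls <- classify_patients(cohort, contacts)
  ev <- classify_events(truth, cls, contacts)
  # day-10 event matched at step 1; day-30 unmatched; day-50 contact is 10
  # days away, outside the +/-1-day match window
  expect_equal(ev$step1, c(TRUE, FALSE, FALSE))
  expect_equal(sum(ev$step5), 1)
})

test_that("an equidistant contact resolves to the earlier event", {
  cohort <- build_cohort(make_tha())
  idx <- as.Date("2011-06-01")
  contacts <- make_contact(contact_id = "between", admit_date = idx + 11,
                           dx_codes = "DT840", proc_codes = "KNFH20")
  truth <- make_truth(rep("p1", 2), event_date = idx + c(10, 12))
  cls <- classify_patients(cohort, contacts)
  ev <- classify_events(truth, cls, contacts)
  expect_equal(ev$step1, c(TRUE, FALSE))
})

test_that("a patient-level detection implies a detected event on generated data", {
  reg <- generate_registry(small_profile(), seed = 5, mode = "quota")
  cohort <- build_cohort(reg$cohort)
  win <- window_contacts(cohort, reg$contacts)
  cls <- classify_patients(cohort, win)
  ev <- classify_events(reg$truth, cls, win)
  pos <- unique(reg$truth$patient_id)
  for (k in 1:5) {
    flagged <- cls$patient_id[cls[[paste0("step", k)]] &
                                cls$patient_id %in% pos]
    detected <- unique(ev$patient_id[ev[[paste0("step", k)]]])
    expect_true(all(flagged %in% detected), info = paste("step", k))
  }
})
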