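classify_all_negative <- function(n_pos, n_neg) {
  # minimal step_classification with every patient unflagged
  ids <- c(sprintf("pos%d", seq_len(n_pos)), sprintf("neg%d", seq_len(n_neg)))
  out <- tibble::tibble(patient_id = ids, first_step = NA_integer_)
  for (s in c(paste0("step", 1:5), "step4A", "step5A")) out[[s]] <- FALSE
  structure(out, qualifying = tibble::tibble(
    contact_id = character(0), patient_id = character(0), group = integer(0)),
    review = character(0),
    class = c("step_classification", class(out)))
}

test_that("confusion tables cross-tabulate detection against the gold standard", {
  cls <- classify_all_negative(3, 7)
  truth <- make_truth(sprintf("pos%d", 1:3))
  ct <- confusion(cls, truth, 1)
  expect_equal(unlist(ct[c("tp", "fp", "tn", "fn")]),
               c(tp = 0L, fp = 0L, tn = 7L, fn = 3L))

  cls$step2[cls$patient_id %in% truth$patient_id] <- TRUE  # perfect at step 2
  ct2 <- confusion(cls, truth, 2)
  expect_equal(ct2$fp + ct2$fn, 0L)

  expect_error(confusion(cls, make_truth("stranger"), 1), "missing")
})

test_that("confusion cells always sum to the cohort size (exhaustive n <= 6)", {
  for (n in 1:6) {
    grid <- expand.grid(replicate(2 * n, c(FALSE, TRUE), simplify = FALSE))
    # subsample the larger grids to keep the loop quick but exhaustive at n<=3
    rows <- if (nrow(grid) > 256) seq(1, nrow(grid), length.out = 256) else seq_len(nrow(grid))
    for (i in round(rows)) {
      lab <- unlist(grid[i, seq_len(n)])
      flag <- unlist(grid[i, n + seq_len(n)])
      cls <- classify_all_negative(0, n)
      cls$step1 <- flag
      truth <- make_truth(cls$patient_id[lab],
                          event_date = rep("2011-07-01", sum(lab)))
      ct <- confusion(cls, truth, 1)
      expect_equal(ct$tp + ct$fp + ct$tn + ct$fn, n)
      expect_equal(ct$tp + ct$fn, sum(lab))
      expect_equal(ct$tp, sum(lab & flag))
    }
  }
})

test_that("accuracy reproduces the validation-study step-1 row from its counts", {
  acc <- accuracy(confusion_table(tp = 686, fp = 15, tn = 30653, fn = 408))
  row <- function(m) acc[acc$metric == m, ]
  expect_equal(row("sensitivity")$estimate, 62.7)
  expect_equal(row("sensitivity")$lower, 59.8)
  expect_equal(row("sensitivity")$upper, 65.6)
  expect_equal(row("ppv")$estimate, 97.9)
  expect_equal(row("npv")$estimate, 98.7)
  # 30653/30668 = 99.951%: half-up rounding carries this to 100.0 (the
  # published table shows 99.9 for this cell, a truncation artifact)
  expect_equal(row("specificity")$estimate, 100.0)
})

test_that("accuracy handles boundary and degenerate tables", {
  acc <- accuracy(confusion_table(tp = 1, fp = 0, tn = 1, fn = 0))
  expect_equal(acc$estimate[acc$metric == "sensitivity"], 100)
  expect_equal(acc$estimate[acc$metric == "specificity"], 100)

  acc0 <- accuracy(confusion_table(tp = 0, fp = 0, tn = 1, fn = 1))
  expect_equal(acc0$estimate[acc0$metric == "sensitivity"], 0)
  expect_equal(acc0$lower[acc0$metric == "sensitivity"], 0)
  expect_true(is.na(acc0$estimate[acc0$metric == "ppv"]))  # 0 denominator

  expect_error(accuracy(confusion_table(0, 0, 0, 0)), "empty")
  expect_error(accuracy(confusion_table(tp = 0, fp = 1, tn = 1, fn = 0)),
               "undefined")
})

test_that("Clopper-Pearson intervals keep at least nominal coverage", {
  set.seed(202)
  for (n in c(20, 1094)) {
    for (p in c(0.05, 0.627, 0.954)) {
      x <- rbinom(2000, n, p)
      ci <- clopper_pearson(x, n)
      coverage <- mean(ci$lower <= p & p <= ci$upper)
      expect_gte(coverage, 0.945)
    }
  }
})

test_that("implied-count reconstruction inverts printed percentages", {
  P <- 1094; N <- 30668
  s1 <- reconstruct_implied_counts(62.7, 97.9, P, N)
  expect_equal(s1$tp, 686)
  expect_equal(s1$fp, 15)
  expect_false(s1$ambiguous)

  s4 <- reconstruct_implied_counts(91.3, 93.3, P, N)
  expect_equal(c(s4$tp, s4$fp), c(999, 72))

  s5 <- reconstruct_implied_counts(95.4, 81.8, P, N)
  expect_equal(s5$tp, 1044)
  expect_equal(s5$fp_candidates, c(232, 233))  # flagged ambiguous
  expect_true(s5$ambiguous)
  expect_equal(s5$fp, 232)                     # smallest admissible

  # the printed step-2 pair is inconsistent at 1-decimal precision
  expect_error(reconstruct_implied_counts(77.0, 96.5, P, N), "inconsistent")
  s2 <- reconstruct_implied_counts(77.0, 96.5, P, N, on_empty = "nearest")
  expect_equal(c(s2$tp, s2$fp), c(842, 31))
  expect_false(s2$exact)

  # coarse printed precision leaves tp ambiguous on huge denominators
  expect_error(reconstruct_implied_counts(50.0, 90.0, 10000, 10), "uniquely")
  # and some printed values are unattainable outright
  expect_error(reconstruct_implied_counts(50.0, 90.0, 3, 10), "no integer tp")
})

test_that("reconstruction matches an independent brute-force scan on a toy table", {
  # independent oracle: plain double loop with its own rounding
  P <- 10; N <- 100
  tp_true <- 7; fp_true <- 3
  printed_sens <- floor(1000 * tp_true / P + 0.5) / 10
  printed_ppv <- floor(1000 * tp_true / (tp_true + fp_true) + 0.5) / 10
  hits <- list()
  for (tp in 0:P) for (fp in 0:N) {
    if (floor(1000 * tp / P + 0.5) / 10 == printed_sens &&
        floor(1000 * tp / (tp + fp) + 0.5) / 10 == printed_ppv) {
      hits[[length(hits) + 1]] <- c(tp, fp)
    }
  }
  hits <- do.call(rbind, hits)
  r <- reconstruct_implied_counts(printed_sens, printed_ppv, P, N)
  expect_equal(unique(hits[, 1]), r$tp)
  expect_setequal(hits[, 2], r$fp_candidates)
  expect_true(fp_true %in% r$fp_candidates)
})

test_that("accuracy round-trips the reconstructed counts to the printed values", {
  ref <- reference_accuracy_table()
  rc <- reconstruct_step_counts()
  for (i in seq_len(nrow(rc))) {
    acc <- accuracy(confusion_table(tp = rc$tp[i], fp = rc$fp[i],
                                    tn = rc$tn[i], fn = rc$fn[i]))
    printed <- ref[ref$step == rc$step[i], ]
    expect_equal(acc$estimate[acc$metric == "sensitivity"],
                 printed$sensitivity, info = rc$step[i])
    expect_equal(acc$estimate[acc$metric == "npv"], printed$npv,
                 info = rc$step[i])
    if (rc$exact[i]) {
      expect_equal(acc$estimate[acc$metric == "ppv"], printed$ppv,
                   info = rc$step[i])
    }
  }
})

test_that("crude incidence is the dislocator fraction of the cohort", {
  cohort <- build_cohort(dplyr::bind_rows(lapply(
    sprintf("p%03d", 1:100), function(p) make_tha(p))))
  truth <- make_truth(sprintf("p%03d", 1:5),
                      event_date = rep("2011-07-01", 5))
  inc <- incidence(cohort, truth)
  expect_equal(inc$percent, 5.0)
  expect_equal(inc$numerator, 5)
  expect_equal(inc$denominator, 100)
  expect_equal(incidence(cohort, make_truth(character(0), character(0),
                                            as.Date(character(0))))$percent, 0)
  empty <- build_cohort(make_tha(character(0), as.Date(character(0)),
                                 character(0), integer(0), character(0),
                                 as.Date(character(0)), character(0)))
  expect_error(incidence(empty, truth), "empty cohort")
})

test_that("review burden counts the patients added by steps 4 and 5", {
  cohort <- build_cohort(dplyr::bind_rows(
    make_tha("a"), make_tha("b"), make_tha("c")))
  contacts <- dplyr::bind_rows(
    make_contact("a", "c1", dx_codes = "DT840", proc_codes = "KNFH20"),
    make_contact("b", "c2", dx_codes = "DS730", side = "unknown"),
    make_contact("c", "c3", dx_codes = "DT840", admission_type = "acute")
  )
  cls <- classify_patients(cohort, contacts)
  expect_equal(review_burden(cls, "4A")$patients, 1)
  expect_equal(review_burden(cls, "5A")$patients, 2)
  # burden(5A) >= burden(4A) always; zero when nothing is added late
  cls1 <- classify_patients(cohort, contacts[1, ])
  expect_equal(review_burden(cls1, "4A")$patients, 0)
  expect_equal(review_burden(cls1, "5A")$patients, 0)
})
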