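#' Published step-wise accuracy of the dislocation algorithm
#'
#' The accuracy table reported for the algorithm's validation cohort of
#' 31,762 primary-osteoarthritis THAs, of which 1,094 had at least one of
#' 1,890 verified dislocations within two years: percentage point
#' estimates (95% CI bounds) for each cumulative step, as printed at one
#' decimal. These published values are the calibration input for
#' [reconstruct_implied_counts()] and [default_profile()].
#'
#' @return a tibble with columns `step`, `sensitivity`, `sens_lower`,
#'   `sens_upper`, `specificity`, `spec_lower`, `spec_upper`, `ppv`,
#'   `ppv_lower`, `ppv_upper`, `npv`, `npv_lower`, `npv_upper`.
#' @export
reference_accuracy_table <- function() {
  tibble(
    step = c("1", "2", "3", "4", "4A", "5", "5A"),
    sensitivity = c(62.7, 77.0, 85.1, 91.3, 91.3, 95.4, 95.4),
    sens_lower  = c(59.8, 74.4, 82.9, 89.5, 89.5, 93.9, 93.9),
    sens_upper  = c(65.6, 79.4, 87.2, 92.9, 92.9, 96.5, 96.5),
    specificity = c(99.9, 99.9, 99.9, 99.8, 99.9, 99.2, 99.8),
    spec_lower  = c(99.9, 99.9, 99.8, 99.7, 99.8, 99.1, 99.8),
    spec_upper  = c(99.9, 99.9, 99.9, 99.8, 99.9, 99.3, 99.9),
    ppv         = c(97.9, 96.5, 96.3, 93.3, 96.5, 81.8, 96.6),
    ppv_lower   = c(96.5, 95.0, 94.9, 91.6, 95.2, 79.4, 95.4),
    ppv_upper   = c(98.8, 97.6, 97.4, 94.7, 97.6, 83.7, 97.7),
    npv         = c(98.7, 99.2, 99.5, 99.7, 99.7, 99.8, 99.8),
    npv_lower   = c(98.6, 99.1, 99.4, 99.6, 99.6, 99.8, 99.8),
    npv_upper   = c(98.8, 99.3, 99.5, 99.7, 99.7, 99.9, 99.9)
  )
}

#' Validation-cohort size constants behind the published table
#'
#' @return a list with `cohort_size` (31,762 THAs), `positives` (1,094
#'   patients with at least one dislocation), `negatives` and
#'   `total_events` (1,890 dislocation episodes).
#' @export
reference_cohort_counts <- function() {
  list(cohort_size = 31762L, positives = 1094L,
       negatives = 31762L - 1094L, total_events = 1890L)
}

#' Reconstruct the integer confusion table implied by printed percentages
#'
#' A published accuracy row reports sensitivity and PPV rounded to one
#' decimal; given the numbers of true positives `P` and true negatives `N`
#' in the cohort, the underlying integer counts can usually be recovered:
#' `tp` is the (required unique) count whose rounded sensitivity matches,
#' and `fp` ranges over every count whose rounded PPV matches. Several
#' `fp` may qualify (the row is flagged ambiguous) or none may (the
#' printed row is inconsistent at the stated precision).
#'
#' @param sensitivity,ppv printed percentages at `digits` decimals.
#' @param positives,negatives cohort truth margins (`P`, `N`).
#' @param digits printed precision (default 1).
#' @param on_empty behaviour when no integer `fp` reproduces the printed
#'   PPV: `"error"` (default) or `"nearest"`, which returns the `fp`
#'   whose unrounded PPV is closest to the printed value and flags the
#'   row inexact.
#' @return a list: `tp`, `fp` (smallest admissible), `fn`, `tn`,
#'   `fp_candidates`, `ambiguous`, `exact`, and a `confusion_table` in
#'   `$table`.
#' @export
reconstruct_implied_counts <- function(sensitivity, ppv, positives, negatives,
                                       digits = 1,
                                       on_empty = c("error", "nearest")) {
  on_empty <- match.arg(on_empty)
  P <- as.integer(positives)
  N <- as.integer(negatives)
  tp_all <- 0:P
  tp <- tp_all[round_half_up(100 * tp_all / P, digits) == sensitivity]
  if (length(tp) == 0) {
    stop(sprintf("no integer tp in 0..%d yields sensitivity %.*f", P,
                 digits, sensitivity), call. = FALSE)
  }
  if (length(tp) > 1) {
    stop(sprintf("sensitivity %.*f does not determine tp uniquely (%s)",
                 digits, sensitivity, paste(tp, collapse = ", ")),
         call. = FALSE)
  }
  fp_all <- 0:N
  ppv_of <- 100 * tp / (tp + fp_all)
  fp <- fp_all[round_half_up(ppv_of, digits) == ppv]
  exact <- length(fp) > 0
  if (!exact) {
    if (on_empty == "error") {
      stop(sprintf(
        "no integer fp yields PPV %.*f with tp = %d: printed row is %s",
        digits, ppv, tp, "inconsistent at the stated precision"),
        call. = FALSE)
    }
    fp <- fp_all[which.min(abs(ppv_of - ppv))]
  }
  list(
    tp = tp, fp = min(fp), fn = P - tp, tn = N - min(fp),
    fp_candidates = fp, ambiguous = length(fp) > 1, exact = exact,
    table = confusion_table(tp = tp, fp = min(fp), tn = N - min(fp),
                            fn = P - tp)
  )
}

#' Reconstruct implied counts for every step of a printed accuracy table
#'
#' Applies [reconstruct_implied_counts()] row-wise. For the published table
#' use the defaults; the step-2 row's printed PPV is known to admit no
#' exact integer solution, so `on_empty = "nearest"` is the default here.
#'
#' @param table a printed accuracy table, by default
#'   [reference_accuracy_table()] restricted to the unadjusted steps 1-5.
#' @param positives,negatives cohort truth margins.
#' @inheritParams reconstruct_implied_counts
#' @return a tibble with one row per step: `step`, `tp`, `fp`, `fn`, `tn`,
#'   `ambiguous`, `exact`.
#' @export
reconstruct_step_counts <- function(table = NULL,
                                    positives = reference_cohort_counts()$positives,
                                    negatives = reference_cohort_counts()$negatives,
                                    digits = 1, on_empty = "nearest") {
  if (is.null(table)) {
    table <- reference_accuracy_table()
    table <- table[table$step %in% as.character(1:5), ]
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- reconstruct_implied_counts(table$sensitivity[i], table$ppv[i],
                                    positives, negatives, digits, on_empty)
    tibble(step = table$step[i], tp = r$tp, fp = r$fp, fn = r$fn, tn = r$tn,
           ambiguous = r$ambiguous, exact = r$exact)
  })
  bind_rows(rows)
}
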