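#' Round half away from zero
#'
#' Presentation rounding used for all reported percentages: halves round
#' up (`96.45` to `96.5`), matching how the accuracy tables are printed,
#' unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5 + 1e-9) / m
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval: lower bound
#' `qbeta(a/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x successes (vectorized).
#' @param n trials.
#' @param conf_level confidence level, default 0.95.
#' @return a list with numeric vectors `lower` and `upper` on the
#'   proportion scale.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(all(x >= 0), all(x <= n), all(n > 0))
  a <- (1 - conf_level) / 2
  lower <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  list(lower = lower, upper = upper)
}

#' Patient-level confusion table at a given algorithm step
#'
#' Cross-tabulates the step's detection flag against the gold standard
#' (at least one verified dislocation event versus none).
#'
#' @param classifications a `step_classification` covering the whole cohort.
#' @param truth gold-standard event table; every truth patient must appear
#'   in `classifications`.
#' @param step one of `1:5`, `"4A"`, `"5A"`.
#' @return an object of class `confusion_table`: list with integer `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(classifications, truth, step) {
  stopifnot(inherits(classifications, "step_classification"))
  col <- paste0("step", step)
  if (!col %in% names(classifications)) {
    stop("unknown step: ", step, call. = FALSE)
  }
  pos <- truth_positive_ids(truth)
  stray <- setdiff(pos, classifications$patient_id)
  if (length(stray)) {
    stop("truth table contains patients missing from the classifications: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  }
  is_pos <- classifications$patient_id %in% pos
  flag <- classifications[[col]]
  confusion_table(
    tp = sum(flag & is_pos), fp = sum(flag & !is_pos),
    tn = sum(!flag & !is_pos), fn = sum(!flag & is_pos)
  )
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative integer cell counts.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  cells <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(as.integer(cells)) |> setNames(names(cells)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("flagged", "not flagged"),
                              c("dislocation", "no dislocation")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 table, each with an exact Clopper-Pearson 95% confidence interval,
#' reported as percentages rounded half-up to one decimal (the printed
#' presentation). PPV and NPV are `NA` when their denominator is zero.
#'
#' @param ct a `confusion_table`.
#' @param conf_level confidence level, default 0.95.
#' @param digits decimal places for the percentage scale; `NULL` for
#'   unrounded values.
#' @return a tibble with columns `metric`, `estimate`, `lower`, `upper`
#'   (percent), and the binomial `x` and `n` behind each proportion.
#' @export
accuracy <- function(ct, conf_level = 0.95, digits = 1) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct$tp + ct$fp + ct$tn + ct$fn == 0) {
    stop("empty confusion table", call. = FALSE)
  }
  if (ct$tp + ct$fn == 0 || ct$tn + ct$fp == 0) {
    stop("sensitivity/specificity undefined: need at least one positive ",
         "and one negative patient", call. = FALSE)
  }
  xs <- c(sensitivity = ct$tp, specificity = ct$tn, ppv = ct$tp, npv = ct$tn)
  ns <- c(ct$tp + ct$fn, ct$tn + ct$fp, ct$tp + ct$fp, ct$tn + ct$fn)
  est <- lo <- hi <- rep(NA_real_, 4)
  ok <- ns > 0
  est[ok] <- 100 * xs[ok] / ns[ok]
  ci <- clopper_pearson(xs[ok], ns[ok], conf_level)
  lo[ok] <- 100 * ci$lower
  hi[ok] <- 100 * ci$upper
  if (!is.null(digits)) {
    est <- round_half_up(est, digits)
    lo <- round_half_up(lo, digits)
    hi <- round_half_up(hi, digits)
  }
  tibble(metric = names(xs), estimate = est, lower = lo, upper = hi,
         x = as.integer(xs), n = as.integer(ns))
}

#' Crude cumulative incidence of dislocation
#'
#' Percentage of cohort patients with at least one verified event over
#' their follow-up, with an exact binomial interval on the crude
#' proportion.
#'
#' @param cohort a `tha_cohort`.
#' @param truth gold-standard event table.
#' @param digits decimal places (default 1).
#' @return a list with `percent`, `lower`, `upper`, `numerator`,
#'   `denominator`.
#' @export
incidence <- function(cohort, truth, digits = 1) {
  stopifnot(inherits(cohort, "tha_cohort"))
  n <- nrow(cohort$records)
  if (n == 0) stop("empty cohort", call. = FALSE)
  k <- sum(cohort$records$patient_id %in% truth_positive_ids(truth))
  ci <- clopper_pearson(k, n)
  list(
    percent = round_half_up(100 * k / n, digits),
    lower = round_half_up(100 * ci$lower, digits),
    upper = round_half_up(100 * ci$upper, digits),
    numerator = k,
    denominator = n
  )
}

#' Chart-review burden of the review-adjusted steps
#'
#' Step 4A reviews the files of patients first flagged at step 4 (their
#' unknown-laterality contacts); step 5A additionally reviews patients
#' first flagged at step 5.
#'
#' @param classifications a `step_classification`.
#' @param step `"4A"` or `"5A"`.
#' @return a list with `patients` (files to review) and `contacts`
#'   (qualifying contacts behind them).
#' @export
review_burden <- function(classifications, step = c("4A", "5A")) {
  step <- match.arg(step)
  stopifnot(inherits(classifications, "step_classification"))
  fs <- classifications$first_step
  groups <- if (step == "4A") 4L else c(4L, 5L)
  pts <- classifications$patient_id[!is.na(fs) & fs %in% groups]
  qual <- attr(classifications, "qualifying")
  k <- sum(qual$patient_id %in% pts & qual$group %in% groups)
  list(patients = length(pts), contacts = k)
}
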