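STEP_ORDER <- c("1", "2", "3", "4", "4A", "5", "5A")

STEP_CODES_ADDED <- c(
  "1" = "correct diagnosis + correct procedure, known laterality",
  "2" = "correct procedure alone, known laterality",
  "3" = "alternative diagnosis/procedure codes, known laterality",
  "4" = "group 1-3 codes with unknown laterality",
  "4A" = "file review of step-4 additions",
  "5" = "correct diagnosis alone, acute/ER, known laterality",
  "5A" = "file review of step-4 and step-5 additions"
)

#' Patient-level accuracy for every algorithm step
#'
#' Runs [confusion()] and [accuracy()] for steps 1-5 and the
#' review-adjusted 4A/5A, returning one row per step in presentation
#' order.
#'
#' @param classifications a `step_classification` (review-adjusted when
#'   the A-steps should reflect chart review).
#' @param truth gold-standard event table.
#' @param digits decimal places on the percent scale.
#' @return a tibble: `step`, `tp`, `fp`, `tn`, `fn`, then
#'   estimate/lower/upper columns for sensitivity, specificity, PPV, NPV.
#' @export
step_accuracy_table <- function(classifications, truth, digits = 1) {
  rows <- lapply(STEP_ORDER, function(s) {
    ct <- confusion(classifications, truth, s)
    acc <- accuracy(ct, digits = digits)
    wide <- as.list(setNames(
      c(acc$estimate, acc$lower, acc$upper),
      c(acc$metric, paste0(acc$metric, "_lower"), paste0(acc$metric, "_upper"))
    ))
    tibble(step = s, tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn,
           !!!wide)
  })
  bind_rows(rows)
}

#' Event-level sensitivity and PPV for steps 1-5
#'
#' Episode counting: the fraction of verified dislocation episodes with a
#' matching qualifying contact at each step (sensitivity), and the
#' fraction of qualifying contacts at each step that confirm an episode
#' (PPV). Confidence intervals are not produced in event mode.
#'
#' @param events the per-event table from [classify_events()].
#' @param classifications the `step_classification` whose qualifying
#'   contacts were used.
#' @param digits decimal places on the percent scale.
#' @return a tibble: `step`, `detected`, `total`, `sensitivity`,
#'   `flagged_contacts`, `ppv`.
#' @export
evaluate_events <- function(events, classifications, digits = 1) {
  qual <- attr(classifications, "qualifying")
  matched_steps <- events$first_step
  rows <- lapply(1:5, function(k) {
    det <- sum(!is.na(matched_steps) & matched_steps <= k)
    flagged <- sum(qual$group <= k)
    tibble(
      step = as.character(k),
      detected = det,
      total = nrow(events),
      sensitivity = round_half_up(100 * det / nrow(events), digits),
      flagged_contacts = flagged,
      ppv = if (flagged > 0) round_half_up(100 * det / flagged, digits) else NA_real_
    )
  })
  bind_rows(rows)
}

#' Configure an end-to-end pipeline run
#'
#' Either a calibration profile (synthetic run) or paths to existing
#' cohort/contact CSVs must be supplied; a truth table (file or tibble) is
#' required for the review-adjusted steps and for event-level evaluation.
#'
#' @param profile a `calibration_profile`, a profile file path, or `NULL`
#'   when reading registry extracts from disk.
#' @param cohort,contacts,truth CSV paths (ignored when `profile` is set;
#'   the generated truth table then doubles as the chart-review oracle).
#' @param codes a `code_set` or a code-set file path.
#' @param seed integer seed for the generator.
#' @param mode generator mode, `"quota"` or `"sampling"`.
#' @param level `"patient"` or `"event"`.
#' @param out_dir optional output directory for `metrics.csv`,
#'   `flow.csv` and the generated registry.
#' @return a `run_config` list.
#' @export
run_config <- function(profile = NULL, cohort = NULL, contacts = NULL,
                       truth = NULL, codes = code_set(), seed = 42L,
                       mode = "quota", level = "patient", out_dir = NULL) {
  if (is.character(profile)) profile <- read_profile(profile)
  if (is.character(codes)) codes <- read_code_set(codes)
  stopifnot(level %in% c("patient", "event"),
            mode %in% c("quota", "sampling"))
  if (is.null(profile)) {
    for (p in c(cohort, contacts)) {
      if (is.character(p) && !file.exists(p)) {
        stop("input file does not exist: ", p, call. = FALSE)
      }
    }
    if (is.null(cohort) || is.null(contacts)) {
      stop("either a profile or cohort+contacts inputs are required",
           call. = FALSE)
    }
  }
  structure(
    list(profile = profile, cohort = cohort, contacts = contacts,
         truth = truth, codes = codes, seed = as.integer(seed),
         mode = mode, level = level, out_dir = out_dir),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full detection pipeline
#'
#' Wires the stages simulate (optional) -> build cohort -> window
#' contacts -> classify -> review-adjust -> evaluate, and assembles a
#' machine-readable run report: the step accuracy table, a step-by-step
#' flow summary (codes added, flagged counts, metrics, review burden) and
#' a log with the seed and package version. Reruns with the same
#' configuration produce identical tables.
#'
#' @param config a [run_config()].
#' @return an object of class `dislocation_run`: list with `metrics`,
#'   `flow`, `event_metrics` (event level only), `classifications`,
#'   `cohort`, `incidence`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$profile)) {
    reg <- run_stage("simulate", generate_registry(
      config$profile, seed = config$seed, mode = config$mode,
      out_dir = config$out_dir))
    raw_cohort <- reg$cohort
    contacts <- reg$contacts
    truth <- reg$truth
  } else {
    raw_cohort <- run_stage("read_inputs", read_cohort_csv(config$cohort))
    contacts <- run_stage("read_inputs", read_contacts_csv(config$contacts))
    truth <- if (is.null(config$truth)) NULL
             else if (is.character(config$truth)) {
               run_stage("read_inputs", read_truth_csv(config$truth))
             } else validate_truth_table(config$truth)
  }

  cohort <- run_stage("build_cohort", build_cohort(raw_cohort))
  windowed <- run_stage("window_contacts", window_contacts(cohort, contacts))
  cls <- run_stage("classify", classify_patients(cohort, windowed,
                                                 config$codes))
  if (is.null(truth)) {
    stop("pipeline stage 'review_adjust' failed: steps 4A/5A require a ",
         "truth table (chart-review oracle)", call. = FALSE)
  }
  cls <- run_stage("review_adjust", {
    cls <- review_adjust(cls, truth, "4A")
    review_adjust(cls, truth, "5A")
  })

  metrics <- run_stage("evaluate", step_accuracy_table(cls, truth))
  b4 <- review_burden(cls, "4A")
  b5 <- review_burden(cls, "5A")
  flow <- metrics %>%
    mutate(
      codes_added = unname(STEP_CODES_ADDED[step]),
      flagged = tp + fp,
      review_patients = c(NA, NA, NA, NA, b4$patients, NA, b5$patients)[
        match(step, STEP_ORDER)]
    ) %>%
    select(step, codes_added, flagged, tp, fp, sensitivity, specificity,
           ppv, npv, review_patients)

  event_metrics <- NULL
  if (config$level == "event") {
    events <- run_stage("classify_events",
                        classify_events(truth, cls, windowed))
    event_metrics <- run_stage("evaluate", evaluate_events(events, cls))
  }

  log <- list(
    seed = config$seed, mode = config$mode, level = config$level,
    package_version = as.character(utils::packageVersion("hipdisloc")),
    r_version = R.version.string,
    n_cohort = nrow(cohort$records), n_contacts = nrow(windowed),
    n_events = nrow(truth)
  )
  out <- structure(
    list(metrics = metrics, flow = flow, event_metrics = event_metrics,
         classifications = cls, cohort = cohort,
         incidence = incidence(cohort, truth), log = log),
    class = "dislocation_run"
  )
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(flow, file.path(config$out_dir, "flow.csv"),
              row.names = FALSE, quote = TRUE)
    if (!is.null(event_metrics)) {
      write.csv(event_metrics, file.path(config$out_dir, "event_metrics.csv"),
                row.names = FALSE, quote = FALSE)
    }
  }
  out
}

#' @export
print.dislocation_run <- function(x, ...) {
  cat(sprintf("<dislocation_run> %d THAs, incidence %.1f%% (%d/%d)\n",
              x$log$n_cohort, x$incidence$percent,
              x$incidence$numerator, x$incidence$denominator))
  print(as.data.frame(x$flow), row.names = FALSE)
  if (!is.null(x$event_metrics)) {
    cat("event level:\n")
    print(as.data.frame(x$event_metrics), row.names = FALSE)
  }
  invisible(x)
}
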