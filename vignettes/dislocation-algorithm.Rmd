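---
title: "Detecting THA dislocations in administrative registry data: methods and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting THA dislocations in administrative registry data: methods and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipdisloc)
```

## The problem

Dislocation after primary total hip arthroplasty (THA) is usually treated
with closed reduction and therefore rarely reaches arthroplasty registers,
which are revision-driven. The burden of this complication must instead be
measured in hospital-contact administrative data, where it hides behind
inconsistent coding: the correct ICD-10 diagnosis (`DT84.0`, mechanical
complication of an internal joint prosthesis) and the correct NCSP
closed-reduction procedure (`KNFH20`) are applied far from universally.
Contacts may instead carry the correct procedure with an unrelated
diagnosis, codes intended for traumatic dislocation of a native hip
(`DS73.0`, `KNFH00/02/21/22`), or the correct diagnosis alone; laterality
may be missing altogether.

`hipdisloc` implements a stepwise code-combination algorithm over such
extracts, the accuracy machinery to validate it against a chart-review
gold standard, and a calibrated synthetic registry generator so that the
whole pipeline can be exercised and its published accuracy profile
reproduced without access to the restricted Danish source registers.

## The algorithm

Every hospital contact in a patient's two-year follow-up window is
assigned to at most one of five code groups, evaluated lowest-first:

| group | definition |
|---|---|
| 1 | correct diagnosis (`DT840`, subcodes via prefix match) **and** correct procedure (`KNFH20`), contact side = operated side |
| 2 | correct procedure with any diagnosis, side matching |
| 3 | alternative diagnosis (`DS730`) or alternative procedures (`KNFH00/02/21/22`), side matching |
| 4 | any group 1–3 code criterion, but contact laterality unknown |
| 5 | correct diagnosis alone (no correct procedure), side matching, acute admission or emergency-room contact only |

Contacts recorded on the side opposite the operated hip never qualify —
this is what keeps bilateral-THA mix-ups out of groups 1–3 and 5 — and
diagnoses count in either primary or secondary position. Step *k* of the
algorithm flags a patient when any contact belongs to a group numbered
*k* or lower, so detection is cumulative: sensitivity can only rise with
the step, specificity and PPV can only fall. Steps 4A and 5A model the
chart review of the weakly coded additions: patients flagged *solely* by
group-4 (4A) or group-4/5 (5A) contacts who have no verified dislocation
are discarded. Review removes only false positives, so it never changes
sensitivity and can only raise PPV; 5A presupposes the step-4 review and
the package enforces that ordering.

The patient-level algorithm measures the *risk* of dislocation (at least
one episode). For study designs that need every episode, the event-level
mode matches each verified event to qualifying contacts of the same
patient admitted within ±1 day (each contact confirms at most one event;
nearest admission wins, an equidistant tie resolves to the earlier
event). The linkage window is a package choice — the source registers do
not define one — and the synthetic generator emits same-day contacts, so
calibration results do not depend on it.

## Cohort rules and the follow-up window

`build_cohort()` retains one primary-osteoarthritis THA per patient,
excluding other indications, patients younger than 40 at surgery, and —
for bilateral patients — every THA after the chronologically first, to
avoid dependent observations. Follow-up is the closed–open interval of
730 days from the index surgery, ended early by revision, death or
emigration; the censoring day itself stays inside the window because a
revision performed on day *d* may carry the codes of the dislocation
that caused it. Day-0 contacts (the index admission) are retained:
in-admission dislocations exist and nothing in the coding rules excludes
them.

## Accuracy metrics and rounding

Sensitivity, specificity, PPV and NPV come from the patient-level 2×2
table against the gold standard, each with an exact Clopper–Pearson 95%
interval (`stats::qbeta` form; lower bound 0 at x = 0, upper bound 1 at
x = n). Percentages are presented rounded half-up to one decimal, the
convention of the published table; `round_half_up()` is exported because
base R's round-half-even produces different final digits exactly at the
presentation boundaries. PPV and NPV are reported as missing when their
denominator is empty rather than forced to 0 or 100.

## Reconstructing integer counts from a printed table

The published validation reports only rounded percentages, but with the
cohort margins known (1,094 dislocators among 31,762 THAs, hence 30,668
negatives) the integer counts are recoverable:
`reconstruct_implied_counts()` scans all tp with
round(100·tp/P) equal to the printed sensitivity (requiring uniqueness)
and all fp whose rounded PPV matches. Three findings from applying this
to the published table are worth recording:

* **Step 5 is ambiguous**: fp ∈ {232, 233} both reproduce PPV 81.8. The
  package flags the ambiguity and resolves to the smallest candidate for
  calibration.
* **Step 2 is inconsistent at the printed precision**: with the unique
  tp = 842, no integer fp rounds to PPV 96.5 (31 gives 96.449, 30 gives
  96.560). The default reconstruction therefore errors; the calibration
  path uses the nearest-unrounded candidate, fp = 31.
* **Specificity cells show truncation**: the implied step-1 specificity
  is 30,653/30,668 = 99.951%, which half-up rounding carries to 100.0
  while the published cell reads 99.9 (likewise 99.88 → printed 99.8 at
  step 5A). The recomputed values are asserted in the tests; the printed
  cells appear to be truncated rather than rounded.

The step-5A PPV is a fourth, related case: review leaves the step-3
false positives (36), giving 1,044/1,080 = 96.7 against a printed 96.6.
And the published step-5 sensitivity interval (93.9–96.5) is not the
Clopper–Pearson interval of 1,044/1,094 (94.0–96.6); steps 1–4 all
reproduce exactly. None of these cells is used for calibration.

## The synthetic registry generator

`generate_registry()` emulates a linked arthroplasty-register /
patient-register extract under a `calibration_profile()`. The default
profile *is* the published study's condition set:

* 31,762 THAs, index dates uniform over 2010–2014, left/right at random,
  ages 40–94, all primary osteoarthritis;
* 1,094 dislocators with 1,890 episodes; episodes per dislocator follow
  a 1-shifted geometric truncated at 10, its rate solved so the mean is
  1,890/1,094 ≈ 1.73 (the literature's 40–68% re-dislocation range makes
  a geometric-type tail plausible; only the mean is calibrated);
* per-step detection categories (686, 156, 89, 68, 45 patients first
  detected at steps 1–5; 50 never) and false-positive increments
  (15, 16, 5, 36, 160) taken from the implied-count reconstruction;
* ~5% of patients censored between day 30 and 729 (revision, death or
  emigration); censored dislocators keep their events inside the
  shortened window so calibration is unaffected;
* nuisance contacts (0–2 per remaining patient) drawn from a hard-coded
  pool of non-qualifying codes, with 10% unknown laterality and 30%
  acute admissions, plus a 2% sliver of *correctly coded contacts on the
  contralateral side* — decoys that the laterality rule must ignore.

In **quota** mode every category count is hit exactly: each dislocator's
episodes get same-day contacts coded so the patient's best qualifying
contact realizes exactly their category, each false-positive patient
gets one contact of the corresponding group, and the episode total is
nudged to 1,890 exactly. The downstream accuracy table is then fully
deterministic, whatever the seed. In **sampling** mode categories are
drawn multinomially, for stochastic power-style experiments; sampling
estimates converge on the quota values (the test suite checks a
20,000-patient sampling run against its quota calibration within three
standard errors — a size chosen to keep the suite fast while leaving
the binomial noise well below the calibrated effects).

The event-calibrated variant (`event_profile()`) fixes instead the
cumulative episodes detected per step: 1,663 = round(0.88 × 1,890) and
1,796 (0.95 × 1,890 = 1,795.5, rounded half-up) at steps 4 and 5 — the
two reported event-level sensitivities — and scales steps 1–3 from the
patient-level fractions (1,185, 1,455, 1,608), for which no event-level
figures were reported. Patient-level accuracy is then emergent.
Patient-level and event-level calibrations are deliberately separate
profiles: jointly matching both tables is over-constrained, and the
event-mode false-positive contact structure remains patient-calibrated
(its event-level PPVs land near, not on, the reported pair).

What the generator does **not** emulate: the real volume and case-mix of
non-dislocation hip-related contacts (the published extraction saw
16,437 contacts and 5,096 reviewed files — we make no attempt at those),
inter-hospital transfer chains, department-level coding culture, or any
seasonality. Reproducing the accuracy table with this generator
therefore demonstrates that the classifier, the review adjustment and
the metrics are internally consistent with the published confusion
structure — not that the algorithm would achieve those values on another
country's registry.

## Numerical and degenerate-input choices

* Rounding: half-up at the presented precision, everywhere.
* Follow-up: last eligible admission day is min(index + 729 d, censoring
  date).
* Group assignment is a partition; when a contact satisfies several
  group definitions the lowest-numbered wins, matching the cumulative
  step construction.
* `reconstruct_implied_counts()` errors on an empty candidate set by
  default (an inconsistent printed row should be loud); the calibration
  path opts into nearest-candidate resolution explicitly.
* Empty cohorts, all-negative classifications, and zero-denominator
  predictive values raise errors or `NA` as documented rather than
  silent zeros.
* Generator determinism: identical (profile, seed, mode) produce
  byte-identical CSVs; the test suite asserts this.

## Problem sizes

The full-size pipeline — generate 31,762 patients with ~35,000 contacts,
window, classify, review-adjust, evaluate — runs in a few seconds, so
the package's end-to-end checks run at the study's real scale rather
than a scaled-down one. The acceptance script repeats the same
computation from scratch at full size for both calibration profiles.

## Limitations

The gold standard here is an oracle table; the chart review itself
(inter-rater reliability, review workload beyond counts) is not
modelled. The default code sets contain only the named algorithm codes —
the source study's full extraction code list was never published in
full, so the extraction filter is configurable
(`code_set()`, `read_code_set()`) rather than fixed. Accuracy values
carry over to other populations (secondary osteoarthritis, fracture
indications, other countries' coding cultures) only by assumption.
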