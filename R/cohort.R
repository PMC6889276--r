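#' Days-to-months conversion
#'
#' Converts a span in days to months using the 30.4375-day convention
#' (365.25 / 12), the unit in which clinical time-to-event results are
#' reported.
#'
#' @param day_span Numeric vector of non-negative day spans.
#' @return Numeric vector of months.
#' @examples
#' months(183)   # ~6 months
#' months(365)   # ~12 months
#' @export
months <- function(day_span) {
  if (any(is.na(day_span))) abort("`day_span` must not contain NA.")
  if (any(day_span < 0)) abort("`day_span` must be non-negative.")
  day_span / 30.4375
}

DAYS_PER_MONTH <- 30.4375

measurement_cols <- c(
  "patient_id", "day", "lesion_id", "organ", "diameter_mm",
  "attenuation_hu", "is_new", "nontarget_progression"
)
outcome_cols <- c("patient_id", "death_day", "last_followup_day")

#' Construct a lesion cohort from measurement and outcome tables
#'
#' A lesion cohort couples a longitudinal table of per-lesion CT
#' measurements with a per-patient outcomes table. Measurements carry one
#' row per (patient, assessment day, lesion): the lesion's longest
#' diameter in mm, its mean arterial-phase attenuation in Hounsfield
#' units (possibly missing), whether it is a new lesion, and an
#' assessment-level flag for unequivocal non-target progression. Outcomes
#' carry the death day (missing while alive) and last follow-up day.
#'
#' Time is measured in integer days from treatment start (day 0 = first
#' dose); the baseline scan may sit in the window \[-28, 0\].
#'
#' @param measurements Data frame with columns `patient_id`, `day`,
#'   `lesion_id`, `organ`, `diameter_mm`, `attenuation_hu`, `is_new`,
#'   `nontarget_progression`.
#' @param outcomes Data frame with columns `patient_id`, `death_day`,
#'   `last_followup_day`.
#' @param validate Check structural invariants (default `TRUE`).
#' @return An object of class `lesion_cohort`: a list with tibbles
#'   `$measurements` (sorted by patient, day, lesion) and `$outcomes`.
#' @export
lesion_cohort <- function(measurements, outcomes, validate = TRUE) {
  m <- as_tibble(measurements)
  o <- as_tibble(outcomes)
  miss_m <- setdiff(measurement_cols, names(m))
  if (length(miss_m) > 0) {
    abort(paste0("measurements table lacks column(s): ",
                 paste(miss_m, collapse = ", ")))
  }
  miss_o <- setdiff(outcome_cols, names(o))
  if (length(miss_o) > 0) {
    abort(paste0("outcomes table lacks column(s): ",
                 paste(miss_o, collapse = ", ")))
  }
  m <- m[measurement_cols]
  o <- o[outcome_cols]
  m$patient_id <- as.character(m$patient_id)
  m$lesion_id <- as.character(m$lesion_id)
  m$organ <- as.character(m$organ)
  m$is_new <- as.logical(m$is_new)
  m$nontarget_progression <- as.logical(m$nontarget_progression)
  o$patient_id <- as.character(o$patient_id)
  if (validate) {
    if (any(!is.finite(m$day))) abort("non-numeric or missing `day`.")
    if (any(is.na(m$diameter_mm)) || any(m$diameter_mm < 0)) {
      abort("`diameter_mm` must be present and non-negative.")
    }
    if (any(m$is_new & m$day <= 0)) {
      abort("new lesions (`is_new`) require day > 0.")
    }
    dup <- duplicated(m[c("patient_id", "day", "lesion_id")])
    if (any(dup)) {
      abort(paste0("duplicate (patient, day, lesion) rows: e.g. ",
                   m$patient_id[dup][1], "/", m$day[dup][1], "/",
                   m$lesion_id[dup][1]))
    }
    if (anyDuplicated(o$patient_id) > 0) abort("duplicate patient_id in outcomes.")
    if (any(!is.na(o$death_day) & o$death_day < 0)) {
      abort("`death_day` must be >= 0.")
    }
  }
  # deterministic ordering regardless of input row order
  m <- arrange(m, .data$patient_id, .data$day, .data$lesion_id)
  o <- arrange(o, .data$patient_id)
  structure(list(measurements = m, outcomes = o), class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  n_pat <- length(unique(x$measurements$patient_id))
  n_ass <- nrow(distinct(x$measurements, .data$patient_id, .data$day))
  cat("<lesion_cohort> ", n_pat, " patients, ", n_ass, " assessments, ",
      nrow(x$measurements), " lesion measurements\n", sep = "")
  invisible(x)
}

# Accept either a lesion_cohort or a bare measurements data frame.
cohort_measurements <- function(x) {
  if (inherits(x, "lesion_cohort")) x$measurements
  else lesion_cohort(x, tibble(patient_id = character(),
                               death_day = integer(),
                               last_followup_day = integer()))$measurements
}

cohort_outcomes <- function(x) {
  if (inherits(x, "lesion_cohort")) return(x$outcomes)
  o <- as_tibble(x)
  miss <- setdiff(outcome_cols, names(o))
  if (length(miss) > 0) {
    abort(paste0("outcomes table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  o$patient_id <- as.character(o$patient_id)
  o
}

#' Read a lesion cohort from delimited text files
#'
#' Reads the two-file interchange format: a measurements CSV (one row per
#' patient, assessment day and lesion) and an outcomes CSV (one row per
#' patient). Empty `attenuation_hu` cells are missing HU; empty
#' `death_day` means alive at last follow-up. `is_new` and
#' `nontarget_progression` are 0/1. Files are UTF-8 with a header row and
#' "." as decimal separator.
#'
#' @param measurements_path,outcomes_path CSV file paths.
#' @return A validated [lesion_cohort()].
#' @export
load_cohort <- function(measurements_path, outcomes_path) {
  for (p in c(measurements_path, outcomes_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  m <- readr::read_csv(
    measurements_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      day = readr::col_integer(),
      lesion_id = readr::col_character(),
      organ = readr::col_character(),
      diameter_mm = readr::col_double(),
      attenuation_hu = readr::col_double(),
      is_new = readr::col_integer(),
      nontarget_progression = readr::col_integer()
    )
  )
  prob <- readr::problems(m)
  if (nrow(prob) > 0) {
    abort(paste0("unparseable value(s) in ", measurements_path,
                 " (first at row ", prob$row[1], ", col ", prob$col[1], ")"))
  }
  miss_m <- setdiff(measurement_cols, names(m))
  if (length(miss_m) > 0) {
    abort(paste0("measurements file lacks column(s): ",
                 paste(miss_m, collapse = ", ")))
  }
  o <- readr::read_csv(
    outcomes_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      death_day = readr::col_integer(),
      last_followup_day = readr::col_integer()
    )
  )
  prob <- readr::problems(o)
  if (nrow(prob) > 0) {
    abort(paste0("unparseable value(s) in ", outcomes_path))
  }
  miss_o <- setdiff(outcome_cols, names(o))
  if (length(miss_o) > 0) {
    abort(paste0("outcomes file lacks column(s): ",
                 paste(miss_o, collapse = ", ")))
  }
  m$is_new <- m$is_new == 1L
  m$nontarget_progression <- m$nontarget_progression == 1L
  lesion_cohort(m, o)
}

#' Write a lesion cohort to delimited text files
#'
#' Inverse of [load_cohort()]: writing then reading reproduces the cohort
#' exactly (round-trip identity on valid cohorts).
#'
#' @param cohort A [lesion_cohort()].
#' @param measurements_path,outcomes_path Output CSV paths.
#' @return The input cohort, invisibly.
#' @export
write_cohort <- function(cohort, measurements_path, outcomes_path) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  m <- cohort$measurements
  m$is_new <- as.integer(m$is_new)
  m$nontarget_progression <- as.integer(m$nontarget_progression)
  readr::write_csv(m, measurements_path, na = "", progress = FALSE)
  readr::write_csv(cohort$outcomes, outcomes_path, na = "", progress = FALSE)
  invisible(cohort)
}

#' Screen a cohort for protocol-quality issues
#'
#' Flags patients whose imaging series cannot support response
#' classification: no baseline assessment (none in the \[-28, 0\] day
#' window), a baseline scan before the 4-week pre-treatment window, no
#' measurable baseline lesion (all diameters 0), or fewer than two
#' assessments. Flagged patients are excluded downstream when strict mode
#' is on; the function itself only reports.
#'
#' @param cohort A [lesion_cohort()] or measurements data frame.
#' @return Tibble with columns `patient_id` and `issue` (one row per
#'   issue; empty when the cohort is fully conformant).
#' @export
validate_cohort <- function(cohort) {
  m <- cohort_measurements(cohort)
  per_pat <- m %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_days = length(unique(.data$day)),
      min_day = min(.data$day),
      has_baseline = any(.data$day >= -28 & .data$day <= 0),
      early_baseline = min(.data$day) < -28,
      .groups = "drop"
    )
  base_meas <- m %>%
    filter(.data$day <= 0) %>%
    group_by(.data$patient_id) %>%
    filter(.data$day == max(.data$day)) %>%
    summarise(measurable = any(.data$diameter_mm > 0), .groups = "drop")
  per_pat <- left_join(per_pat, base_meas, by = "patient_id")

  issues <- list(
    per_pat %>% filter(!.data$has_baseline) %>%
      mutate(issue = "no baseline assessment"),
    per_pat %>% filter(.data$early_baseline) %>%
      mutate(issue = "baseline outside 4-week window"),
    per_pat %>% filter(.data$has_baseline, !is.na(.data$measurable),
                       !.data$measurable) %>%
      mutate(issue = "no measurable baseline lesion"),
    per_pat %>% filter(.data$n_days < 2) %>%
      mutate(issue = "insufficient follow-up imaging")
  )
  bind_rows(issues) %>%
    select("patient_id", "issue") %>%
    arrange(.data$patient_id, .data$issue)
}

# Patients passing validate_cohort (strict-mode filter).
conformant_patients <- function(cohort) {
  m <- cohort_measurements(cohort)
  setdiff(unique(m$patient_id), unique(validate_cohort(cohort)$patient_id))
}

# Baseline day per patient: the assessment with the largest non-positive day.
baseline_days <- function(measurements) {
  measurements %>%
    filter(.data$day <= 0) %>%
    group_by(.data$patient_id) %>%
    summarise(baseline_day = max(.data$day), .groups = "drop")
}
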