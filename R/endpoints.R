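#' Derive progression-free survival from a classified series
#'
#' PFS runs from treatment start until the first progression per the
#' series' criterion or death, whichever comes first; patients with
#' neither are censored at their last adequate tumour assessment (not
#' last contact). Death without documented progression counts as a PFS
#' event at the death time. Times are reported in months.
#'
#' @param responses A `response_series` tibble ([classify_recist()] or
#'   [classify_choi()]); must hold a single criterion.
#' @param outcomes A [lesion_cohort()] or outcomes data frame
#'   (`patient_id`, `death_day`, `last_followup_day`).
#' @return Tibble `patient_id`, `endpoint` (`"PFS_RECIST"` or
#'   `"PFS_CHOI"`), `time` (months), `event` (logical).
#' @export
derive_pfs <- function(responses, outcomes) {
  r <- as_tibble(responses)
  crit <- unique(as.character(r$criterion))
  if (length(crit) != 1) abort("`responses` must hold exactly one criterion.")
  o <- cohort_outcomes(outcomes)
  per_pat <- r %>%
    group_by(.data$patient_id) %>%
    summarise(
      pd_day = if (any(.data$label == "PD")) min(.data$day[.data$label == "PD"])
               else NA_integer_,
      last_assessment_day = max(.data$day),
      .groups = "drop"
    ) %>%
    left_join(o, by = "patient_id")
  event_day <- pmin(per_pat$pd_day, per_pat$death_day, na.rm = TRUE)
  has_event <- !is.na(per_pat$pd_day) | !is.na(per_pat$death_day)
  day <- ifelse(has_event, event_day, per_pat$last_assessment_day)
  tibble(
    patient_id = per_pat$patient_id,
    endpoint = paste0("PFS_", crit),
    time = months(day),
    event = has_event
  )
}

#' Derive overall survival
#'
#' Event at `death_day` when present, otherwise censored at
#' `last_followup_day`. Times in months.
#'
#' @param outcomes A [lesion_cohort()] or outcomes data frame.
#' @return Tibble `patient_id`, `endpoint` (`"OS"`), `time` (months),
#'   `event`.
#' @export
derive_os <- function(outcomes) {
  o <- cohort_outcomes(outcomes)
  dead <- !is.na(o$death_day)
  tibble(
    patient_id = o$patient_id,
    endpoint = "OS",
    time = months(ifelse(dead, o$death_day, o$last_followup_day)),
    event = dead
  )
}

#' Pair PFS and OS records per patient
#'
#' Joins one PFS table with an OS table into bivariate pairs for copula
#' analysis, enforcing the semi-competing-risks constraint PFS <= OS. A
#' PFS censoring time beyond the OS time (imaging continued past the
#' recorded outcome horizon) is clipped to the OS time and inherits the
#' OS event status — in particular a death then becomes a PFS event.
#' Clipped records are flagged. A PFS *event* strictly after the OS
#' time is a data-integrity error.
#'
#' @param pfs,os Survival tibbles from [derive_pfs()] / [derive_os()].
#' @return Tibble `patient_id`, `pfs_time`, `pfs_event`, `os_time`,
#'   `os_event`, `clipped`.
#' @export
pair_endpoints <- function(pfs, os) {
  p <- as_tibble(pfs)
  o <- as_tibble(os)
  merged <- dplyr::inner_join(
    select(p, "patient_id", pfs_time = "time", pfs_event = "event"),
    select(o, "patient_id", os_time = "time", os_event = "event"),
    by = "patient_id"
  )
  bad <- merged$pfs_event & merged$pfs_time > merged$os_time
  if (any(bad)) {
    abort(paste0("PFS event after OS time for patient(s): ",
                 paste(merged$patient_id[bad], collapse = ", ")))
  }
  clip <- !merged$pfs_event & merged$pfs_time > merged$os_time
  merged$pfs_time[clip] <- merged$os_time[clip]
  merged$pfs_event[clip] <- merged$os_event[clip]
  merged$clipped <- clip
  merged
}
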