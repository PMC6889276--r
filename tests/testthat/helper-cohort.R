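# Builders for small in-code fixtures.

mrow <- function(patient_id, day, lesion_id, organ = "liver",
                 diameter_mm = 20, attenuation_hu = NA_real_,
                 is_new = FALSE, nontarget_progression = FALSE) {
  tibble::tibble(
    patient_id = patient_id, day = as.integer(day), lesion_id = lesion_id,
    organ = organ, diameter_mm = diameter_mm,
    attenuation_hu = attenuation_hu, is_new = is_new,
    nontarget_progression = nontarget_progression
  )
}

# Single-lesion patient whose diameter sum and HU follow the given series.
series_patient <- function(pid, days, sums, hus = rep(NA_real_, length(days)),
                           new_at = integer(0)) {
  dplyr::bind_rows(lapply(seq_along(days), function(i) {
    base <- mrow(pid, days[i], "L1", diameter_mm = sums[i],
                 attenuation_hu = hus[i])
    if (days[i] %in% new_at) {
      base <- dplyr::bind_rows(
        base, mrow(pid, days[i], "Lnew", diameter_mm = 6, is_new = TRUE))
    }
    base
  }))
}

outcomes_for <- function(measurements, death_day = NA_integer_) {
  ids <- unique(measurements$patient_id)
  tibble::tibble(
    patient_id = ids,
    death_day = rep(as.integer(death_day), length(ids)),
    last_followup_day = vapply(ids, function(p) {
      max(measurements$day[measurements$patient_id == p])
    }, numeric(1)) |> as.integer()
  )
}

small_cohort <- function() {
  m <- dplyr::bind_rows(
    series_patient("A", c(0, 90, 180), c(100, 70, 60), c(100, 80, 75)),
    series_patient("B", c(-7, 100, 200), c(50, 55, 65), c(120, 118, 119))
  )
  lesion_cohort(m, outcomes_for(m))
}

# Independent re-statement of the classification rules as plain nested
# conditionals on a single follow-up, used as a brute-force oracle.
oracle_recist <- function(pct_base, pct_nadir, abs_nadir, sum_now,
                          new_lesion = FALSE, nontarget = FALSE) {
  if (new_lesion || nontarget) return("PD")
  if (pct_nadir >= 20 && abs_nadir >= 5) return("PD")
  if (sum_now == 0) return("CR")
  if (pct_base <= -30) return("PR")
  "SD"
}

oracle_choi <- function(pct_base, pct_hu, sum_now,
                        new_lesion = FALSE, nontarget = FALSE) {
  if (new_lesion || nontarget) return("PD")
  if (sum_now == 0) return("CR")
  hu_pr <- !is.na(pct_hu) && pct_hu <= -15
  if (hu_pr) return("PR")
  if (pct_base >= 10) return("PD")
  if (pct_base <= -10) return("PR")
  "SD"
}
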