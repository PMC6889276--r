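#' Run the response-classification pipeline
#'
#' Orchestrates validation, dual-criterion classification, endpoint
#' derivation, kinetics and the landmark transition table for a cohort.
#' In strict mode, patients flagged by [validate_cohort()] are excluded
#' before classification.
#'
#' @param cohort A [lesion_cohort()].
#' @param config A [criterion_config()].
#' @param landmark_day,window_days Landmark for the transition table
#'   (days; defaults 183 +/- 60).
#' @param strict Exclude protocol-nonconformant patients (default TRUE).
#' @return A `response_analysis`: list with `$responses` (both criteria),
#'   `$survival` (PFS per criterion + OS, long format), `$kinetics`,
#'   `$transition` ([transition_table()]), `$kappa`, `$issues`,
#'   `$landmark_day`, `$window_days`, `$config`.
#' @export
run_classification <- function(cohort, config = criterion_config(),
                               landmark_day = 183, window_days = 60,
                               strict = TRUE) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (nrow(cohort$measurements) == 0) abort("empty cohort.")
  issues <- validate_cohort(cohort)
  if (strict && nrow(issues) > 0) {
    keep <- conformant_patients(cohort)
    if (length(keep) == 0) abort("no protocol-conformant patients remain.")
    cohort <- lesion_cohort(
      filter(cohort$measurements, .data$patient_id %in% keep),
      filter(cohort$outcomes, .data$patient_id %in% keep)
    )
  }
  recist <- classify_recist(cohort, config)
  choi <- classify_choi(cohort, config)
  responses <- bind_rows(recist, choi)
  class(responses) <- class(recist)
  survival_tbl <- bind_rows(
    derive_pfs(recist, cohort),
    derive_pfs(choi, cohort),
    derive_os(cohort)
  )
  trans <- transition_table(recist, choi, landmark_day, window_days)
  structure(
    list(
      responses = responses,
      survival = survival_tbl,
      kinetics = compute_kinetics(cohort),
      transition = trans,
      kappa = if (trans$n > 0) cohens_kappa(trans) else NA_real_,
      issues = issues,
      landmark_day = landmark_day, window_days = window_days,
      config = config
    ),
    class = "response_analysis"
  )
}

#' @export
print.response_analysis <- function(x, ...) {
  cat("<response_analysis> ",
      length(unique(x$responses$patient_id)), " patients; kappa at day ",
      x$landmark_day, " = ",
      if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa), "\n", sep = "")
  invisible(x)
}

endpoint_records <- function(survival_tbl, endpoint) {
  filter(as_tibble(survival_tbl), .data$endpoint == .env$endpoint)
}

# First day (months) a series reaches a given label, per patient.
first_label_time <- function(responses, label) {
  r <- as_tibble(responses)
  r %>%
    group_by(.data$patient_id) %>%
    summarise(
      transition_time = if (any(.data$label == .env$label)) {
        months(min(.data$day[.data$label == .env$label]))
      } else NA_real_,
      .groups = "drop"
    )
}

#' Run the surrogacy battery
#'
#' For each criterion: fits the Clayton copula to the (PFS, OS) pairs
#' and reports Kendall's tau with bootstrap SE; estimates landmark
#' conditional survival by response category; and tests/estimates the
#' effect of attaining response with the Mantel-Byar test and the
#' time-dependent Cox model, against both PFS and OS.
#'
#' @param analysis A `response_analysis` from [run_classification()].
#' @param B Bootstrap replicates for the copula SE.
#' @param seed Bootstrap seed.
#' @param landmark_months,horizon_months Landmark analysis window
#'   (defaults 6 and 24 months).
#' @return A `surrogacy_report`: list with tibbles `$copula`,
#'   `$landmark`, `$mantel_byar`, `$cox`; fits kept in
#'   `$copula_fits`.
#' @export
run_surrogacy <- function(analysis, B = 200, seed = 1L,
                          landmark_months = 6, horizon_months = 24) {
  stopifnot(inherits(analysis, "response_analysis"))
  os <- endpoint_records(analysis$survival, "OS")
  criteria <- c("RECIST", "CHOI")
  copula_fits <- list()
  copula_rows <- landmark_rows <- mb_rows <- cox_rows <- list()
  for (crit in criteria) {
    pfs <- endpoint_records(analysis$survival, paste0("PFS_", crit))
    pairs <- pair_endpoints(pfs, os)
    fit <- fit_clayton(pairs, B = B, seed = seed)
    copula_fits[[crit]] <- fit
    copula_rows[[crit]] <- mutate(glance(fit), criterion = crit,
                                  .before = 1)

    resp <- filter(as_tibble(analysis$responses), .data$criterion == crit)
    grp <- response_at(resp, analysis$landmark_day, analysis$window_days)
    grp <- mutate(grp,
                  label = ifelse(as.character(.data$label) == "CR", "PR",
                                 as.character(.data$label)))
    lm_tbl <- suppressWarnings(
      landmark_survival(os, grp, landmark_months, horizon_months)
    )
    if (nrow(lm_tbl) > 0) {
      landmark_rows[[crit]] <- mutate(lm_tbl, criterion = crit, .before = 1)
    }

    transitions <- first_label_time(resp, "PR")
    for (ep in c(paste0("PFS_", crit), "OS")) {
      rec <- endpoint_records(analysis$survival, ep)
      mb <- mantel_byar(transitions, rec)
      mb_rows[[paste(crit, ep)]] <- mutate(
        tidy(mb), criterion = crit, endpoint = ep, .before = 1)
      fit_cox <- tryCatch(cox_td(rec, transitions, label = "response"),
                          error = function(e) NULL)
      if (!is.null(fit_cox)) {
        cox_rows[[paste(crit, ep)]] <- mutate(
          tidy(fit_cox), criterion = crit, endpoint = ep, .before = 1)
      }
    }
  }
  structure(
    list(
      copula = bind_rows(copula_rows),
      landmark = bind_rows(landmark_rows),
      mantel_byar = bind_rows(mb_rows),
      cox = bind_rows(cox_rows),
      copula_fits = copula_fits
    ),
    class = "surrogacy_report"
  )
}

#' @export
print.surrogacy_report <- function(x, ...) {
  cat("<surrogacy_report>\n")
  print(x$copula)
  invisible(x)
}

#' Spider-plot table: per-patient relative change over time
#'
#' The tidy table behind a spider plot: one row per patient and
#' follow-up assessment, with time in months and percent changes in the
#' diameter sum and mean attenuation vs baseline.
#'
#' @param responses A `response_series` tibble (one or both criteria;
#'   duplicate timepoints across criteria are collapsed).
#' @return Tibble `patient_id`, `months`, `pct_change_size`,
#'   `pct_change_hu`, `label`.
#' @export
spider_table <- function(responses) {
  r <- as_tibble(responses)
  r %>%
    distinct(.data$patient_id, .data$day, .keep_all = TRUE) %>%
    mutate(months = months(.data$day)) %>%
    select("patient_id", "months",
           pct_change_size = "pct_change_size_vs_baseline",
           pct_change_hu = "pct_change_hu_vs_baseline",
           "label") %>%
    arrange(.data$patient_id, .data$months)
}

#' Waterfall table: attenuation change, RECIST label and PFS
#'
#' The tidy table behind a 3D-waterfall display: per patient, the best
#' (most negative) percent change in mean attenuation vs baseline, the
#' RECIST label at the landmark, and the RECIST PFS.
#'
#' @param analysis A `response_analysis`.
#' @return Tibble `patient_id`, `delta_hu_pct`, `recist_label`,
#'   `pfs_months`, `pfs_event`, ordered by `delta_hu_pct`.
#' @export
waterfall_table <- function(analysis) {
  stopifnot(inherits(analysis, "response_analysis"))
  recist <- filter(as_tibble(analysis$responses), .data$criterion == "RECIST")
  hu <- recist %>%
    group_by(.data$patient_id) %>%
    summarise(
      delta_hu_pct = if (all(is.na(.data$pct_change_hu_vs_baseline)))
        NA_real_ else min(.data$pct_change_hu_vs_baseline, na.rm = TRUE),
      .groups = "drop"
    )
  lab <- response_at(recist, analysis$landmark_day, analysis$window_days)
  pfs <- endpoint_records(analysis$survival, "PFS_RECIST")
  hu %>%
    left_join(select(lab, "patient_id", recist_label = "label"),
              by = "patient_id") %>%
    left_join(select(pfs, "patient_id", pfs_months = "time",
                     pfs_event = "event"),
              by = "patient_id") %>%
    arrange(.data$delta_hu_pct)
}

#' Write analysis outputs and a run manifest to a directory
#'
#' Emits the per-patient response table, survival records, kinetics,
#' transition table, spider and waterfall tables as CSV, plus (when a
#' surrogacy report is supplied) the copula/landmark/Mantel-Byar/Cox
#' tables, and a JSON run manifest holding the configuration snapshot,
#' input-file digests, seed, package version and timestamp. Apart from
#' the manifest's timestamp, outputs are byte-identical across reruns on
#' identical inputs.
#'
#' @param analysis A `response_analysis`.
#' @param outdir Output directory (created if needed).
#' @param surrogacy Optional `surrogacy_report`.
#' @param input_paths Optional character vector of input files to digest
#'   into the manifest.
#' @param seed Seed recorded in the manifest.
#' @return `outdir`, invisibly.
#' @export
write_analysis <- function(analysis, outdir, surrogacy = NULL,
                           input_paths = character(0), seed = NA_integer_) {
  stopifnot(inherits(analysis, "response_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(as_tibble(x), file.path(outdir, name), na = "",
                     progress = FALSE)
  }
  wr(analysis$responses, "responses.csv")
  wr(analysis$survival, "survival.csv")
  wr(analysis$kinetics, "kinetics.csv")
  wr(tidy(analysis$transition), "transition_table.csv")
  wr(spider_table(analysis$responses), "spider_table.csv")
  wr(waterfall_table(analysis), "waterfall_table.csv")
  if (!is.null(analysis$issues)) wr(analysis$issues, "validation_issues.csv")
  if (!is.null(surrogacy)) {
    wr(surrogacy$copula, "copula.csv")
    wr(surrogacy$landmark, "landmark.csv")
    wr(surrogacy$mantel_byar, "mantel_byar.csv")
    wr(surrogacy$cox, "cox.csv")
  }
  digests <- if (length(input_paths) > 0) {
    as.list(tools::md5sum(input_paths))
  } else {
    NULL
  }
  manifest <- list(
    package = "radresponse",
    version = as.character(utils::packageVersion("radresponse")),
    seed = seed,
    config = unclass(analysis$config),
    landmark_day = analysis$landmark_day,
    window_days = analysis$window_days,
    input_digests = digests,
    kappa = analysis$kappa,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
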