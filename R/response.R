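#' Response-criterion configuration
#'
#' Thresholds for RECIST v1.1 and Choi classification. All percentage
#' thresholds are relative changes in percent; comparisons are inclusive
#' (a -30.0% change is RECIST PR, a +20.0% change with a +5.0 mm
#' absolute increase is RECIST PD).
#'
#' @param recist_pr_threshold RECIST PR: change in sum of diameters vs
#'   baseline at or below this (default -30).
#' @param recist_pd_threshold RECIST PD: change vs nadir at or above this
#'   (default +20), together with `recist_pd_abs_mm`.
#' @param recist_pd_abs_mm RECIST PD also requires an absolute increase
#'   vs nadir of at least this many mm (default 5).
#' @param choi_size_pr_threshold Choi PR by size: change vs baseline at
#'   or below this (default -10).
#' @param choi_hu_pr_threshold Choi PR by attenuation: change in mean HU
#'   vs baseline at or below this (default -15).
#' @param choi_pd_threshold Choi PD: size increase vs the PD reference at
#'   or above this (default +10).
#' @param reference_policy_choi_pd Reference for the Choi PD size change:
#'   `"baseline"` (default) or `"nadir"`.
#' @return A list of class `criterion_config`.
#' @export
criterion_config <- function(recist_pr_threshold = -30,
                             recist_pd_threshold = 20,
                             recist_pd_abs_mm = 5,
                             choi_size_pr_threshold = -10,
                             choi_hu_pr_threshold = -15,
                             choi_pd_threshold = 10,
                             reference_policy_choi_pd = c("baseline", "nadir")) {
  reference_policy_choi_pd <- match.arg(reference_policy_choi_pd)
  structure(
    list(
      recist_pr_threshold = recist_pr_threshold,
      recist_pd_threshold = recist_pd_threshold,
      recist_pd_abs_mm = recist_pd_abs_mm,
      choi_size_pr_threshold = choi_size_pr_threshold,
      choi_hu_pr_threshold = choi_hu_pr_threshold,
      choi_pd_threshold = choi_pd_threshold,
      reference_policy_choi_pd = reference_policy_choi_pd
    ),
    class = "criterion_config"
  )
}

response_levels <- c("CR", "PR", "SD", "PD")

#' Select target lesions at baseline
#'
#' Picks target lesions by descending baseline diameter, capped per organ
#' and overall. Ties are broken by organ label then lesion id
#' (lexicographic), so the selection is deterministic. Under these caps
#' the greedy choice maximises the total selected diameter.
#'
#' @param baseline Data frame of one assessment's measurement rows
#'   (columns `lesion_id`, `organ`, `diameter_mm`).
#' @param max_total Maximum number of target lesions (default 5).
#' @param max_per_organ Maximum per organ (default 2).
#' @return Character vector of selected `lesion_id`s, in selection order.
#' @export
select_target_lesions <- function(baseline, max_total = 5, max_per_organ = 2) {
  b <- as_tibble(baseline)
  b <- b[b$diameter_mm > 0, , drop = FALSE]
  if (nrow(b) == 0) abort("no measurable disease at baseline.")
  ord <- order(-b$diameter_mm, b$organ, b$lesion_id)
  b <- b[ord, , drop = FALSE]
  chosen <- character(0)
  organ_count <- integer(0)
  for (i in seq_len(nrow(b))) {
    if (length(chosen) >= max_total) break
    org <- b$organ[i]
    cnt <- if (org %in% names(organ_count)) organ_count[[org]] else 0L
    if (cnt < max_per_organ) {
      chosen <- c(chosen, b$lesion_id[i])
      organ_count[[org]] <- cnt + 1L
    }
  }
  chosen
}

#' Sum of target-lesion diameters at one assessment
#'
#' @param assessment Data frame of one assessment's measurement rows.
#' @param target_ids Lesion ids selected at baseline.
#' @return Sum of diameters in mm. A target lesion absent from the
#'   assessment is an error: a vanished lesion must be recorded as 0 mm.
#' @export
sum_of_diameters <- function(assessment, target_ids) {
  a <- as_tibble(assessment)
  idx <- match(target_ids, a$lesion_id)
  if (anyNA(idx)) {
    abort(paste0("target lesion(s) missing from assessment: ",
                 paste(target_ids[is.na(idx)], collapse = ", "),
                 " (record vanished lesions as 0 mm)"))
  }
  sum(a$diameter_mm[idx])
}

#' Mean attenuation of target lesions at one assessment
#'
#' Unweighted arithmetic mean of the available HU values across target
#' lesions; `NA` when no target lesion has an HU value.
#'
#' @inheritParams sum_of_diameters
#' @return Mean HU, or `NA`.
#' @export
mean_attenuation <- function(assessment, target_ids) {
  a <- as_tibble(assessment)
  hu <- a$attenuation_hu[a$lesion_id %in% target_ids]
  hu <- hu[!is.na(hu)]
  if (length(hu) == 0) NA_real_ else mean(hu)
}

# Vectorised per-patient classification. `meas` is this patient's
# measurement rows (base data frame); returns a base data frame of
# follow-up rows, or NULL when the patient has no usable baseline.
classify_patient <- function(meas, criterion, config) {
  pre <- meas$day <= 0
  if (!any(pre)) return(NULL)
  b_day <- max(meas$day[pre])
  base <- meas[meas$day == b_day, , drop = FALSE]
  if (!any(base$diameter_mm > 0)) return(NULL)
  targets <- select_target_lesions(base)
  baseline_sum <- sum_of_diameters(base, targets)
  baseline_hu <- mean_attenuation(base, targets)

  fu_days <- sort(unique(meas$day[meas$day > b_day]))
  n_fu <- length(fu_days)
  if (n_fu == 0) return(NULL)

  out <- vector("list", n_fu)
  nadir <- baseline_sum
  choi_hu_missing_baseline <- criterion == "CHOI" && is.na(baseline_hu)
  for (i in seq_len(n_fu)) {
    a <- meas[meas$day == fu_days[i], , drop = FALSE]
    s <- sum_of_diameters(a, targets)
    hu <- mean_attenuation(a, targets)
    new_lesion <- any(a$is_new)
    nontarget <- any(a$nontarget_progression)
    pct_base <- 100 * (s - baseline_sum) / baseline_sum
    pct_nadir <- if (nadir > 0) 100 * (s - nadir) / nadir else Inf
    abs_nadir <- s - nadir
    pct_hu <- if (!is.na(baseline_hu) && !is.na(hu) && baseline_hu != 0) {
      100 * (hu - baseline_hu) / baseline_hu
    } else NA_real_

    flag <- NA_character_
    if (criterion == "RECIST") {
      if (new_lesion) {
        label <- "PD"; trigger <- "new_lesion"
      } else if (nontarget) {
        label <- "PD"; trigger <- "nontarget_progression"
      } else if (pct_nadir >= config$recist_pd_threshold &&
                 abs_nadir >= config$recist_pd_abs_mm) {
        label <- "PD"; trigger <- "size_pd"
      } else if (s == 0) {
        label <- "CR"; trigger <- "cr"
      } else if (pct_base <= config$recist_pr_threshold) {
        label <- "PR"; trigger <- "size_pr"
      } else {
        label <- "SD"; trigger <- "size_sd"
      }
    } else {
      hu_pr <- !is.na(pct_hu) && pct_hu <= config$choi_hu_pr_threshold
      if (choi_hu_missing_baseline) {
        flag <- "no_baseline_hu"
      } else if (is.na(hu)) {
        flag <- "hu_unavailable"
      }
      pd_ref_pct <- if (config$reference_policy_choi_pd == "baseline") {
        pct_base
      } else {
        pct_nadir
      }
      if (new_lesion) {
        label <- "PD"; trigger <- "new_lesion"
      } else if (nontarget) {
        label <- "PD"; trigger <- "nontarget_progression"
      } else if (s == 0) {
        label <- "CR"; trigger <- "cr"
      } else if (hu_pr) {
        label <- "PR"; trigger <- "hu_drop"
      } else if (pd_ref_pct >= config$choi_pd_threshold) {
        label <- "PD"; trigger <- "size_pd"
      } else if (pct_base <= config$choi_size_pr_threshold) {
        label <- "PR"; trigger <- "size_pr"
      } else {
        label <- "SD"; trigger <- "size_sd"
      }
    }

    out[[i]] <- data.frame(
      day = fu_days[i], label = label, sum_diameters = s,
      mean_hu = if (is.na(hu)) NA_real_ else hu,
      pct_change_size_vs_baseline = pct_base,
      pct_change_size_vs_nadir = if (is.finite(pct_nadir)) pct_nadir else NA_real_,
      pct_change_hu_vs_baseline = pct_hu,
      trigger = trigger, flag = flag,
      baseline_day = b_day, baseline_sum = baseline_sum,
      baseline_hu = baseline_hu,
      stringsAsFactors = FALSE
    )
    if (label == "PD") {
      out <- out[seq_len(i)]
      break
    }
    nadir <- min(nadir, s)
  }
  res <- do.call(rbind, out)
  if (choi_hu_missing_baseline) {
    warn(paste0("patient ", meas$patient_id[1],
                ": baseline HU unavailable; Choi classified on size only."))
  }
  res
}

classify_cohort_impl <- function(cohort, criterion, config) {
  m <- cohort_measurements(cohort)
  by_pat <- split(as.data.frame(m), m$patient_id)
  rows <- lapply(names(by_pat), function(pid) {
    r <- classify_patient(by_pat[[pid]], criterion, config)
    if (is.null(r)) return(NULL)
    cbind(data.frame(patient_id = pid, criterion = criterion,
                     stringsAsFactors = FALSE), r)
  })
  bound <- do.call(rbind, rows)
  res <- if (is.null(bound)) NULL else as_tibble(bound)
  if (is.null(res) || nrow(res) == 0) {
    res <- tibble(
      patient_id = character(), criterion = character(), day = integer(),
      label = character(), sum_diameters = double(), mean_hu = double(),
      pct_change_size_vs_baseline = double(),
      pct_change_size_vs_nadir = double(),
      pct_change_hu_vs_baseline = double(), trigger = character(),
      flag = character(), baseline_day = integer(), baseline_sum = double(),
      baseline_hu = double()
    )
  }
  res$label <- factor(res$label, levels = response_levels)
  class(res) <- c("response_series", class(res))
  res
}

#' Classify tumour response per RECIST v1.1
#'
#' Applies RECIST v1.1 to each patient's target-lesion series. Per
#' follow-up assessment: PD if a new lesion or unequivocal non-target
#' progression is present, or the sum of diameters has increased vs the
#' nadir by at least +20% and at least 5 mm; otherwise CR if the sum is
#' 0, PR if the change vs baseline is at or below -30%, else SD. The
#' nadir is the smallest sum observed so far, baseline included.
#' Progression-vs-nadir takes precedence over PR-vs-baseline, as in
#' standard RECIST practice. A patient's series terminates at the first
#' PD; later assessments are not evaluated.
#'
#' Patients without a usable baseline (no assessment in day \[-28, 0\],
#' or no measurable lesion there, or no follow-up) are omitted; use
#' [validate_cohort()] to list them.
#'
#' @param cohort A [lesion_cohort()] or measurements data frame.
#' @param config A [criterion_config()].
#' @return A `response_series` tibble: one row per evaluated follow-up
#'   assessment with the label, sums, percent changes and the rule that
#'   fired (`trigger`).
#' @export
classify_recist <- function(cohort, config = criterion_config()) {
  classify_cohort_impl(cohort, "RECIST", config)
}

#' Classify tumour response per Choi criteria
#'
#' Applies Choi criteria: PR if the sum of diameters has decreased vs
#' baseline by at least 10% or the mean target-lesion attenuation has
#' dropped vs baseline by at least 15%, with no new lesion; PD if the
#' size increase vs the configured reference (baseline by default) is at
#' least +10% and the attenuation-PR condition is not met, or a new
#' lesion / unequivocal non-target progression is present; CR if the sum
#' is 0; else SD. A tumour that grows but hypo-attenuates by >= 15% is
#' thus a responder, not a progressor. When HU is unavailable at a
#' follow-up the attenuation clause is treated as not met and the row is
#' flagged `"hu_unavailable"`; a missing baseline HU triggers a warning
#' and size-only classification flagged `"no_baseline_hu"`. The series
#' terminates at the first PD.
#'
#' @inheritParams classify_recist
#' @return A `response_series` tibble (see [classify_recist()]).
#' @export
classify_choi <- function(cohort, config = criterion_config()) {
  classify_cohort_impl(cohort, "CHOI", config)
}

#' Response label at a landmark time
#'
#' Returns, per patient, the label of the assessment closest to
#' `landmark_day` within `window_days`. If the patient's series
#' terminated with PD on or before `landmark_day + window_days`, the PD
#' is carried forward; otherwise the label is missing when no assessment
#' falls in the window.
#'
#' @param responses A `response_series` tibble from [classify_recist()]
#'   or [classify_choi()].
#' @param landmark_day Landmark in days from treatment start (default
#'   183, ~6 months).
#' @param window_days Half-width of the acceptance window in days
#'   (default 60).
#' @return Tibble `patient_id`, `day` (of the used assessment), `label`
#'   (`NA` when unavailable).
#' @export
response_at <- function(responses, landmark_day = 183, window_days = 60) {
  if (window_days < 0) abort("`window_days` must be >= 0.")
  r <- as_tibble(responses)
  if (nrow(r) == 0) {
    return(tibble(patient_id = character(), day = integer(),
                  label = factor(character(), levels = response_levels)))
  }
  by_pat <- split(r, r$patient_id)
  rows <- lapply(by_pat, function(d) {
    pd <- d[d$label == "PD" & d$day <= landmark_day + window_days, , drop = FALSE]
    if (nrow(pd) > 0) {
      return(tibble(patient_id = d$patient_id[1], day = pd$day[1],
                    label = "PD"))
    }
    inwin <- d[abs(d$day - landmark_day) <= window_days, , drop = FALSE]
    if (nrow(inwin) == 0) {
      return(tibble(patient_id = d$patient_id[1], day = NA_integer_,
                    label = NA_character_))
    }
    k <- order(abs(inwin$day - landmark_day), inwin$day)[1]
    tibble(patient_id = d$patient_id[1], day = inwin$day[k],
           label = as.character(inwin$label[k]))
  })
  out <- bind_rows(rows)
  out$label <- factor(out$label, levels = response_levels)
  arrange(out, .data$patient_id)
}

#' Cross-tabulate RECIST vs Choi response at a landmark
#'
#' Builds the 3x3 transition table (rows RECIST PR/SD/PD, columns Choi
#' PR/SD/PD; CR folded into PR) over patients with both labels available
#' at the landmark.
#'
#' @param recist,choi `response_series` tibbles for the two criteria.
#' @inheritParams response_at
#' @return A `transition_table`: list with the 3x3 integer `counts`
#'   matrix and `n`.
#' @export
transition_table <- function(recist, choi, landmark_day = 183,
                             window_days = 60) {
  r <- response_at(recist, landmark_day, window_days)
  c_ <- response_at(choi, landmark_day, window_days)
  merged <- left_join(
    select(r, "patient_id", recist = "label"),
    select(c_, "patient_id", choi = "label"),
    by = "patient_id"
  )
  merged <- merged[!is.na(merged$recist) & !is.na(merged$choi), , drop = FALSE]
  fold <- function(x) {
    x <- as.character(x)
    x[x == "CR"] <- "PR"
    factor(x, levels = c("PR", "SD", "PD"))
  }
  counts <- table(RECIST = fold(merged$recist), Choi = fold(merged$choi))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(RECIST = c("PR", "SD", "PD"),
                                   Choi = c("PR", "SD", "PD")))
  new_transition_table(counts, landmark_day, window_days)
}

new_transition_table <- function(counts, landmark_day = NA, window_days = NA) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(3, 3)),
            all(counts >= 0))
  dimnames(counts) <- list(RECIST = c("PR", "SD", "PD"),
                           Choi = c("PR", "SD", "PD"))
  structure(list(counts = counts, n = sum(counts),
                 landmark_day = landmark_day, window_days = window_days),
            class = "transition_table")
}

#' Reconstruct a transition table from published marginals
#'
#' Recovers the full 3x3 RECIST-by-Choi table from summary numbers of the
#' kind reported with transition diagrams: the two sets of category
#' marginals (as percentages of n, converted to counts by
#' nearest-integer rounding), the two off-diagonal cells of the
#' RECIST-SD row, and the structural implication that a RECIST PR (>=30%
#' shrinkage) always satisfies the 10% Choi size criterion, so the
#' RECIST-PR row is concentrated in Choi PR. The PD row then follows
#' from the column margins.
#'
#' @param recist_margins_pct Length-3 numeric, RECIST PR/SD/PD marginal
#'   percentages.
#' @param choi_margins_pct Length-3 numeric, Choi PR/SD/PD marginal
#'   percentages.
#' @param n Number of evaluable patients.
#' @param sd_to_pr Count of RECIST-SD patients reclassified Choi-PR.
#' @param sd_to_pd Count of RECIST-SD patients reclassified Choi-PD.
#' @return A `transition_table`.
#' @export
reconstruct_transition_table <- function(recist_margins_pct,
                                         choi_margins_pct,
                                         n, sd_to_pr, sd_to_pd) {
  row_m <- round(recist_margins_pct / 100 * n)
  col_m <- round(choi_margins_pct / 100 * n)
  if (sum(row_m) != n || sum(col_m) != n) {
    abort("rounded marginals do not sum to n.")
  }
  counts <- matrix(0L, 3, 3)
  counts[1, ] <- c(row_m[1], 0L, 0L)                      # RECIST PR => Choi PR
  counts[2, ] <- c(sd_to_pr, row_m[2] - sd_to_pr - sd_to_pd, sd_to_pd)
  counts[3, ] <- col_m - colSums(counts[1:2, , drop = FALSE])
  if (any(counts < 0) || any(rowSums(counts) != row_m)) {
    abort("marginals and cells are inconsistent; no valid table exists.")
  }
  new_transition_table(counts)
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' @export
as.matrix.transition_table <- function(x, ...) x$counts

#' @rdname transition_table
#' @param x A `transition_table`.
#' @param ... Unused.
#' @export
tidy.transition_table <- function(x, ...) {
  counts <- x$counts
  tibble(
    recist = rep(rownames(counts), times = 3),
    choi = rep(colnames(counts), each = 3),
    count = as.integer(counts)
  )
}

#' Cohen's kappa for a square agreement table
#'
#' Unweighted kappa, `(p_o - p_e) / (1 - p_e)`, with observed agreement
#' `p_o = trace/n` and chance agreement `p_e` from the products of the
#' marginals.
#'
#' @param table A `transition_table` or square numeric matrix of counts.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(table) {
  m <- if (inherits(table, "transition_table")) table$counts else as.matrix(table)
  if (nrow(m) != ncol(m)) abort("agreement table must be square.")
  n <- sum(m)
  if (n == 0) abort("empty table: kappa undefined.")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe == 1) {
    if (po == 1) return(1)
    abort("degenerate margins: kappa undefined.")
  }
  (po - pe) / (1 - pe)
}
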