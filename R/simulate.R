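#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort of ~85 patients with slow-growing,
#' liver-dominant, hypervascular multi-lesion disease followed by CT at
#' 3-6-month intervals: a responder phenotype whose attenuation drops
#' early while diameters change little, a minority of deep responders
#' reaching RECIST PR, growing-but-hypoattenuating patients that are
#' discordant between criteria, progression-triggered new lesions,
#' post-progression death and administrative right-censoring.
#'
#' All rates are per month on the diameter log scale unless noted;
#' percentages are relative changes.
#'
#' @param n_patients Cohort size.
#' @param seed Master seed; per-patient sub-streams are derived from it.
#' @param lesion_count_probs Probabilities for 1-6 baseline lesions.
#' @param organ_probs Named organ sampling weights (liver-dominant).
#' @param baseline_diameter_meanlog,baseline_diameter_sdlog Log-normal
#'   baseline lesion diameter (mm).
#' @param baseline_hu_mean,baseline_hu_sd Normal baseline mean
#'   arterial-phase attenuation (HU).
#' @param responder_fraction Fraction with an early attenuation response.
#' @param deep_response_fraction Fraction of responders whose shrinkage
#'   reaches the RECIST PR range.
#' @param discordant_pd_fraction Fraction growing on treatment while
#'   hypo-attenuating (Choi PR, RECIST progression track).
#' @param hu_drop_mean,hu_drop_sd Responder attenuation drop (%) at the
#'   first on-treatment scan, maintained until progression.
#' @param hu_drift_mean,hu_drift_sd Non-responder attenuation change (%).
#' @param growth_rate_mean,growth_rate_sd Non-responder diameter
#'   log-growth rate per month (median TGR a few percent/month).
#' @param shrink_rate_mean,shrink_rate_sd Responder diameter log-rate.
#' @param deep_shrink_rate_mean,deep_shrink_rate_sd Deep-responder rate.
#' @param progression_median_months,progression_sdlog Log-normal latent
#'   progression time for non-responders; responders progress later by
#'   `responder_progression_multiplier`.
#' @param responder_progression_multiplier See above.
#' @param post_progression_growth Diameter log-rate after progression.
#' @param new_lesion_prob Probability a new lesion is reported at the
#'   first scan after latent progression.
#' @param post_progression_survival_months Mean exponential lag from
#'   progression to death.
#' @param min_death_months Floor on death time (guarantees at least one
#'   on-treatment scan, as protocol-conformant series require).
#' @param censor_min_months,censor_max_months Administrative censoring
#'   window (uniform).
#' @param scan_interval_days,scan_interval_sd Scheduled CT spacing and
#'   jitter (days).
#' @param max_followup_months Imaging stops after this horizon.
#' @param diameter_noise_sd,hu_noise_sd Measurement noise (mm, HU).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 85,
                              seed = 1L,
                              lesion_count_probs = c(0.25, 0.30, 0.20, 0.12, 0.08, 0.05),
                              organ_probs = c(liver = 0.70, lymph_node = 0.15,
                                              lung = 0.05, peritoneum = 0.05,
                                              other = 0.05),
                              baseline_diameter_meanlog = log(25),
                              baseline_diameter_sdlog = 0.5,
                              baseline_hu_mean = 110,
                              baseline_hu_sd = 20,
                              responder_fraction = 0.45,
                              deep_response_fraction = 0.28,
                              discordant_pd_fraction = 0.10,
                              hu_drop_mean = -28,
                              hu_drop_sd = 8,
                              hu_drift_mean = -3,
                              hu_drift_sd = 5,
                              growth_rate_mean = 0.015,
                              growth_rate_sd = 0.010,
                              shrink_rate_mean = -0.020,
                              shrink_rate_sd = 0.010,
                              deep_shrink_rate_mean = -0.075,
                              deep_shrink_rate_sd = 0.020,
                              progression_median_months = 9,
                              progression_sdlog = 0.5,
                              responder_progression_multiplier = 2.0,
                              post_progression_growth = 0.06,
                              new_lesion_prob = 0.5,
                              post_progression_survival_months = 14,
                              min_death_months = 4.5,
                              censor_min_months = 24,
                              censor_max_months = 42,
                              scan_interval_days = 105,
                              scan_interval_sd = 15,
                              max_followup_months = 42,
                              diameter_noise_sd = 1.5,
                              hu_noise_sd = 5) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$lesion_count_probs) - 1) > 1e-8) {
    abort("`lesion_count_probs` must sum to 1.")
  }
  probs <- c(cfg$responder_fraction, cfg$deep_response_fraction,
             cfg$discordant_pd_fraction, cfg$new_lesion_prob)
  if (any(probs < 0 | probs > 1)) abort("fractions must lie in [0, 1].")
  if (cfg$censor_max_months < cfg$censor_min_months) {
    abort("censoring window is inverted.")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a synthetic lesion cohort
#'
#' Generates per-lesion diameter/attenuation series and outcomes with
#' the statistical structure the response and surrogacy analyses assume
#' (see [simulation_config()]). Each lesion evolves as exponential
#' growth or shrinkage with a patient-level rate; responders additionally
#' receive an early attenuation drop at the first on-treatment scan.
#' Growth accelerates at the latent progression time, when a new lesion
#' may also be reported; death follows progression after an exponential
#' lag, and follow-up is administratively censored. All randomness flows
#' from `config$seed` via per-patient sub-streams, so output is
#' reproducible and independent of patient order.
#'
#' @param config A [simulation_config()].
#' @return A [lesion_cohort()]; conformant with [validate_cohort()] in
#'   strict mode by construction.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().")
  }
  cfg <- config
  set.seed(cfg$seed)
  pat_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_patients)
  per_patient <- lapply(seq_len(cfg$n_patients), function(i) {
    set.seed(pat_seeds[i])
    simulate_patient(sprintf("P%03d", i), cfg)
  })
  measurements <- bind_rows(lapply(per_patient, `[[`, "measurements"))
  outcomes <- bind_rows(lapply(per_patient, `[[`, "outcomes"))
  lesion_cohort(measurements, outcomes)
}

simulate_patient <- function(pid, cfg) {
  n_lesions <- sample.int(6, 1, prob = cfg$lesion_count_probs)
  organs <- sample(names(cfg$organ_probs), n_lesions, replace = TRUE,
                   prob = cfg$organ_probs)
  d0 <- rlnorm(n_lesions, cfg$baseline_diameter_meanlog,
               cfg$baseline_diameter_sdlog)
  hu0 <- pmax(40, rnorm(n_lesions, cfg$baseline_hu_mean, cfg$baseline_hu_sd))

  u <- runif(1)
  phenotype <- if (u < cfg$responder_fraction) {
    if (runif(1) < cfg$deep_response_fraction) "deep_responder" else "responder"
  } else if (u < cfg$responder_fraction + cfg$discordant_pd_fraction) {
    "discordant"
  } else {
    "nonresponder"
  }
  rate <- switch(phenotype,
    deep_responder = rnorm(1, cfg$deep_shrink_rate_mean, cfg$deep_shrink_rate_sd),
    responder = rnorm(1, cfg$shrink_rate_mean, cfg$shrink_rate_sd),
    discordant = rnorm(1, cfg$growth_rate_mean + 0.010, cfg$growth_rate_sd),
    nonresponder = rnorm(1, cfg$growth_rate_mean, cfg$growth_rate_sd)
  )
  hu_mult <- if (phenotype %in% c("responder", "deep_responder", "discordant")) {
    1 + rnorm(1, cfg$hu_drop_mean, cfg$hu_drop_sd) / 100
  } else {
    1 + rnorm(1, cfg$hu_drift_mean, cfg$hu_drift_sd) / 100
  }
  prog_mult <- if (phenotype %in% c("responder", "deep_responder")) {
    cfg$responder_progression_multiplier
  } else 1
  t_prog <- rlnorm(1, log(cfg$progression_median_months * prog_mult),
                   cfg$progression_sdlog)
  t_death <- max(t_prog + rexp(1, 1 / cfg$post_progression_survival_months),
                 cfg$min_death_months)
  t_censor <- runif(1, cfg$censor_min_months, cfg$censor_max_months)
  t_end <- min(t_death, t_censor, cfg$max_followup_months)

  baseline_day <- -round(runif(1, 3, 21))
  scan_days <- baseline_day
  day <- 0
  repeat {
    day <- day + max(30, round(rnorm(1, cfg$scan_interval_days,
                                     cfg$scan_interval_sd)))
    if (day / DAYS_PER_MONTH > t_end) break
    scan_days <- c(scan_days, day)
  }
  # protocol-conformant series need at least one on-treatment scan
  if (length(scan_days) < 2) scan_days <- c(baseline_day, day)

  new_lesion_day <- NA_integer_
  if (runif(1) < cfg$new_lesion_prob) {
    cand <- scan_days[scan_days / DAYS_PER_MONTH >= t_prog]
    if (length(cand) > 0) new_lesion_day <- cand[1]
  }

  rows <- lapply(seq_along(scan_days), function(k) {
    dday <- scan_days[k]
    t_m <- max(dday, 0) / DAYS_PER_MONTH
    on_treatment <- dday > 0
    # piecewise log-linear diameter: treatment-phase rate, then accelerated
    # growth after latent progression
    t_pre <- min(t_m, t_prog)
    t_post <- max(0, t_m - t_prog)
    diam <- d0 * exp(rate * t_pre + cfg$post_progression_growth * t_post)
    hu_scale <- if (on_treatment) hu_mult else 1
    diam_obs <- pmax(0, diam + rnorm(length(diam), 0, cfg$diameter_noise_sd))
    hu_obs <- hu0 * hu_scale + rnorm(length(hu0), 0, cfg$hu_noise_sd)
    out <- data.frame(
      patient_id = pid, day = as.integer(dday),
      lesion_id = sprintf("%s_L%d", pid, seq_along(diam)),
      organ = organs, diameter_mm = round(diam_obs, 1),
      attenuation_hu = round(hu_obs, 1),
      is_new = FALSE, nontarget_progression = FALSE,
      stringsAsFactors = FALSE
    )
    if (!is.na(new_lesion_day) && dday >= new_lesion_day) {
      nl_months <- (dday - new_lesion_day) / DAYS_PER_MONTH
      nl_diam <- 8 * exp(cfg$post_progression_growth * nl_months)
      out <- rbind(out, data.frame(
        patient_id = pid, day = as.integer(dday),
        lesion_id = paste0(pid, "_Lnew"), organ = "liver",
        diameter_mm = round(max(0, nl_diam + rnorm(1, 0, cfg$diameter_noise_sd)), 1),
        attenuation_hu = round(rnorm(1, cfg$baseline_hu_mean, cfg$baseline_hu_sd), 1),
        is_new = dday == new_lesion_day, nontarget_progression = FALSE,
        stringsAsFactors = FALSE
      ))
    }
    out
  })
  death_day <- if (t_death <= min(t_censor, cfg$max_followup_months)) {
    as.integer(round(t_death * DAYS_PER_MONTH))
  } else NA_integer_
  last_day <- max(vapply(rows, function(r) max(r$day), numeric(1)))
  last_followup_day <- if (!is.na(death_day)) {
    as.integer(max(death_day, last_day))
  } else {
    as.integer(max(round(min(t_censor, cfg$max_followup_months) *
                           DAYS_PER_MONTH), last_day))
  }
  list(
    measurements = do.call(rbind, rows),
    outcomes = data.frame(patient_id = pid, death_day = death_day,
                          last_followup_day = last_followup_day,
                          stringsAsFactors = FALSE)
  )
}

#' Simulate censored PFS/OS pairs from a Clayton copula
#'
#' Samples latent (progression, death) times with Clayton(theta)
#' dependence by conditional inversion, maps them through exponential
#' margins, and builds semi-competing pairs: PFS is the minimum of the
#' latent progression and death times, so PFS <= OS holds by
#' construction, and independent censoring is applied to both endpoints.
#' The margins default to a progression-dominant regime (latent
#' progression much faster than death) so that death-first ties — which
#' are perfectly concordant and would otherwise push the pair dependence
#' above the copula's Kendall's tau of `theta / (theta + 2)` — stay
#' rare.
#'
#' @param theta Clayton dependence parameter (> 0; values near 0 give
#'   independence).
#' @param n Number of pairs.
#' @param censoring_rate Target censoring fraction on the OS margin
#'   (exponential censoring; 0 disables).
#' @param seed Seed.
#' @param pfs_scale,os_scale Exponential means (months) of the latent
#'   progression and death margins.
#' @return Tibble `patient_id`, `pfs_time`, `pfs_event`, `os_time`,
#'   `os_event`.
#' @export
simulate_clayton_pairs <- function(theta, n, censoring_rate = 0, seed = 1L,
                                   pfs_scale = 3, os_scale = 90) {
  if (theta < 0) abort("`theta` must be >= 0.")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must be in [0, 1).")
  }
  set.seed(seed)
  U <- runif(n)
  W <- runif(n)
  V <- if (theta > 1e-8) {
    ((W^(-theta / (1 + theta)) - 1) * U^(-theta) + 1)^(-1 / theta)
  } else {
    W
  }
  t_prog <- -log(U) * pfs_scale
  t_death <- -log(V) * os_scale
  pfs <- pmin(t_prog, t_death)
  cens <- if (censoring_rate > 0) {
    rexp(n, censoring_rate / (1 - censoring_rate) / os_scale)
  } else {
    rep(Inf, n)
  }
  tibble(
    patient_id = sprintf("S%04d", seq_len(n)),
    pfs_time = pmin(pfs, cens), pfs_event = pfs <= cens,
    os_time = pmin(t_death, cens), os_event = t_death <= cens
  )
}
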