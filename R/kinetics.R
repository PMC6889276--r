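#' Tumour growth (TG)
#'
#' Log-scale growth rate `TG = 3 * ln(Dt / D0) / t`, where `D0` and `Dt`
#' are sums of target-lesion diameters (mm) at the interval's origin and
#' endpoint and `t` is the elapsed time in months. The factor 3 converts
#' a diameter ratio to a volume-scale log-ratio (sphere approximation);
#' the logarithm is natural.
#'
#' @param D0,Dt Diameter sums in mm, strictly positive.
#' @param t Elapsed time in months, strictly positive.
#' @return TG, per month (vectorised).
#' @export
tumor_growth <- function(D0, Dt, t) {
  if (any(D0 <= 0, na.rm = TRUE) || any(Dt <= 0, na.rm = TRUE)) {
    abort("`D0` and `Dt` must be strictly positive.")
  }
  if (any(t <= 0, na.rm = TRUE)) abort("`t` must be strictly positive.")
  3 * log(Dt / D0) / t
}

#' Tumour growth rate (TGR)
#'
#' Expresses TG as a percent volume change over one month:
#' `TGR = 100 * (exp(TG) - 1)`.
#'
#' @param TG Growth rate from [tumor_growth()].
#' @return Percent per month (vectorised).
#' @export
tgr <- function(TG) {
  if (any(!is.finite(TG) & !is.na(TG))) abort("`TG` must be finite.")
  100 * (exp(TG) - 1)
}

#' Diameter variation rate (DVR)
#'
#' Relative change in the diameter sum divided by the elapsed time:
#' `100 * (Dt - D0) / D0 / t`, percent per month.
#'
#' @inheritParams tumor_growth
#' @return Percent per month (vectorised).
#' @export
dvr <- function(D0, Dt, t) {
  if (any(D0 <= 0, na.rm = TRUE)) abort("`D0` must be strictly positive.")
  if (any(t <= 0, na.rm = TRUE)) abort("`t` must be strictly positive.")
  100 * (Dt - D0) / D0 / t
}

#' Attenuation variation rate (AVR)
#'
#' Relative change in mean attenuation divided by the elapsed time:
#' `100 * (HUt - HU0) / HU0 / t`, percent per month.
#'
#' @param HU0,HUt Mean attenuation in HU at origin and endpoint; `HU0`
#'   must be strictly positive.
#' @param t Elapsed time in months, strictly positive.
#' @return Percent per month (vectorised).
#' @export
avr <- function(HU0, HUt, t) {
  if (any(HU0 <= 0, na.rm = TRUE)) abort("`HU0` must be strictly positive.")
  if (any(t <= 0, na.rm = TRUE)) abort("`t` must be strictly positive.")
  100 * (HUt - HU0) / HU0 / t
}

#' Share of variance explained between two rate series
#'
#' Squared Pearson correlation over complete pairs. Sign-blind: a
#' perfectly anti-correlated pair also yields 1.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs.
#' @return R-squared in \[0, 1\].
#' @export
variance_explained <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("need at least 3 complete pairs.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("zero variance in a series: R-squared undefined.")
  }
  cor(x[ok], y[ok])^2
}

#' Kendall rank correlation between two rate series
#'
#' Kendall's tau-b over complete pairs.
#'
#' @param x,y Numeric vectors of equal length; at least 2 complete pairs.
#' @return Tau in \[-1, 1\].
#' @export
rank_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2) abort("need at least 2 complete pairs.")
  if (length(unique(x[ok])) == 1 && length(unique(y[ok])) == 1) {
    abort("all pairs tied: tau undefined.")
  }
  cor(x[ok], y[ok], method = "kendall")
}

#' Per-patient growth and attenuation kinetics
#'
#' Computes TG, TGR, DVR and AVR for each patient over each evaluation
#' interval, from the target-lesion diameter sums and mean attenuations.
#' Two interval families are emitted, distinguished by `interval_type`:
#' `"from_baseline"` rows run from the baseline values to each follow-up
#' scan with `t` measured from day 0 (treatment start) to the scan, the
#' convention used for response-rate analyses even when the baseline scan
#' precedes day 0; `"previous"` rows run between consecutive scans.
#'
#' Rates are `NA` where undefined (non-positive diameters for TG, missing
#' or non-positive baseline HU for AVR).
#'
#' @param cohort A [lesion_cohort()] or measurements data frame.
#' @return Tibble with columns `patient_id`, `interval_type`, `day_from`,
#'   `day_to`, `t_months`, `D0`, `Dt`, `HU0`, `HUt`, `TG`, `TGR`, `DVR`,
#'   `AVR`.
#' @export
compute_kinetics <- function(cohort) {
  m <- cohort_measurements(cohort)
  by_pat <- split(as.data.frame(m), m$patient_id)
  rows <- lapply(by_pat, function(meas) {
    pre <- meas$day <= 0
    if (!any(pre)) return(NULL)
    b_day <- max(meas$day[pre])
    base <- meas[meas$day == b_day, , drop = FALSE]
    if (!any(base$diameter_mm > 0)) return(NULL)
    targets <- select_target_lesions(base)
    days <- sort(unique(meas$day))
    sums <- vapply(days, function(d) {
      sum_of_diameters(meas[meas$day == d, , drop = FALSE], targets)
    }, numeric(1))
    hus <- vapply(days, function(d) {
      mean_attenuation(meas[meas$day == d, , drop = FALSE], targets)
    }, numeric(1))
    i_b <- match(b_day, days)
    fu <- which(days > b_day)
    if (length(fu) == 0) return(NULL)
    # origin for elapsed time is treatment start (day 0), even when the
    # baseline scan was performed up to 4 weeks earlier
    t_base <- pmax(days[fu], 1) / DAYS_PER_MONTH
    from_baseline <- data.frame(
      patient_id = meas$patient_id[1], interval_type = "from_baseline",
      day_from = b_day, day_to = days[fu], t_months = t_base,
      D0 = sums[i_b], Dt = sums[fu], HU0 = hus[i_b], HUt = hus[fu],
      stringsAsFactors = FALSE
    )
    prev_i <- c(i_b, fu[-length(fu)])
    t_prev <- (days[fu] - days[prev_i]) / DAYS_PER_MONTH
    previous <- data.frame(
      patient_id = meas$patient_id[1], interval_type = "previous",
      day_from = days[prev_i], day_to = days[fu], t_months = t_prev,
      D0 = sums[prev_i], Dt = sums[fu], HU0 = hus[prev_i], HUt = hus[fu],
      stringsAsFactors = FALSE
    )
    rbind(from_baseline, previous)
  })
  bound <- do.call(rbind, rows)
  k <- if (is.null(bound)) NULL else as_tibble(bound)
  if (is.null(k) || nrow(k) == 0) {
    return(tibble(
      patient_id = character(), interval_type = character(),
      day_from = integer(), day_to = integer(), t_months = double(),
      D0 = double(), Dt = double(), HU0 = double(), HUt = double(),
      TG = double(), TGR = double(), DVR = double(), AVR = double()
    ))
  }
  ok_d <- k$D0 > 0 & k$Dt > 0 & k$t_months > 0
  k$TG <- ifelse(ok_d, 3 * log(k$Dt / k$D0) / k$t_months, NA_real_)
  k$TGR <- 100 * (exp(k$TG) - 1)
  k$DVR <- ifelse(k$D0 > 0 & k$t_months > 0,
                  100 * (k$Dt - k$D0) / k$D0 / k$t_months, NA_real_)
  ok_h <- !is.na(k$HU0) & !is.na(k$HUt) & k$HU0 > 0 & k$t_months > 0
  k$AVR <- ifelse(ok_h, 100 * (k$HUt - k$HU0) / k$HU0 / k$t_months, NA_real_)
  k
}
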