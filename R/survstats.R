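#' Kaplan-Meier curve with median and log-log confidence bands
#'
#' Product-limit estimate with Greenwood variance and log-log 95%
#' intervals, via [survival::survfit()]. The median is the first time at
#' which the estimated survival drops to 0.5 or below; `NA` ("not
#' reached") when the curve never does.
#'
#' @param records Data frame with columns `time` and `event` (logical or
#'   0/1).
#' @return A `km_curve` object: list with `$steps` (tibble `time`,
#'   `n_risk`, `n_event`, `surv`, `ci_low`, `ci_high`), `$median`,
#'   `$median_ci` (length-2), `$n`.
#' @export
km_curve <- function(records) {
  r <- as_tibble(records)
  if (nrow(r) == 0) abort("need at least one record.")
  fit <- survival::survfit(survival::Surv(r$time, r$event) ~ 1,
                           conf.type = "log-log")
  # median = first time S(t) drops to 0.5 or below (no averaging over
  # horizontal segments); CI bounds from the log-log confidence curves
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  q <- quantile(fit, probs = 0.5)
  med_ci <- c(unname(q$lower), unname(q$upper))
  structure(
    list(
      steps = tibble(
        time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
        surv = fit$surv, ci_low = fit$lower, ci_high = fit$upper
      ),
      median = med, median_ci = med_ci, n = fit$n
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n, " median =",
      if (is.na(x$median)) "not reached" else
        sprintf("%.2f (95%% CI %.2f-%.2f)", x$median,
                x$median_ci[1], x$median_ci[2]), "\n")
  invisible(x)
}

#' @rdname km_curve
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) x$steps

#' Survival at a step function time
#' @noRd
km_surv_at <- function(fit, t) {
  s <- summary(fit, times = t, extend = TRUE)
  s$surv
}

#' Landmark conditional survival by response group
#'
#' Restricts to patients event-free and still under follow-up at the
#' landmark, groups them by their response label at the landmark, and
#' estimates the conditional Kaplan-Meier survival from the landmark,
#' reported at the horizon with a log-log 95% interval. This avoids the
#' immortal-time bias of naive responder/non-responder comparisons.
#'
#' @param records Survival tibble (`patient_id`, `time` months, `event`).
#' @param groups Tibble `patient_id`, `label` — response category at the
#'   landmark (e.g. from [response_at()]); patients with `NA` labels are
#'   dropped.
#' @param landmark,horizon Months; `horizon > landmark`. Both measured
#'   from treatment start.
#' @return Tibble `label`, `landmark`, `horizon`, `survival`, `ci_low`,
#'   `ci_high`, `n_at_risk`. Empty groups are omitted with a warning.
#' @export
landmark_survival <- function(records, groups, landmark = 6, horizon = 24) {
  if (horizon <= landmark) abort("`horizon` must exceed `landmark`.")
  r <- as_tibble(records)
  g <- as_tibble(groups)
  g <- g[!is.na(g$label), , drop = FALSE]
  d <- dplyr::inner_join(r, select(g, "patient_id", "label"),
                         by = "patient_id")
  # at risk at the landmark: no event and not censored before it
  d <- d[d$time > landmark | (d$time == landmark & !d$event), , drop = FALSE]
  labels <- unique(as.character(g$label))
  out <- lapply(labels, function(lab) {
    di <- d[as.character(d$label) == lab, , drop = FALSE]
    if (nrow(di) == 0) {
      warn(paste0("landmark group '", lab, "' is empty; omitted."))
      return(NULL)
    }
    fit <- survival::survfit(
      survival::Surv(di$time - landmark, di$event) ~ 1,
      conf.type = "log-log"
    )
    s <- summary(fit, times = horizon - landmark, extend = TRUE)
    tibble(
      label = lab, landmark = landmark, horizon = horizon,
      survival = s$surv, ci_low = s$lower, ci_high = s$upper,
      n_at_risk = nrow(di)
    )
  })
  bind_rows(out)
}

#' Mantel-Byar test for response-state survival comparison
#'
#' A modification of the log-rank test in which each patient contributes
#' person-time to the non-responder group until their response
#' (transition) time and to the responder group afterwards, avoiding the
#' guarantee-time bias of landmark-free responder analyses. At each
#' event time the observed number of events in the responder state is
#' compared to its hypergeometric expectation given the current risk
#' sets; the accumulated observed-minus-expected over its variance is
#' chi-square with 1 degree of freedom.
#'
#' @param transitions Tibble `patient_id`, `transition_time` (months;
#'   `NA` for patients who never enter the responder state).
#' @param records Survival tibble (`patient_id`, `time`, `event`).
#' @return A `mantel_byar_test`: list with `statistic`, `p_value`,
#'   `observed`, `expected`, `variance`, `n_transitions`.
#' @export
mantel_byar <- function(transitions, records) {
  r <- as_tibble(records)
  tr <- as_tibble(transitions)
  if (any(tr$transition_time < 0, na.rm = TRUE)) {
    abort("`transition_time` must be >= 0.")
  }
  d <- left_join(r, select(tr, "patient_id", "transition_time"),
                 by = "patient_id")
  s <- ifelse(is.na(d$transition_time), Inf, d$transition_time)
  event_times <- sort(unique(d$time[d$event]))
  if (length(event_times) == 0 || nrow(d) < 2) {
    return(new_mantel_byar(0, 0, 0, sum(is.finite(s) & s <= d$time)))
  }
  O <- E <- V <- 0
  for (t in event_times) {
    at_risk <- d$time >= t
    exposed <- at_risk & s < t           # entered responder state before t
    n <- sum(at_risk)
    n1 <- sum(exposed)
    dt <- sum(d$event & d$time == t)
    d1 <- sum(d$event & d$time == t & exposed)
    O <- O + d1
    E <- E + dt * n1 / n
    if (n > 1) V <- V + dt * (n1 / n) * (1 - n1 / n) * (n - dt) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  new_mantel_byar(stat, O, E, V,
                  n_transitions = sum(is.finite(s) & s <= d$time))
}

new_mantel_byar <- function(stat, O, E, V = 0, n_transitions = 0) {
  structure(
    list(statistic = stat,
         p_value = if (V > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1,
         observed = O, expected = E, variance = V,
         n_transitions = n_transitions),
    class = "mantel_byar_test"
  )
}

#' @export
print.mantel_byar_test <- function(x, ...) {
  cat(sprintf(
    "<mantel_byar_test> chi-square = %.4f (1 df), p = %.4g; O = %g, E = %.2f\n",
    x$statistic, x$p_value, x$observed, x$expected))
  invisible(x)
}

#' @rdname mantel_byar
#' @param x A `mantel_byar_test`.
#' @param ... Unused.
#' @export
tidy.mantel_byar_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         observed = x$observed, expected = x$expected,
         n_transitions = x$n_transitions)
}

#' Cox model with a single binary time-dependent covariate
#'
#' Maximum partial likelihood for a proportional-hazards model whose only
#' covariate switches from 0 to 1 at a per-patient transition time (e.g.
#' documented response). Ties are handled by the Breslow approximation;
#' the scalar Newton iteration runs to a gradient tolerance of 1e-8. The
#' 95% interval is Wald on the log hazard ratio.
#'
#' @param records Survival tibble (`patient_id`, `time`, `event`).
#' @param transitions Tibble `patient_id`, `transition_time` (months,
#'   `NA` = never switches). A transition at time 0 means the covariate
#'   is 1 throughout.
#' @param label Covariate label carried into the tidy output.
#' @return A `cox_td_fit`: list with `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `beta`, `se`, `n`, `n_events`, `iterations`, `label`.
#' @export
cox_td <- function(records, transitions, label = "response") {
  r <- as_tibble(records)
  tr <- as_tibble(transitions)
  d <- left_join(r, select(tr, "patient_id", "transition_time"),
                 by = "patient_id")
  s <- ifelse(is.na(d$transition_time), Inf, d$transition_time)
  if (sum(d$event) < 2) abort("need at least 2 events.")
  event_times <- sort(unique(d$time[d$event]))
  # per event time: deaths in each state and risk-set composition
  z_at_event <- (s < d$time) & d$event           # covariate of the dying subject
  sum_z_events <- sum(z_at_event)
  n1 <- vapply(event_times, function(t) sum(d$time >= t & s < t), numeric(1))
  n0 <- vapply(event_times, function(t) sum(d$time >= t & s >= t), numeric(1))
  dt <- vapply(event_times, function(t) sum(d$event & d$time == t), numeric(1))
  if (all(n1 == 0) || all(n0 == 0)) {
    abort("HR not estimable: covariate has no contrast over the risk sets.")
  }
  beta <- 0
  for (iter in 1:50) {
    w1 <- n1 * exp(beta)
    denom <- w1 + n0
    mu <- w1 / denom
    grad <- sum_z_events - sum(dt * mu)
    info <- sum(dt * mu * (1 - mu))
    if (info <= 0) abort("HR not estimable: no events in one state.")
    step <- grad / info
    beta <- beta + step
    if (abs(grad) < 1e-8) break
  }
  if (abs(grad) >= 1e-8) {
    abort("Newton iteration failed to converge (monotone likelihood?).")
  }
  se <- 1 / sqrt(info)
  structure(
    list(
      hr = exp(beta),
      ci_low = exp(beta - qnorm(0.975) * se),
      ci_high = exp(beta + qnorm(0.975) * se),
      p_value = 2 * pnorm(-abs(beta / se)),
      beta = beta, se = se, n = nrow(d), n_events = sum(d$event),
      iterations = iter, label = label
    ),
    class = "cox_td_fit"
  )
}

#' @export
print.cox_td_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_td_fit> %s: HR %.3f (95%% CI %.3f-%.3f), p = %.4g, %d events\n",
    x$label, x$hr, x$ci_low, x$ci_high, x$p_value, x$n_events))
  invisible(x)
}

#' @rdname cox_td
#' @param x A `cox_td_fit`.
#' @param ... Unused.
#' @export
tidy.cox_td_fit <- function(x, ...) {
  tibble(term = x$label, estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p_value,
         hr = x$hr, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname cox_td
#' @export
glance.cox_td_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, iterations = x$iterations)
}

#' Wilcoxon signed-rank test for paired series
#'
#' Compares paired measurements (e.g. size or attenuation changes
#' between consecutive radiological studies). Exact distribution when at
#' most 25 non-zero differences, normal approximation with continuity
#' correction above. All-zero differences are degenerate with p = 1.
#'
#' @param before,after Numeric vectors of equal length.
#' @return List `statistic` (V), `p_value`, `n_nonzero`, `method`.
#' @export
paired_wilcoxon <- function(before, after) {
  if (length(before) != length(after)) abort("series must have equal length.")
  diffs <- after - before
  diffs <- diffs[!is.na(diffs)]
  nz <- sum(diffs != 0)
  if (nz == 0) {
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate (all differences zero)"))
  }
  exact <- nz <= 25
  wt <- suppressWarnings(
    wilcox.test(diffs, mu = 0, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = as.integer(nz), method = wt$method)
}
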