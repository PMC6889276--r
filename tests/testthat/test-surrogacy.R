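test_that("Kaplan-Meier curve matches hand-computed product-limit values", {
  # uncensored 1..10
  km <- km_curve(tibble::tibble(time = 1:10, event = TRUE))
  expect_equal(km$steps$surv[km$steps$time == 5], 0.5)
  expect_equal(km$median, 5)

  # all censored: flat curve, median not reached
  km2 <- km_curve(tibble::tibble(time = c(3, 8, 12), event = FALSE))
  expect_true(all(km2$steps$surv == 1))
  expect_true(is.na(km2$median))

  # n = 6 mixed set vs hand-computed product-limit table:
  # times 1, 2+, 3, 4, 5+, 6 -> S = 5/6, 5/6*3/4, *2/3, *0
  km3 <- km_curve(tibble::tibble(time = c(1, 2, 3, 4, 5, 6),
                                 event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)))
  ev <- km3$steps[km3$steps$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 4, 6))
  expect_equal(ev$surv, c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)
})

test_that("landmark estimates are conditional and avoid immortal-time bias", {
  # no censoring: plain conditional proportion
  rec <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:10),
    time = c(25, 26, 30, 40, 10, 12, 15, 18, 20, 23),
    event = TRUE
  )
  grp <- tibble::tibble(patient_id = rec$patient_id, label = "SD")
  lm <- landmark_survival(rec, grp, landmark = 6, horizon = 24)
  expect_equal(lm$survival, 0.4)
  expect_equal(lm$n_at_risk, 10)
  expect_true(lm$ci_low <= lm$survival && lm$survival <= lm$ci_high)

  # patient progressing before the landmark is excluded from the group
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(patient_id = "P11", time = 3,
                                               event = TRUE))
  grp2 <- dplyr::bind_rows(grp, tibble::tibble(patient_id = "P11", label = "SD"))
  lm2 <- landmark_survival(rec2, grp2, landmark = 6, horizon = 24)
  expect_equal(lm2$n_at_risk, 10)

  # exponential closed form: S(24 | 6) = exp(-18 * lambda)
  set.seed(21)
  lam <- 1 / 20
  rec3 <- tibble::tibble(patient_id = sprintf("E%04d", 1:4000),
                         time = rexp(4000, lam), event = TRUE)
  grp3 <- tibble::tibble(patient_id = rec3$patient_id, label = "all")
  lm3 <- landmark_survival(rec3, grp3, landmark = 6, horizon = 24)
  expect_equal(lm3$survival, exp(-18 * lam), tolerance = 0.05)

  # landmark 0 equals the unconditional KM at the horizon
  km <- km_curve(rec)
  lm0 <- landmark_survival(rec, grp, landmark = 0, horizon = 24)
  s24 <- min(km$steps$surv[km$steps$time <= 24])
  expect_equal(lm0$survival, s24, tolerance = 1e-12)

  expect_warning(
    landmark_survival(rec, dplyr::mutate(grp, label = c("X", rep("SD", 9))),
                      landmark = 30, horizon = 40),
    "empty")
})

test_that("Mantel-Byar with all transitions at zero equals the log-rank test", {
  set.seed(31)
  n <- 60
  grp1 <- rbinom(n, 1, 0.5)
  t_lat <- rexp(n, ifelse(grp1 == 1, 1 / 8, 1 / 14))
  cens <- runif(n, 5, 30)
  rec <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                        time = pmin(t_lat, cens), event = t_lat <= cens)
  tr <- tibble::tibble(patient_id = rec$patient_id,
                       transition_time = ifelse(grp1 == 1, 0, NA_real_))
  mb <- mantel_byar(tr, rec)
  sd_ <- survival::survdiff(survival::Surv(rec$time, rec$event) ~ grp1)
  expect_equal(mb$statistic, sd_$chisq, tolerance = 1e-8)
  expect_equal(mb$p_value, pchisq(sd_$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("Mantel-Byar handles degenerate inputs", {
  one <- tibble::tibble(patient_id = "P1", time = 5, event = TRUE)
  tr1 <- tibble::tibble(patient_id = "P1", transition_time = 2)
  expect_equal(mantel_byar(tr1, one)$statistic, 0)
  none <- tibble::tibble(patient_id = c("A", "B"), time = c(5, 7),
                         event = FALSE)
  tr2 <- tibble::tibble(patient_id = c("A", "B"), transition_time = c(1, NA))
  res <- mantel_byar(tr2, none)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(
    mantel_byar(dplyr::mutate(tr2, transition_time = c(-1, 2)), none),
    ">= 0")
})

test_that("time-dependent Cox matches coxph for time-fixed covariates", {
  set.seed(41)
  n <- 50
  z <- rbinom(n, 1, 0.4)
  t_lat <- rexp(n, 0.1 * exp(log(2) * z))
  cens <- runif(n, 2, 25)
  rec <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                        time = pmin(t_lat, cens), event = t_lat <= cens)
  tr <- tibble::tibble(patient_id = rec$patient_id,
                       transition_time = ifelse(z == 1, 0, NA_real_))
  fit <- cox_td(rec, tr)
  oracle <- survival::coxph(survival::Surv(rec$time, rec$event) ~ z,
                            ties = "breslow")
  expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$se, unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-4)
  expect_equal(fit$hr, unname(exp(coef(oracle))), tolerance = 1e-4)
})

test_that("time-dependent Cox matches counting-process coxph with switches", {
  set.seed(43)
  n <- 120
  s <- ifelse(rbinom(n, 1, 0.6) == 1, runif(n, 1, 10), NA)
  lam0 <- 1 / 15
  hr <- 2
  t0 <- rexp(n, lam0)
  t_lat <- ifelse(!is.na(s) & t0 > s, s + rexp(n, lam0 * hr), t0)
  cens <- runif(n, 3, 40)
  rec <- tibble::tibble(patient_id = sprintf("P%03d", 1:n),
                        time = pmin(t_lat, cens), event = t_lat <= cens)
  tr <- tibble::tibble(patient_id = rec$patient_id, transition_time = s)
  fit <- cox_td(rec, tr)
  # independent oracle: (start, stop] counting-process representation
  rows <- lapply(seq_len(n), function(i) {
    if (is.na(s[i]) || s[i] >= rec$time[i]) {
      data.frame(start = 0, stop = rec$time[i], ev = rec$event[i], z = 0)
    } else {
      rbind(
        data.frame(start = 0, stop = s[i], ev = FALSE, z = 0),
        data.frame(start = s[i], stop = rec$time[i], ev = rec$event[i], z = 1)
      )
    }
  })
  cp <- do.call(rbind, rows)
  oracle <- survival::coxph(
    survival::Surv(cp$start, cp$stop, cp$ev) ~ cp$z, ties = "breslow")
  expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(fit$se, unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-4)

  # no contrast -> not estimable
  tr0 <- dplyr::mutate(tr, transition_time = NA_real_)
  expect_error(cox_td(rec, tr0), "not estimable")
})

test_that("paired Wilcoxon matches exact sign-pattern enumeration", {
  before <- c(12.1, 10.5, 14.2, 9.8, 11.0, 13.3, 10.1, 12.7)
  after <- c(11.0, 10.9, 12.5, 9.1, 10.2, 12.0, 10.6, 11.1)
  res <- paired_wilcoxon(before, after)
  # oracle: enumerate all 2^8 sign assignments of the ranked |differences|
  d <- after - before
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  vs <- vapply(0:(2^8 - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:8]
    sum(rk[signs == 1])
  }, numeric(1))
  p_exact <- mean(vs <= v_obs) * 2
  p_exact <- min(1, p_exact)
  expect_equal(res$statistic, v_obs)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)

  expect_equal(paired_wilcoxon(before, before)$p_value, 1)

  set.seed(51)
  x <- rnorm(100)
  expect_lt(paired_wilcoxon(x, x + 1)$p_value, 1e-3)
})

test_that("Clayton fit recovers the dependence parameter", {
  # tau = theta / (theta + 2) identity and shrinking bias with n
  for (n in c(100, 500, 2000)) {
    pairs <- simulate_clayton_pairs(theta = 2, n = n, censoring_rate = 0,
                                    seed = 61)
    fit <- fit_clayton(pairs, B = 0)
    expect_true(fit$converged)
    expect_equal(fit$tau, fit$theta / (fit$theta + 2), tolerance = 1e-12)
    tol <- c(`100` = 0.12, `500` = 0.06, `2000` = 0.04)[[as.character(n)]]
    expect_equal(fit$tau, 0.5, tolerance = tol)
  }
})

test_that("Clayton fit flags the comonotone boundary and reports bootstrap SE", {
  t <- rexp(50, 1 / 10)
  pairs <- tibble::tibble(patient_id = sprintf("P%02d", 1:50),
                          pfs_time = t, pfs_event = TRUE,
                          os_time = t, os_event = TRUE)
  fit <- fit_clayton(pairs, B = 0)
  expect_true(!fit$converged || fit$tau > 0.9)

  pairs2 <- simulate_clayton_pairs(2, 120, censoring_rate = 0.2, seed = 63)
  fit2 <- fit_clayton(pairs2, B = 30, seed = 7)
  expect_true(is.finite(fit2$se_tau) && fit2$se_tau > 0)
  expect_lt(fit2$se_tau, 0.5)
  g <- glance(fit2)
  expect_equal(g$tau, fit2$tau)
  expect_error(fit_clayton(pairs2[1:5, ]), "at least 10")
})

test_that("Clayton pair simulation has the stated dependence and structure", {
  p <- simulate_clayton_pairs(theta = 2, n = 4000, censoring_rate = 0,
                              seed = 71)
  expect_true(all(p$pfs_time <= p$os_time))
  expect_true(all(p$pfs_event & p$os_event))
  expect_equal(cor(p$pfs_time, p$os_time, method = "kendall"), 0.5,
               tolerance = 0.04)
  p0 <- simulate_clayton_pairs(theta = 1e-9, n = 4000, censoring_rate = 0,
                               seed = 72)
  expect_equal(cor(p0$pfs_time, p0$os_time, method = "kendall"), 0,
               tolerance = 0.04)
  # deterministic under seed
  expect_identical(simulate_clayton_pairs(2, 100, 0.2, seed = 9),
                   simulate_clayton_pairs(2, 100, 0.2, seed = 9))
  cens <- simulate_clayton_pairs(2, 2000, censoring_rate = 0.2, seed = 73)
  expect_equal(mean(!cens$os_event), 0.2, tolerance = 0.05)
})
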