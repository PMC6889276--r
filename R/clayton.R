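#' Fit a Clayton copula to censored PFS/OS pairs
#'
#' Two-stage semiparametric estimation of the Clayton dependence
#' parameter for right-censored bivariate survival data. Stage one
#' estimates the marginal survival functions of the two endpoints by
#' Kaplan-Meier and transforms each observation to the survival-uniform
#' scale, using the left-continuous estimate S(t-) so that fully
#' observed extremes do not collapse to zero. Stage two maximises the
#' censored-data pseudo-likelihood over theta > 0, with the four
#' censoring-pattern contributions: both events use the copula density;
#' one censored observation uses the corresponding partial derivative of
#' the copula; both censored uses the copula (joint survival) itself.
#' Kendall's tau is theta / (theta + 2); its standard error comes from
#' `B` nonparametric bootstrap resamples of patients.
#'
#' Tied pairs with `pfs_time == os_time` and both events (death before
#' documented progression) enter the both-event contribution at equal
#' uniforms without jittering.
#'
#' @param pairs Bivariate pairs tibble (`pfs_time`, `pfs_event`,
#'   `os_time`, `os_event`), e.g. from [pair_endpoints()] or
#'   [simulate_clayton_pairs()].
#' @param B Bootstrap replicates for the SE of tau (default 200; 0 skips
#'   the bootstrap and leaves the SE `NA`).
#' @param seed Seed for the bootstrap resampling.
#' @param theta_interval Search interval for theta.
#' @return A `clayton_fit`: list with `theta`, `tau`, `se_tau`,
#'   `n_pairs`, `B`, `converged`, `loglik`.
#' @export
fit_clayton <- function(pairs, B = 200, seed = 1L,
                        theta_interval = c(1e-6, 50)) {
  p <- as_tibble(pairs)
  need <- c("pfs_time", "pfs_event", "os_time", "os_event")
  miss <- setdiff(need, names(p))
  if (length(miss) > 0) {
    abort(paste0("pairs lack column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(p) < 10) abort("need at least 10 pairs.")
  est <- clayton_point_estimate(p, theta_interval)
  se_tau <- NA_real_
  if (B > 0 && est$converged) {
    taus <- numeric(B)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(p), replace = TRUE)
      eb <- clayton_point_estimate(p[idx, , drop = FALSE], theta_interval)
      taus[b] <- if (eb$converged) eb$tau else NA_real_
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    se_tau <- sd(taus, na.rm = TRUE)
  }
  structure(
    list(theta = est$theta, tau = est$tau, se_tau = se_tau,
         n_pairs = nrow(p), B = B, converged = est$converged,
         loglik = est$loglik),
    class = "clayton_fit"
  )
}

# Left-continuous KM plug-in: S(t-) evaluated at each observation.
km_uniform <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- c(1, fit$surv)[findInterval(time, fit$time, left.open = TRUE) + 1]
  pmax(s, 1e-10)
}

clayton_neg_loglik <- function(theta, u, v, d1, d2) {
  lu <- log(u); lv <- log(v)
  lA <- log(u^(-theta) + v^(-theta) - 1)
  ll <- ifelse(
    d1 & d2,
    log1p(theta) + (-theta - 1) * (lu + lv) + (-1 / theta - 2) * lA,
    ifelse(
      d1 & !d2, (-theta - 1) * lu + (-1 / theta - 1) * lA,
      ifelse(
        !d1 & d2, (-theta - 1) * lv + (-1 / theta - 1) * lA,
        (-1 / theta) * lA
      )
    )
  )
  -sum(ll)
}

clayton_point_estimate <- function(p, theta_interval) {
  u <- km_uniform(p$pfs_time, p$pfs_event)
  v <- km_uniform(p$os_time, p$os_event)
  opt <- tryCatch(
    suppressWarnings(optimize(
      clayton_neg_loglik, interval = theta_interval,
      u = u, v = v, d1 = as.logical(p$pfs_event),
      d2 = as.logical(p$os_event)
    )),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$objective)) {
    return(list(theta = NA_real_, tau = NA_real_, converged = FALSE,
                loglik = NA_real_))
  }
  theta <- opt$minimum
  list(theta = theta, tau = theta / (theta + 2),
       converged = theta < theta_interval[2] * 0.999,
       loglik = -opt$objective)
}

#' @export
print.clayton_fit <- function(x, ...) {
  cat(sprintf(
    "<clayton_fit> theta = %.3f, Kendall's tau = %.3f (SE %s), n = %d%s\n",
    x$theta, x$tau,
    if (is.na(x$se_tau)) "NA" else sprintf("%.3f", x$se_tau),
    x$n_pairs,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @rdname fit_clayton
#' @param x A `clayton_fit`.
#' @param ... Unused.
#' @export
tidy.clayton_fit <- function(x, ...) {
  tibble(term = c("theta", "tau"),
         estimate = c(x$theta, x$tau),
         std.error = c(NA_real_, x$se_tau))
}

#' @rdname fit_clayton
#' @export
glance.clayton_fit <- function(x, ...) {
  tibble(theta = x$theta, tau = x$tau, se_tau = x$se_tau,
         n_pairs = x$n_pairs, B = x$B, converged = x$converged,
         loglik = x$loglik)
}
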