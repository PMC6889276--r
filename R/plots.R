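#' Spider plot of per-patient relative change over time
#'
#' One line per patient: percent change vs baseline in the diameter sum
#' (`metric = "size"`) or mean attenuation (`metric = "hu"`), against
#' months on treatment.
#'
#' @param responses A `response_series` tibble.
#' @param metric `"size"` or `"hu"`.
#' @return A ggplot object.
#' @export
plot_spider <- function(responses, metric = c("size", "hu")) {
  metric <- match.arg(metric)
  tab <- spider_table(responses)
  ycol <- if (metric == "size") "pct_change_size" else "pct_change_hu"
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$months, y = .data[[ycol]], group = .data$patient_id
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1.5) +
    ggplot2::labs(
      x = "Months from treatment start",
      y = if (metric == "size") "Δ sum of diameters (%)"
          else "Δ mean attenuation (%)",
      colour = "Response"
    ) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of attenuation change by patient
#'
#' Bars of the best percent attenuation change per patient, coloured by
#' the RECIST label at the landmark; bar height ordering mirrors the
#' tabular [waterfall_table()].
#'
#' @param analysis A `response_analysis`.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(analysis) {
  tab <- waterfall_table(analysis)
  tab <- tab[!is.na(tab$delta_hu_pct), , drop = FALSE]
  tab$patient_id <- factor(tab$patient_id, levels = tab$patient_id)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$patient_id, y = .data$delta_hu_pct, fill = .data$recist_label
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Best Δ mean attenuation (%)",
                  fill = "RECIST") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.response_series <- function(object, metric = "size", ...) {
  plot_spider(object, metric = metric)
}

#' @export
autoplot.transition_table <- function(object, ...) {
  tab <- tidy(object)
  tab$recist <- factor(tab$recist, levels = c("PR", "SD", "PD"))
  tab$choi <- factor(tab$choi, levels = c("PR", "SD", "PD"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$choi, y = .data$recist,
                                    fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Choi", y = "RECIST v1.1") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_curve <- function(object, ...) {
  st <- object$steps
  df <- tibble(
    time = c(0, st$time), surv = c(1, st$surv),
    ci_low = c(1, st$ci_low), ci_high = c(1, st$ci_high)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_low), linetype = 3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ci_high), linetype = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}
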