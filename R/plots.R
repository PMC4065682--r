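# ggplot2 views of the result types.

#' Plot dissolution profiles
#'
#' @param data Dissolution tibble (`product_id`, `time_min`,
#'   `pct_dissolved`).
#' @return A ggplot object.
#' @export
plot_dissolution <- function(data) {
  check_cols(data, c("product_id", "time_min", "pct_dissolved"))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$time_min, y = .data$pct_dissolved,
    colour = .data$product_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "% label dissolved",
                  colour = "Product") +
    ggplot2::theme_minimal()
}

#' Plot a plasma concentration study
#'
#' Per-subject concentration-time curves, faceted by brand when present.
#' Censored samples are dropped from the display.
#'
#' @param data Study tibble (`subject_id`, `time_hr`, `conc_mg_L`, ...).
#' @param log_y Use a log concentration axis? Default `FALSE`.
#' @return A ggplot object.
#' @export
plot_pk_study <- function(data, log_y = FALSE) {
  check_cols(data, c("subject_id", "time_hr", "conc_mg_L"))
  d <- data[!is.na(data$conc_mg_L), ]
  if (log_y) d <- d[d$conc_mg_L > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$time_hr, y = .data$conc_mg_L, group = .data$subject_id
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (hr)", y = "Concentration (mg/L)") +
    ggplot2::theme_minimal()
  if ("brand" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$brand))
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn fit_compartment_model Observed points and fitted curve.
#' @param object A `pk_fit`.
#' @param log_y Use a log concentration axis (the classic feathering view)?
#' @export
autoplot.pk_fit <- function(object, log_y = FALSE, ...) {
  grid <- seq(min(object$times), max(object$times), length.out = 200)
  obs <- tibble::tibble(time = object$times, conc = object$conc)
  mod <- tibble::tibble(time = grid, conc = predict(object, grid))
  if (log_y) {
    obs <- obs[obs$conc > 0, ]
    mod <- mod[mod$conc > 0, ]
  }
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$time, y = .data$conc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = mod, colour = "steelblue") +
    ggplot2::labs(
      x = "Time (hr)", y = "Concentration (mg/L)",
      title = sprintf("%s fit (SSE %.3g)", object$variant, object$sse)
    ) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @describeIn run_bioeq_study Relative-bioavailability chart with the 90\%
#'   interchangeability floor.
#' @param object A `bioeq_result`.
#' @export
autoplot.bioeq_result <- function(object, ...) {
  ggplot2::ggplot(object$fr, ggplot2::aes(
    x = .data$brand, y = .data$fr_ratio_of_means,
    fill = .data$interchangeable
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(90, 100), linetype = c(2, 3)) +
    ggplot2::labs(x = "Brand", y = "Relative bioavailability (%)",
                  fill = "Fr >= 90%") +
    ggplot2::theme_minimal()
}
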