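# Noncompartmental analysis: trapezoidal areas, terminal-slope selection,
# and the moment-based statistics derived from them.

#' Trapezoidal area under a concentration-time curve
#'
#' Linear trapezoidal AUC over the observed points, up to the last measurable
#' concentration. The `"linear-log"` method uses the log-trapezoid on
#' strictly declining positive segments (the lin-up/log-down rule) and the
#' linear rule elsewhere; the default is purely linear.
#'
#' @param times Sampling times in hours, strictly increasing.
#' @param conc Concentrations in mg/L, same length; censored samples must
#'   already be removed.
#' @param method `"linear"` (default) or `"linear-log"`.
#' @return AUC in hr·mg/L.
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 10, 0))  # 10
#' @export
auc_trapezoid <- function(times, conc, method = c("linear", "linear-log")) {
  method <- match.arg(method)
  check_times(times)
  check_numeric(conc, "conc", nonneg = TRUE)
  if (length(times) != length(conc)) {
    stop_input("`times` and `conc` must have equal length.")
  }
  if (length(times) < 2) {
    stop_input("At least 2 points are required for a trapezoidal area.")
  }
  dt <- diff(times)
  c1 <- head(conc, -1)
  c2 <- tail(conc, -1)
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear-log") {
    logdown <- c2 < c1 & c2 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
      log(c1[logdown] / c2[logdown])
  }
  sum(seg)
}

#' Trapezoidal area under the first-moment curve
#'
#' Applies the linear trapezoidal rule to \eqn{t \cdot C(t)}, giving the
#' AUMC used in mean-residence-time calculations.
#'
#' @inheritParams auc_trapezoid
#' @return AUMC in hr^2·mg/L.
#' @export
aumc_trapezoid <- function(times, conc) {
  auc_trapezoid(times, times * conc)
}

#' Terminal elimination slope by best-window log-linear regression
#'
#' Fits log-linear least squares on candidate terminal windows of at least 3
#' points that lie strictly after Tmax, and keeps the window maximising the
#' adjusted R-squared. The terminal half-life is `ln(2)/lambda_z`.
#'
#' @inheritParams auc_trapezoid
#' @return A list with `lambda_z` (1/hr), `hl` (hr), `n_points`, `r2`,
#'   `adj_r2`. All `NA` (with `n_points = 0`) when no window with a negative
#'   slope and positive concentrations exists.
#' @export
estimate_lambda_z <- function(times, conc) {
  check_times(times)
  not_est <- list(lambda_z = NA_real_, hl = NA_real_, n_points = 0L,
                  r2 = NA_real_, adj_r2 = NA_real_)
  i_max <- which.max(conc)[1]
  post <- which(seq_along(times) > i_max & conc > 0)
  if (length(post) < 3) {
    return(not_est)
  }
  best <- NULL
  for (k in 3:length(post)) {
    idx <- tail(post, k)
    fit <- lm(log(conc[idx]) ~ times[idx])
    slope <- coef(fit)[[2]]
    if (slope >= 0) next
    y <- log(conc[idx])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 0
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj_r2) {
      best <- list(lambda_z = -slope, hl = log(2) / -slope,
                   n_points = as.integer(k), r2 = r2, adj_r2 = adj)
    }
  }
  best %||% not_est
}

#' Noncompartmental analysis of one concentration-time profile
#'
#' Computes the full set of noncompartmental statistics for a single-dose
#' extravascular profile: observed Tmax/Cmax (earliest time on ties),
#' trapezoidal AUC and AUMC to the last measurable sample, the extrapolated
#' `auc_inf = auc_last + C_last / lambda_z`, mean residence time
#' `mrt_last = aumc_last / auc_last`, apparent clearance
#' `cl_f = dose / auc_inf`, terminal volume
#' `vz_f = dose / (lambda_z * auc_inf)`, and the moment-based variants
#' `kel_eq2 = 1 / mrt_last`, `hl_eq2 = 0.693 * mrt_last`, and the predicted
#' steady-state concentration `css_24h = auc_inf / 24` for a 24-hour dosing
#' interval. The moment-based rate constant and half-life are reported
#' separately from the regression-based `lambda_z` and `hl_lambda_z` and are
#' never mixed.
#'
#' @inheritParams auc_trapezoid
#' @param dose Administered dose in mg.
#' @param censored Optional logical vector; censored samples are dropped
#'   before analysis (a pre-dose zero is retained).
#' @return A one-row tibble with columns `tmax`, `cmax`, `auc_last`,
#'   `auc_inf`, `aumc_last`, `mrt_last`, `lambda_z`, `hl_lambda_z`, `vz_f`,
#'   `cl_f`, `kel_eq2`, `hl_eq2`, `css_24h`, `n_lambda_points`, `lambda_r2`.
#' @examples
#' tr <- rabbit_cipro_truth(0, 0)
#' tt <- rabbit_sampling_times()
#' cc <- conc_two_compartment_oral(tt, tr$ka, tr$v1_f, tr$k10,
#'                                 tr$k12, tr$k21, tr$dose)
#' nca_profile(tt, cc, dose = 500)
#' @export
nca_profile <- function(times, conc, dose, censored = NULL,
                        method = c("linear", "linear-log")) {
  method <- match.arg(method)
  check_numeric(dose, "dose", positive = TRUE)
  if (!is.null(censored)) {
    keep <- !censored
    times <- times[keep]
    conc <- conc[keep]
  }
  keep <- !is.na(conc)
  times <- times[keep]
  conc <- conc[keep]
  if (sum(conc > 0) < 2) {
    stop_input("Fewer than 2 measurable concentrations; NCA is not possible.",
               class = "pkbioeq_insufficient_data")
  }
  # extravascular anchor: a single dose implies C(0) = 0, so profiles that
  # start after dosing are integrated from an implicit (0, 0) sample
  if (times[1] > 0) {
    times <- c(0, times)
    conc <- c(0, conc)
  }
  i_max <- which.max(conc)[1]
  tmax <- times[i_max]
  cmax <- conc[i_max]
  auc_last <- auc_trapezoid(times, conc, method = method)
  aumc_last <- aumc_trapezoid(times, conc)
  mrt_last <- aumc_last / auc_last
  lam <- estimate_lambda_z(times, conc)
  c_last <- conc[max(which(conc > 0))]
  auc_inf <- if (is.na(lam$lambda_z)) NA_real_ else auc_last + c_last / lam$lambda_z
  cl_f <- dose / auc_inf
  vz_f <- dose / (lam$lambda_z * auc_inf)
  tibble::tibble(
    tmax = tmax, cmax = cmax,
    auc_last = auc_last, auc_inf = auc_inf, aumc_last = aumc_last,
    mrt_last = mrt_last,
    lambda_z = lam$lambda_z, hl_lambda_z = lam$hl,
    vz_f = vz_f, cl_f = cl_f,
    kel_eq2 = 1 / mrt_last, hl_eq2 = 0.693 * mrt_last,
    css_24h = auc_inf / 24,
    n_lambda_points = lam$n_points, lambda_r2 = lam$r2
  )
}

#' Noncompartmental analysis of a tabulated study
#'
#' Runs [nca_profile()] on every subject of a long-format study table (as
#' produced by [simulate_pk_study()], [simulate_bioeq_study()], or
#' [read_pk_study()]), preserving any `brand` grouping column.
#'
#' @param data A data frame with columns `subject_id`, `time_hr`,
#'   `conc_mg_L`, optionally `censored`, `dose_mg`, and `brand`.
#' @param dose Dose in mg; only needed when `data` lacks a `dose_mg` column.
#' @param method Trapezoid rule passed to [nca_profile()].
#' @return A tibble with one row per (brand,) subject and all [nca_profile()]
#'   columns.
#' @export
nca <- function(data, dose = NULL, method = c("linear", "linear-log")) {
  method <- match.arg(method)
  check_cols(data, c("subject_id", "time_hr", "conc_mg_L"))
  if (!"censored" %in% names(data)) data$censored <- FALSE
  if (!"dose_mg" %in% names(data)) {
    if (is.null(dose)) {
      stop_input("Provide `dose` or a `dose_mg` column.")
    }
    data$dose_mg <- dose
  }
  keys <- intersect(c("brand", "subject_id"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_hr, .by_group = TRUE) |>
    dplyr::group_modify(function(d, g) {
      nca_profile(d$time_hr, d$conc_mg_L, dose = d$dose_mg[1],
                  censored = d$censored, method = method)
    }) |>
    dplyr::ungroup()
}

#' Summarise noncompartmental results by brand
#'
#' Mean, standard deviation and n of every NCA statistic per brand, the usual
#' mean-plus-minus-SD presentation of formulation comparisons. For the
#' terminal half-life both aggregation conventions are available in the
#' output: the mean of per-subject half-lives (`hl_lambda_z` row) and the
#' half-life of the mean rate constant (`hl_of_mean_lambda_z` row), which
#' differ whenever `lambda_z` varies between subjects.
#'
#' @param nca_tbl Output of [nca()] containing a `brand` column.
#' @return A tibble with columns `brand`, `parameter`, `mean`, `sd`, `n`.
#' @export
nca_summary <- function(nca_tbl) {
  check_cols(nca_tbl, c("brand"), "nca_tbl")
  params <- setdiff(
    names(nca_tbl)[vapply(nca_tbl, is.numeric, logical(1))],
    c("n_lambda_points")
  )
  long <- nca_tbl |>
    tidyr::pivot_longer(dplyr::all_of(params),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$brand, .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  hl_ratio <- nca_tbl |>
    dplyr::group_by(.data$brand) |>
    dplyr::summarise(
      parameter = "hl_of_mean_lambda_z",
      mean = log(2) / mean(.data$lambda_z, na.rm = TRUE),
      sd = NA_real_,
      n = sum(!is.na(.data$lambda_z)),
      .groups = "drop"
    )
  dplyr::bind_rows(long, hl_ratio) |>
    dplyr::arrange(.data$brand, .data$parameter)
}
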