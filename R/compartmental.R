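# Compartmental model fitting: curve stripping for starting values,
# log-parameterized nonlinear least squares, and the macro/micro constant
# identities of the two-compartment open model.

FIT_VARIANTS <- c("oral_first_order", "iv_biexponential",
                  "oral_one_compartment", "iv_monoexponential")

#' Curve stripping (method of residuals) for a biexponential profile
#'
#' Classical feathering: a log-linear fit on the terminal window gives the
#' slow phase `B exp(-beta t)`; this is subtracted and the positive residuals
#' of the earlier post-peak points are fitted log-linearly to give the fast
#' phase `A exp(-alpha t)`. The result (always with `alpha > beta`) is the
#' standard initialization for nonlinear fitting. When the residual stage
#' degenerates (essentially monoexponential data) a flagged one-compartment
#' fallback is returned with `alpha` set to `5 * beta`.
#'
#' @inheritParams auc_trapezoid
#' @return A list with `A`, `B` (mg/L), `alpha`, `beta` (1/hr), and
#'   `fallback` (logical; `TRUE` when the fast phase could not be resolved).
#' @export
strip_residuals <- function(times, conc) {
  check_times(times)
  keep <- !is.na(conc) & conc > 0
  t_u <- times[keep]
  c_u <- conc[keep]
  if (length(t_u) < 5) {
    stop_input("Curve stripping needs at least 5 positive concentrations.")
  }
  lam <- estimate_lambda_z(t_u, c_u)
  if (is.na(lam$lambda_z)) {
    n <- length(t_u)
    idx <- (n - 2):n
    fit <- lm(log(c_u[idx]) ~ t_u[idx])
    beta <- max(-coef(fit)[[2]], 1e-6)
    b_int <- exp(coef(fit)[[1]])
    n_term <- 3L
  } else {
    beta <- lam$lambda_z
    n_term <- lam$n_points
    idx <- tail(seq_along(t_u), n_term)
    fit <- lm(log(c_u[idx]) ~ t_u[idx])
    b_int <- exp(coef(fit)[[1]])
  }
  i_peak <- which.max(c_u)[1]
  first_term <- length(t_u) - n_term + 1L
  resid <- c_u - b_int * exp(-beta * t_u)
  early <- which(seq_along(t_u) >= i_peak &
                 seq_along(t_u) < first_term & resid > 0)
  if (length(early) >= 2) {
    fit_a <- lm(log(resid[early]) ~ t_u[early])
    alpha <- -coef(fit_a)[[2]]
    a_int <- exp(coef(fit_a)[[1]])
    fallback <- FALSE
    if (!is.finite(alpha) || alpha <= 0) fallback <- TRUE
  } else {
    fallback <- TRUE
  }
  if (fallback) {
    alpha <- 5 * beta
    a_int <- max(c_u)
  }
  if (alpha < beta) {
    tmp <- alpha; alpha <- beta; beta <- tmp
    tmp <- a_int; a_int <- b_int; b_int <- tmp
  }
  list(A = a_int, B = b_int, alpha = alpha, beta = beta, fallback = fallback)
}

#' Micro rate constants from macro (hybrid) constants
#'
#' Standard two-compartment identities linking the biexponential intercepts
#' and slopes to the micro constants:
#' \deqn{k_{21} = \frac{A\beta + B\alpha}{A + B},\quad
#'       k_{10} = \frac{\alpha\beta}{k_{21}},\quad
#'       k_{12} = \alpha + \beta - k_{21} - k_{10}.}
#' With a dose, the apparent central volume `v1_f = dose / (A + B)` is also
#' returned.
#'
#' @param A,B Macro intercepts, mg/L (`A + B > 0`, both `>= 0`).
#' @param alpha,beta Macro rate constants, 1/hr, `alpha > beta > 0`.
#' @param dose Optional dose in mg for `v1_f`.
#' @return A list with `k21`, `k10`, `k12` (1/hr) and `v1_f` (L or `NA`).
#' @examples
#' m <- macro_constants(k10 = 0.5, k12 = 0.3, k21 = 0.2)
#' derive_microconstants(A = 1, B = 1, alpha = m$alpha, beta = m$beta)
#' @export
derive_microconstants <- function(A, B, alpha, beta, dose = NULL) {
  check_numeric(A, "A", nonneg = TRUE)
  check_numeric(B, "B", nonneg = TRUE)
  if (A + B <= 0) stop_input("`A + B` must be positive.")
  check_numeric(alpha, "alpha", positive = TRUE)
  check_numeric(beta, "beta", positive = TRUE)
  if (alpha <= beta) stop_input("`alpha` must exceed `beta`.")
  k21 <- (A * beta + B * alpha) / (A + B)
  k10 <- alpha * beta / k21
  k12 <- alpha + beta - k21 - k10
  if (k12 < -1e-8 * (alpha + beta)) {
    stop_input("Parameters imply k12 < 0; the fit is inconsistent with a two-compartment model.",
               class = "pkbioeq_inconsistent_fit")
  }
  k12 <- max(k12, 0)
  v1_f <- if (is.null(dose)) NA_real_ else dose / (A + B)
  list(k21 = k21, k10 = k10, k12 = k12, v1_f = v1_f)
}

# Small-sample corrected Akaike criterion from a least-squares fit;
# k = number of fitted mean parameters. Inf when the correction blows up.
aicc_from_sse <- function(sse, n, k) {
  if (n - k - 1 <= 0) {
    return(Inf)
  }
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Model curve for a natural-scale parameter vector, per variant.
model_curve <- function(variant, p, times, dose) {
  switch(variant,
    oral_first_order = conc2_core(times, p[["ka"]], p[["v1_f"]], p[["k10"]],
                                  p[["k12"]], p[["k21"]], dose),
    iv_biexponential = p[["A"]] * exp(-(p[["beta"]] + p[["dab"]]) * times) +
      p[["B"]] * exp(-p[["beta"]] * times),
    oral_one_compartment = conc1_core(times, p[["ka"]], p[["v_f"]],
                                      p[["ke"]], dose),
    iv_monoexponential = p[["C0"]] * exp(-p[["ke"]] * times)
  )
}

n_par_of <- c(oral_first_order = 5L, iv_biexponential = 4L,
              oral_one_compartment = 3L, iv_monoexponential = 2L)

# Starting values (natural scale) per variant, from curve stripping and the
# observed peak.
init_params <- function(variant, times, conc, dose) {
  i_peak <- which.max(conc)[1]
  tmax <- max(times[i_peak], min(times[times > 0]))
  ka0 <- 2 / tmax
  lam <- estimate_lambda_z(times, conc)
  ke0 <- if (is.na(lam$lambda_z)) 0.1 else lam$lambda_z
  auc_g <- auc_trapezoid(times, conc) + conc[length(conc)] / ke0
  switch(variant,
    oral_first_order = {
      s <- strip_residuals(times, conc)
      m <- derive_microconstants(s$A, s$B, s$alpha, s$beta)
      if (abs(ka0 - s$alpha) < 0.1 * s$alpha) ka0 <- ka0 * 1.3
      c(ka = ka0,
        v1_f = dose / (max(m$k10, 1e-3) * auc_g),
        k10 = max(m$k10, 1e-3), k12 = max(m$k12, 1e-3),
        k21 = max(m$k21, 1e-3))
    },
    iv_biexponential = {
      s <- strip_residuals(times, conc)
      c(A = s$A, B = s$B, beta = s$beta,
        dab = max(s$alpha - s$beta, 1e-3))
    },
    oral_one_compartment = c(ka = max(ka0, 2 * ke0), v_f = dose / (ke0 * auc_g),
                             ke = ke0),
    iv_monoexponential = c(C0 = max(conc), ke = ke0)
  )
}

#' Fit a compartmental model to one concentration-time profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) on log-parameterized rate
#' constants and volumes, started from the curve-stripping initialization
#' ([strip_residuals()]; absorption rate initialized from the observed Tmax
#' for the oral variants). Four model variants are available:
#' `"oral_first_order"` (two-compartment disposition with first-order
#' absorption, the default), `"iv_biexponential"` (classic
#' `A e^{-alpha t} + B e^{-beta t}`), and their one-compartment analogues
#' `"oral_one_compartment"` and `"iv_monoexponential"` used for model
#' selection. Log-parameterization enforces positivity of every parameter
#' (and `alpha > beta` for the biexponential, which is parameterized as
#' `beta` plus a positive gap). Convergence tolerance is 1e-10 on the
#' relative change in the residual sum of squares, with at most 500
#' iterations; non-convergence is flagged, not an error.
#'
#' @inheritParams nca_profile
#' @param variant Model variant, see Details.
#' @param weighting `"uniform"` (default), `"inv_c"` (weights 1/C) or
#'   `"inv_c2"` (weights 1/C^2) applied to squared residuals.
#' @return An object of class `pk_fit`; see [tidy.pk_fit()] and
#'   [glance.pk_fit()] for tabular views. Key elements: `coefficients`
#'   (natural-scale fitted parameters), `macro` (`A`, `B`, `alpha`, `beta`),
#'   `micro` (`k10`, `k12`, `k21`), `v1_f`, `v2_f`, `cl_f`, `alpha_hl`,
#'   `beta_hl`, `auc_model`, `tmax_pred`, `cmax_pred`, `sse`, `init_sse`,
#'   `aicc`, `converged`.
#' @examples
#' tr <- rabbit_cipro_truth(0, 0)
#' tt <- rabbit_sampling_times()
#' cc <- conc_two_compartment_oral(tt, tr$ka, tr$v1_f, tr$k10,
#'                                 tr$k12, tr$k21, tr$dose)
#' fit <- fit_compartment_model(tt, cc, dose = 500)
#' glance(fit)
#' @export
fit_compartment_model <- function(times, conc, dose,
                                  variant = FIT_VARIANTS,
                                  weighting = c("uniform", "inv_c", "inv_c2"),
                                  censored = NULL) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  check_numeric(dose, "dose", positive = TRUE)
  if (!is.null(censored)) {
    times <- times[!censored]
    conc <- conc[!censored]
  }
  keep <- !is.na(conc)
  times <- times[keep]
  conc <- conc[keep]
  check_times(times)
  n <- length(times)
  min_n <- if (variant == "oral_first_order") 6L else 4L
  if (n < min_n) {
    stop_input(sprintf("Variant '%s' needs at least %d usable points.",
                       variant, min_n))
  }
  w <- switch(weighting,
    uniform = rep(1, n),
    inv_c = 1 / pmax(conc, min(conc[conc > 0])),
    inv_c2 = 1 / pmax(conc, min(conc[conc > 0]))^2
  )
  sw <- sqrt(w)
  p0 <- init_params(variant, times, conc, dose)
  resid_fn <- function(lp) {
    p <- exp(pmin(pmax(lp, -25), 25))
    names(p) <- names(p0)
    sw * (conc - model_curve(variant, p, times, dose))
  }
  out <- minpack.lm::nls.lm(
    par = log(p0), fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)
  )
  converged <- out$info %in% 1:4
  p_hat <- exp(pmin(pmax(coef(out), -25), 25))
  names(p_hat) <- names(p0)
  if (!converged) {
    p_hat <- p0 # retain the stripping initialization when LM failed
  }
  sse <- sum((conc - model_curve(variant, p_hat, times, dose))^2)
  init_sse <- sum((conc - model_curve(variant, p0, times, dose))^2)
  fit <- structure(
    list(
      variant = variant, weighting = weighting,
      coefficients = p_hat, init = p0,
      dose = dose, times = times, conc = conc,
      n_obs = n, n_par = n_par_of[[variant]],
      sse = sse, init_sse = init_sse,
      aicc = aicc_from_sse(sse, n, n_par_of[[variant]]),
      converged = converged
    ),
    class = "pk_fit"
  )
  derive_fit_quantities(fit)
}

# Fill macro/micro constants, volumes, clearance, half-lives, model AUC and
# predicted peak for a fitted object.
derive_fit_quantities <- function(fit) {
  p <- fit$coefficients
  dose <- fit$dose
  if (fit$variant == "oral_first_order") {
    mac <- macro_constants(p[["k10"]], p[["k12"]], p[["k21"]])
    a <- mac$alpha; b <- mac$beta
    m <- p[["ka"]] * dose / p[["v1_f"]]
    A <- m * (p[["k21"]] - a) / ((p[["ka"]] - a) * (b - a))
    B <- m * (p[["k21"]] - b) / ((p[["ka"]] - b) * (a - b))
    Cka <- m * (p[["k21"]] - p[["ka"]]) /
      ((a - p[["ka"]]) * (b - p[["ka"]]))
    fit$macro <- list(A = A, B = B, alpha = a, beta = b)
    fit$micro <- list(k10 = p[["k10"]], k12 = p[["k12"]], k21 = p[["k21"]])
    fit$ka <- p[["ka"]]
    fit$v1_f <- p[["v1_f"]]
    fit$v2_f <- p[["v1_f"]] * p[["k12"]] / p[["k21"]]
    fit$auc_model <- A / a + B / b + Cka / p[["ka"]]
  } else if (fit$variant == "iv_biexponential") {
    A <- p[["A"]]; B <- p[["B"]]
    b <- p[["beta"]]; a <- b + p[["dab"]]
    mic <- derive_microconstants(A, B, a, b, dose = dose)
    fit$macro <- list(A = A, B = B, alpha = a, beta = b)
    fit$micro <- mic[c("k10", "k12", "k21")]
    fit$ka <- NA_real_
    fit$v1_f <- mic$v1_f
    fit$v2_f <- mic$v1_f * mic$k12 / mic$k21
    fit$auc_model <- A / a + B / b
  } else if (fit$variant == "oral_one_compartment") {
    fit$macro <- list(A = 0, B = dose / p[["v_f"]],
                      alpha = NA_real_, beta = p[["ke"]])
    fit$micro <- list(k10 = p[["ke"]], k12 = 0, k21 = NA_real_)
    fit$ka <- p[["ka"]]
    fit$v1_f <- p[["v_f"]]
    fit$v2_f <- 0
    fit$auc_model <- dose / (p[["ke"]] * p[["v_f"]])
  } else { # iv_monoexponential
    fit$macro <- list(A = 0, B = p[["C0"]], alpha = NA_real_,
                      beta = p[["ke"]])
    fit$micro <- list(k10 = p[["ke"]], k12 = 0, k21 = NA_real_)
    fit$ka <- NA_real_
    fit$v1_f <- dose / p[["C0"]]
    fit$v2_f <- 0
    fit$auc_model <- p[["C0"]] / p[["ke"]]
  }
  fit$cl_f <- dose / fit$auc_model
  fit$alpha_hl <- if (is.na(fit$macro$alpha)) NA_real_ else log(2) / fit$macro$alpha
  fit$beta_hl <- log(2) / fit$macro$beta
  pk <- predict_tmax_cmax(fit)
  fit$tmax_pred <- pk$tmax_pred
  fit$cmax_pred <- pk$cmax_pred
  fit
}

#' Predict a fitted model curve
#'
#' @param object A `pk_fit`.
#' @param times Times (hr) at which to evaluate; defaults to the fitted
#'   times.
#' @param ... Unused.
#' @return Numeric vector of model concentrations, mg/L.
#' @export
predict.pk_fit <- function(object, times = object$times, ...) {
  model_curve(object$variant, object$coefficients, times, object$dose)
}

#' Predicted time and height of the concentration peak
#'
#' For the oral variants the model curve is maximised numerically on
#' `[0, 5 * beta_hl]`; for the intravenous variants the peak is at time zero
#' with height `A + B`.
#'
#' @param fit A `pk_fit`.
#' @return A list with `tmax_pred` (hr) and `cmax_pred` (mg/L).
#' @export
predict_tmax_cmax <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  if (fit$variant %in% c("iv_biexponential", "iv_monoexponential")) {
    return(list(tmax_pred = 0, cmax_pred = fit$macro$A + fit$macro$B))
  }
  upper <- 5 * log(2) / fit$macro$beta
  opt <- optimize(function(t) predict(fit, t), c(0, upper), maximum = TRUE)
  list(tmax_pred = opt$maximum, cmax_pred = opt$objective)
}

#' Rank compartmental model variants by small-sample AIC
#'
#' Fits each candidate variant to the same profile and ranks them by AICc
#' (computed from the residual sum of squares and the fitted parameter
#' count). Ties in fit quality are resolved in favour of the simpler model
#' by the AICc penalty itself.
#'
#' @inheritParams fit_compartment_model
#' @param variants Character vector of candidate variants (at least 2).
#' @return A tibble ranked by AICc with columns `variant`, `n_par`, `sse`,
#'   `aicc`, `delta_aicc`, `converged`, and a `fit` list-column.
#' @export
select_model <- function(times, conc, dose,
                         variants = c("oral_first_order", "oral_one_compartment"),
                         weighting = "uniform", censored = NULL) {
  if (length(variants) < 2) {
    stop_input("Provide at least 2 candidate variants.")
  }
  fits <- purrr::map(variants, function(v) {
    tryCatch(
      fit_compartment_model(times, conc, dose, variant = v,
                            weighting = weighting, censored = censored),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop_input("All candidate fits failed.")
  }
  tbl <- purrr::map_dfr(which(ok), function(i) {
    f <- fits[[i]]
    tibble::tibble(variant = f$variant, n_par = f$n_par, sse = f$sse,
                   aicc = f$aicc, converged = f$converged)
  })
  tbl$fit <- fits[ok]
  tbl <- dplyr::arrange(tbl, .data$aicc)
  tbl$delta_aicc <- tbl$aicc - tbl$aicc[1]
  dplyr::relocate(tbl, "fit", .after = dplyr::last_col())
}

#' Fit a compartmental model to every subject of a study
#'
#' Maps [fit_compartment_model()] over the subjects of a long-format study
#' table, returning the per-subject compartmental parameter estimates in the
#' mean-plus-minus-SD-ready wide form.
#'
#' @inheritParams nca
#' @inheritParams fit_compartment_model
#' @return A tibble with one row per (brand,) subject: all [tidy.pk_fit()]
#'   quantities in wide form plus a `fit` list-column.
#' @export
fit_pk_study <- function(data, dose = NULL, variant = "oral_first_order",
                         weighting = "uniform") {
  check_cols(data, c("subject_id", "time_hr", "conc_mg_L"))
  if (!"censored" %in% names(data)) data$censored <- FALSE
  if (!"dose_mg" %in% names(data)) {
    if (is.null(dose)) stop_input("Provide `dose` or a `dose_mg` column.")
    data$dose_mg <- dose
  }
  keys <- intersect(c("brand", "subject_id"), names(data))
  nested <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$time_hr, .by_group = TRUE) |>
    tidyr::nest()
  nested$fit <- purrr::map(nested$data, function(d) {
    fit_compartment_model(d$time_hr, d$conc_mg_L, dose = d$dose_mg[1],
                          variant = variant, weighting = weighting,
                          censored = d$censored)
  })
  wide <- purrr::map_dfr(nested$fit, fit_row)
  dplyr::bind_cols(dplyr::ungroup(nested)[keys], wide,
                   tibble::tibble(fit = nested$fit))
}

# One-row wide summary of a pk_fit.
fit_row <- function(f) {
  tibble::tibble(
    A = f$macro$A, B = f$macro$B,
    alpha = f$macro$alpha, beta = f$macro$beta, ka = f$ka,
    k10 = f$micro$k10, k12 = f$micro$k12, k21 = f$micro$k21,
    v1_f = f$v1_f, v2_f = f$v2_f, cl_f = f$cl_f,
    alpha_hl = f$alpha_hl, beta_hl = f$beta_hl,
    auc_model = f$auc_model,
    tmax_pred = f$tmax_pred, cmax_pred = f$cmax_pred,
    sse = f$sse, converged = f$converged
  )
}

#' @describeIn fit_compartment_model Tidy per-parameter view of a fit.
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @export
tidy.pk_fit <- function(x, ...) {
  row <- fit_row(x)
  vals <- row[!(names(row) %in% c("sse", "converged"))]
  tibble::tibble(
    term = names(vals),
    estimate = as.numeric(vals[1, ])
  )
}

#' @describeIn fit_compartment_model One-row fit summary.
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, n_obs = x$n_obs, n_par = x$n_par,
    sse = x$sse, init_sse = x$init_sse, aicc = x$aicc,
    converged = x$converged
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Compartmental fit (%s, %s weighting)\n", x$variant, x$weighting))
  cat(sprintf("  %d points, SSE %.4g, AICc %.4g, converged: %s\n",
              x$n_obs, x$sse, x$aicc, x$converged))
  cat(sprintf("  alpha %.4g, beta %.4g /hr (half-lives %.3g, %.3g hr)\n",
              x$macro$alpha, x$macro$beta, x$alpha_hl, x$beta_hl))
  cat(sprintf("  Cl/F %.4g L/hr, V1/F %.4g L, model AUC %.4g hr*mg/L\n",
              x$cl_f, x$v1_f, x$auc_model))
  invisible(x)
}
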