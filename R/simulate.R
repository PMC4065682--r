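# Synthetic study generation: Weibull dissolution curves and seeded
# multi-subject oral two-compartment plasma studies with known ground truth.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a Weibull-type dissolution curve
#'
#' Generates percent-dissolved values from the cumulative Weibull release
#' model \eqn{f(t) = f_{max}(1 - e^{-(t/t_d)^b})}, optionally with additive
#' Gaussian measurement noise, clipped to the physically meaningful 0--110\%
#' range. `td` is the time at which 63.2\% of `f_max` has been released and
#' `b` controls the curve shape (b = 1 is first-order release).
#'
#' @param times Sampling times in minutes, strictly increasing, nonnegative.
#' @param f_max Asymptotic release in percent of label (0--110].
#' @param td Time scale parameter in minutes, `> 0`.
#' @param b Dimensionless shape parameter, `> 0`.
#' @param noise_sd Standard deviation of additive measurement noise in
#'   percent-of-label units; `0` returns the exact model curve.
#' @param seed Optional integer seed; the same seed reproduces the same curve
#'   without disturbing the caller's RNG stream.
#' @return A tibble with columns `time_min` and `pct_dissolved`.
#' @examples
#' weibull_release(c(5, 10, 30), f_max = 100, td = 5, b = 1)
#' @export
weibull_release <- function(times, f_max, td, b, noise_sd = 0, seed = NULL) {
  check_times(times, "times")
  check_numeric(f_max, "f_max", positive = TRUE)
  check_numeric(td, "td", positive = TRUE)
  check_numeric(b, "b", positive = TRUE)
  check_numeric(noise_sd, "noise_sd", nonneg = TRUE)
  if (f_max > 110) {
    stop_input("`f_max` must not exceed 110% of label.")
  }
  mean_curve <- f_max * (1 - exp(-(times / td)^b))
  values <- with_seed(seed, {
    if (noise_sd > 0) {
      mean_curve + rnorm(length(times), 0, noise_sd)
    } else {
      mean_curve
    }
  })
  tibble::tibble(
    time_min = as.numeric(times),
    pct_dissolved = pmin(pmax(values, 0), 110)
  )
}

#' Simulate dissolution curves for several products
#'
#' Vectorised front end to [weibull_release()]: one Weibull parameter set per
#' product, all sampled on a common time grid, returned in the long format
#' used throughout the package.
#'
#' @param products A data frame with one row per product and columns
#'   `product_id`, `f_max`, `td`, `b`, and optionally `noise_sd` (default 0).
#' @param times Shared sampling grid in minutes.
#' @param seed Optional integer seed governing all noise draws.
#' @return A tibble with columns `product_id`, `time_min`, `pct_dissolved`.
#' @export
simulate_dissolution <- function(products, times, seed = NULL) {
  check_cols(products, c("product_id", "f_max", "td", "b"), "products")
  if (!"noise_sd" %in% names(products)) {
    products$noise_sd <- 0
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(products)), function(i) {
      p <- products[i, ]
      curve <- weibull_release(times, p$f_max, p$td, p$b, p$noise_sd)
      tibble::tibble(product_id = p$product_id, curve)
    })
  })
}

#' Ground-truth parameters for an oral two-compartment study
#'
#' Bundles the generative parameters of the simulator: first-order absorption
#' (`ka`) into a central compartment (apparent volume `v1_f`) that exchanges
#' with a peripheral compartment (`k12`, `k21`) and eliminates from the
#' central compartment (`k10`). Between-subject variability is log-normal on
#' `ka`, `v1_f`, and `k10`; residual (assay) error is proportional;
#' concentrations below `loq` are reported as censored.
#'
#' @param ka First-order absorption rate constant, 1/hr.
#' @param v1_f Apparent central volume of distribution V1/F, litres.
#' @param k10 Elimination rate constant from the central compartment, 1/hr.
#' @param k12,k21 Central-to-peripheral and peripheral-to-central
#'   distribution rate constants, 1/hr.
#' @param dose Administered dose, mg.
#' @param between_subject_cv Coefficient of variation of the log-normal
#'   between-subject distribution of `ka`, `v1_f`, `k10` (fraction, `< 1`).
#' @param residual_cv Proportional residual error CV (fraction, `< 1`).
#' @param loq Lower limit of quantification, mg/L.
#' @return An object of class `pk_truth`.
#' @seealso [rabbit_cipro_truth()] for the packaged preset,
#'   [simulate_pk_study()] to draw a study from it.
#' @export
pk_truth <- function(ka, v1_f, k10, k12, k21, dose = 500,
                     between_subject_cv = 0, residual_cv = 0, loq = 0) {
  for (nm in c("ka", "v1_f", "k10", "k12", "k21", "dose")) {
    check_numeric(get(nm), nm, positive = TRUE)
  }
  for (nm in c("between_subject_cv", "residual_cv")) {
    v <- get(nm)
    check_numeric(v, nm, nonneg = TRUE)
    if (v >= 1) stop_input(sprintf("`%s` must be below 1.", nm))
  }
  check_numeric(loq, "loq", nonneg = TRUE)
  mac <- macro_constants(k10, k12, k21)
  structure(
    list(
      ka = ka, v1_f = v1_f, k10 = k10, k12 = k12, k21 = k21,
      dose = dose, between_subject_cv = between_subject_cv,
      residual_cv = residual_cv, loq = loq,
      alpha = mac$alpha, beta = mac$beta
    ),
    class = "pk_truth"
  )
}

#' @export
print.pk_truth <- function(x, ...) {
  cat("Oral two-compartment ground truth\n")
  cat(sprintf(
    "  ka %.3g /hr, V1/F %.3g L, k10 %.3g, k12 %.3g, k21 %.3g /hr\n",
    x$ka, x$v1_f, x$k10, x$k12, x$k21
  ))
  cat(sprintf(
    "  alpha %.4g /hr, beta %.4g /hr, Cl/F %.3g L/hr, dose %.4g mg\n",
    x$alpha, x$beta, x$k10 * x$v1_f, x$dose
  ))
  cat(sprintf(
    "  BSV CV %.2g, residual CV %.2g, LOQ %.3g mg/L\n",
    x$between_subject_cv, x$residual_cv, x$loq
  ))
  invisible(x)
}

#' Packaged ground truth emulating a rabbit ciprofloxacin study
#'
#' A single 500 mg oral dose in rabbits sampled pre-dose and at 0.25, 0.5, 1,
#' 1.5, 2, 4, 8, 12 and 24 hr. The kinetic parameters give a pronounced
#' distribution phase (alpha = 1.80/hr, beta = 0.159/hr, terminal half-life
#' 4.3 hr), Tmax near 0.6 hr, Cmax near 11 mg/L, and apparent clearance near
#' 8.9 L/hr, all inside the ranges reported for ciprofloxacin in rabbits.
#' Assay LOQ is 0.05 mg/L.
#'
#' @param between_subject_cv,residual_cv Override the default variability
#'   (10\% between subjects, 5\% residual).
#' @return A `pk_truth` object.
#' @export
rabbit_cipro_truth <- function(between_subject_cv = 0.10, residual_cv = 0.05) {
  pk_truth(
    ka = 3.0, v1_f = 25.5, k10 = 0.35, k12 = 0.79, k21 = 0.82,
    dose = 500, between_subject_cv = between_subject_cv,
    residual_cv = residual_cv, loq = 0.05
  )
}

#' Default rabbit sampling schedule (hours)
#'
#' Pre-dose plus 0.25, 0.5, 1, 1.5, 2, 4, 8, 12, 24 hr.
#' @return Numeric vector of sampling times in hours.
#' @export
rabbit_sampling_times <- function() {
  c(0, 0.25, 0.5, 1, 1.5, 2, 4, 8, 12, 24)
}

#' Macro rate constants of a two-compartment model
#'
#' Converts the micro constants to the hybrid (macro) rate constants
#' \eqn{\alpha > \beta}, the roots of
#' \eqn{s^2 - (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0}.
#'
#' @inheritParams pk_truth
#' @return A list with elements `alpha` and `beta` (1/hr).
#' @export
macro_constants <- function(k10, k12, k21) {
  check_numeric(k10, "k10", positive = TRUE)
  check_numeric(k12, "k12", positive = TRUE)
  check_numeric(k21, "k21", positive = TRUE)
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Oral two-compartment concentration-time curve
#'
#' Evaluates the triexponential solution of the two-compartment open model
#' with first-order absorption:
#' \deqn{C(t) = \frac{k_a D}{V_1}\left[
#'   \frac{(k_{21}-\alpha)e^{-\alpha t}}{(k_a-\alpha)(\beta-\alpha)} +
#'   \frac{(k_{21}-\beta)e^{-\beta t}}{(k_a-\beta)(\alpha-\beta)} +
#'   \frac{(k_{21}-k_a)e^{-k_a t}}{(\alpha-k_a)(\beta-k_a)}\right]}
#' with \eqn{\alpha,\beta} from [macro_constants()]. `C(0) = 0` and the curve
#' is nonnegative for all valid parameter sets.
#'
#' @param times Times in hours, `>= 0` (vectorised).
#' @inheritParams pk_truth
#' @return Numeric vector of concentrations in mg/L.
#' @examples
#' tr <- rabbit_cipro_truth()
#' conc_two_compartment_oral(c(0, 0.5, 2, 24), tr$ka, tr$v1_f,
#'                           tr$k10, tr$k12, tr$k21, tr$dose)
#' @export
conc_two_compartment_oral <- function(times, ka, v1_f, k10, k12, k21, dose) {
  check_numeric(times, "times", nonneg = TRUE)
  mac <- macro_constants(k10, k12, k21)
  tol <- 1e-6
  if (abs(ka - mac$alpha) < tol * mac$alpha ||
      abs(ka - mac$beta) < tol * mac$beta) {
    stop_input(
      "`ka` coincides with a disposition rate constant; the triexponential form is degenerate.",
      class = "pkbioeq_degenerate_model"
    )
  }
  conc2_core(times, ka, v1_f, k10, k12, k21, dose)
}

# Unchecked core used by both the public function and the fitter. Nudges ka
# away from exact coincidence with alpha/beta so optimizer excursions cannot
# produce NaN.
conc2_core <- function(times, ka, v1_f, k10, k12, k21, dose) {
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  a <- (s + disc) / 2
  b <- (s - disc) / 2
  if (abs(ka - a) < 1e-9 * a) ka <- ka * (1 + 1e-7)
  if (abs(ka - b) < 1e-9 * b) ka <- ka * (1 + 1e-7)
  m <- ka * dose / v1_f
  out <- m * ((k21 - a) / ((ka - a) * (b - a)) * exp(-a * times) +
              (k21 - b) / ((ka - b) * (a - b)) * exp(-b * times) +
              (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * times))
  pmax(out, 0)
}

# One-compartment oral (Bateman) curve, used by the fitter and for model
# selection benchmarks.
conc1_core <- function(times, ka, v_f, ke, dose) {
  if (abs(ka - ke) < 1e-9 * ke) ka <- ka * (1 + 1e-7)
  pmax((ka * dose / (v_f * (ka - ke))) * (exp(-ke * times) - exp(-ka * times)), 0)
}

#' Simulate a multi-subject plasma concentration study
#'
#' Draws one concentration-time profile per subject from a [pk_truth()]
#' generative model. Per-subject parameters `ka`, `v1_f`, `k10` are
#' log-normally perturbed with CV `between_subject_cv` (`k12`, `k21` are
#' shared), observed concentrations carry proportional log-normal residual
#' error with CV `residual_cv`, and post-dose values below `loq` are reported
#' as censored (`conc_mg_L = NA`, `censored = TRUE`). The pre-dose sample is
#' an exact zero.
#'
#' @param truth A `pk_truth` object.
#' @param n_subjects Number of subjects.
#' @param times Sampling times in hours (include 0 for the pre-dose sample).
#' @param seed Optional integer seed; identical inputs and seed give
#'   bit-identical output.
#' @param brand Optional brand label added as a `brand` column.
#' @param rel_f Relative bioavailable fraction multiplier (1 = nominal);
#'   scales all concentrations, emulating a formulation releasing a
#'   different fraction of the dose.
#' @return A tibble with columns (`brand`,) `subject_id`, `time_hr`,
#'   `conc_mg_L`, `censored`, `dose_mg`.
#' @examples
#' simulate_pk_study(rabbit_cipro_truth(), n_subjects = 2, seed = 1)
#' @export
simulate_pk_study <- function(truth, n_subjects = 6,
                              times = rabbit_sampling_times(),
                              seed = NULL, brand = NULL, rel_f = 1) {
  stopifnot(inherits(truth, "pk_truth"))
  check_times(times, "times")
  if (n_subjects < 1) stop_input("`n_subjects` must be at least 1.")
  check_numeric(rel_f, "rel_f", positive = TRUE)
  with_seed(seed, simulate_pk_study_impl(truth, n_subjects, times, brand, rel_f))
}

simulate_pk_study_impl <- function(truth, n_subjects, times, brand, rel_f) {
  sdlog_bsv <- sqrt(log(1 + truth$between_subject_cv^2))
  sdlog_res <- sqrt(log(1 + truth$residual_cv^2))
  out <- purrr::map_dfr(seq_len(n_subjects), function(i) {
    eta <- if (sdlog_bsv > 0) rnorm(3, 0, sdlog_bsv) else c(0, 0, 0)
    ka_i <- truth$ka * exp(eta[1])
    v1_i <- truth$v1_f * exp(eta[2])
    k10_i <- truth$k10 * exp(eta[3])
    c_true <- rel_f * conc2_core(
      times, ka_i, v1_i, k10_i, truth$k12, truth$k21, truth$dose
    )
    eps <- if (sdlog_res > 0) rnorm(length(times), 0, sdlog_res) else rep(0, length(times))
    c_obs <- c_true * exp(eps)
    c_obs[times == 0] <- 0
    censored <- times > 0 & c_obs < truth$loq
    c_obs[censored] <- NA_real_
    tibble::tibble(
      subject_id = sprintf("S%02d", i),
      time_hr = as.numeric(times),
      conc_mg_L = c_obs,
      censored = censored,
      dose_mg = truth$dose
    )
  })
  if (!is.null(brand)) {
    out <- tibble::add_column(out, brand = brand, .before = 1)
  }
  out
}

#' Simulate a multi-brand bioequivalence study
#'
#' One [simulate_pk_study()] draw per brand under a shared ground truth,
#' optionally with brand-specific relative bioavailable fractions, emulating
#' a parallel-group formulation comparison (e.g. six brands, six rabbits
#' each).
#'
#' @inheritParams simulate_pk_study
#' @param brands Character vector of brand labels.
#' @param rel_f Either a single multiplier applied to all brands or a named
#'   vector giving one per brand.
#' @return A tibble in the same shape as [simulate_pk_study()] with a leading
#'   `brand` column.
#' @export
simulate_bioeq_study <- function(truth, brands = c("A", "B", "C", "D", "E", "F"),
                                 n_subjects = 6,
                                 times = rabbit_sampling_times(),
                                 seed = NULL, rel_f = 1) {
  if (length(rel_f) == 1 && is.null(names(rel_f))) {
    rel_f <- setNames(rep(rel_f, length(brands)), brands)
  }
  if (!all(brands %in% names(rel_f))) {
    stop_input("`rel_f` must be named for every brand when not scalar.")
  }
  with_seed(seed, {
    purrr::map_dfr(brands, function(b) {
      simulate_pk_study_impl(truth, n_subjects, times, brand = b,
                             rel_f = rel_f[[b]])
    })
  })
}
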