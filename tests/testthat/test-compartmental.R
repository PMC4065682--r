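test_that("curve stripping recovers an exact biexponential within 5%", {
  tt <- c(0.25, 0.5, 1, 1.5, 2, 4, 8, 12, 24)
  cc <- 12 * exp(-2 * tt) + 11 * exp(-0.24 * tt)
  s <- strip_residuals(tt, cc)
  expect_false(s$fallback)
  expect_equal(s$A, 12, tolerance = 0.05)
  expect_equal(s$B, 11, tolerance = 0.05)
  expect_equal(s$alpha, 2, tolerance = 0.05)
  expect_equal(s$beta, 0.24, tolerance = 0.05)
})

test_that("stripping falls back on monoexponential data and always orders alpha > beta", {
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  mono <- 10 * exp(-0.3 * tt)
  s <- strip_residuals(tt, mono)
  expect_true(s$fallback)
  expect_gt(s$alpha, s$beta)
  set.seed(12)
  for (i in 1:10) {
    cc <- runif(1, 5, 20) * exp(-runif(1, 1, 3) * tt) +
      runif(1, 5, 15) * exp(-runif(1, 0.1, 0.4) * tt) *
        exp(rnorm(length(tt), 0, 0.05))
    s <- strip_residuals(tt, cc)
    expect_gt(s$alpha, s$beta)
  }
})

test_that("micro constants follow the standard identities and limits", {
  m <- derive_microconstants(A = 3, B = 3, alpha = 1.2, beta = 0.2)
  expect_equal(m$k21, (1.2 + 0.2) / 2)
  m0 <- derive_microconstants(A = 5, B = 0, alpha = 1.2, beta = 0.2)
  expect_equal(m0$k21, 0.2)
  expect_equal(m0$k10, 1.2)
  expect_equal(m0$k12, 0)
  mac <- macro_constants(k10 = 0.5, k12 = 0.3, k21 = 0.2)
  expect_equal(mac$alpha, (1 + sqrt(1 - 0.4)) / 2, tolerance = 1e-12)
  expect_equal(mac$beta, (1 - sqrt(1 - 0.4)) / 2, tolerance = 1e-12)
  expect_error(derive_microconstants(1, 1, alpha = 0.2, beta = 1.2),
               "exceed")
})

test_that("micro -> macro -> micro is the identity to 1e-9 over random draws", {
  set.seed(2024)
  worst <- 0
  for (i in 1:200) {
    k10 <- runif(1, 0.02, 4)
    k12 <- runif(1, 0.02, 4)
    k21 <- runif(1, 0.02, 4)
    mac <- macro_constants(k10, k12, k21)
    # iv-bolus intercept shares implied by the micro constants
    a_share <- (mac$alpha - k21) / (mac$alpha - mac$beta)
    A <- a_share
    B <- 1 - a_share
    m <- derive_microconstants(A, B, mac$alpha, mac$beta)
    worst <- max(worst, abs(m$k10 - k10), abs(m$k12 - k12),
                 abs(m$k21 - k21))
  }
  expect_lt(worst, 1e-9)
})

test_that("noise-free oral fit recovers the generating parameters", {
  p <- noise_free_profile()
  fit <- fit_compartment_model(p$times, p$conc, dose = p$dose)
  tr <- p$truth
  expect_true(fit$converged)
  expect_equal(fit$macro$alpha, tr$alpha, tolerance = 0.01)
  expect_equal(fit$macro$beta, tr$beta, tolerance = 0.01)
  expect_equal(fit$ka, tr$ka, tolerance = 0.05)
  expect_equal(fit$cl_f, tr$k10 * tr$v1_f, tolerance = 0.01)
  # macro/micro round-trip identities hold on the fitted object
  expect_equal(fit$macro$alpha * fit$macro$beta,
               fit$micro$k10 * fit$micro$k21, tolerance = 1e-9)
  expect_equal(fit$macro$alpha + fit$macro$beta,
               fit$micro$k10 + fit$micro$k12 + fit$micro$k21,
               tolerance = 1e-9)
  expect_equal(fit$alpha_hl, log(2) / fit$macro$alpha, tolerance = 1e-12)
  expect_equal(fit$beta_hl, log(2) / fit$macro$beta, tolerance = 1e-12)
})

test_that("iv biexponential fit of one-compartment truth collapses toward k12 = 0", {
  tt <- c(0.25, 0.5, 1, 1.5, 2, 4, 8, 12, 24)
  cc <- 12 * exp(-0.3 * tt)
  fit <- fit_compartment_model(tt, cc, dose = 500,
                               variant = "iv_biexponential")
  expect_lt(fit$micro$k12, 0.01)
  expect_equal(fit$micro$k10, 0.3, tolerance = 0.02)
})

test_that("fitted SSE never exceeds the stripping-initialization SSE", {
  set.seed(31)
  tr <- rabbit_cipro_truth(0, 0.08)
  st <- simulate_pk_study(tr, n_subjects = 5, seed = 31)
  for (s in unique(st$subject_id)) {
    d <- st[st$subject_id == s, ]
    fit <- fit_compartment_model(d$time_hr, d$conc_mg_L, dose = 500,
                                 censored = d$censored)
    expect_lte(fit$sse, fit$init_sse + 1e-12)
  }
})

test_that("predicted peak matches the variant geometry", {
  p <- noise_free_profile()
  fit <- fit_compartment_model(p$times, p$conc, dose = p$dose)
  obs_peak <- max(p$conc)
  expect_equal(fit$cmax_pred, obs_peak, tolerance = 0.05)
  expect_lt(fit$cmax_pred, p$dose / fit$v1_f)
  # iv variant peaks at t = 0 with height A + B
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  cc <- 12 * exp(-2 * tt) + 11 * exp(-0.24 * tt)
  ivfit <- fit_compartment_model(tt, cc, dose = 500,
                                 variant = "iv_biexponential")
  pk <- predict_tmax_cmax(ivfit)
  expect_equal(pk$tmax_pred, 0)
  expect_equal(pk$cmax_pred, ivfit$macro$A + ivfit$macro$B)
  # very fast absorption pushes the oral peak toward t = 0
  tr <- p$truth
  cfast <- conc_two_compartment_oral(p$times, 1000 * tr$alpha, tr$v1_f,
                                     tr$k10, tr$k12, tr$k21, tr$dose)
  ffast <- fit_compartment_model(p$times, cfast, dose = tr$dose)
  expect_lt(ffast$tmax_pred, 0.05)
})

test_that("model selection identifies the generating compartment count", {
  tt <- rabbit_sampling_times()
  tr <- truth_noise_free()
  set.seed(77)
  # two-compartment truth, low noise
  c2 <- conc_two_compartment_oral(tt, tr$ka, tr$v1_f, tr$k10, tr$k12,
                                  tr$k21, tr$dose) *
    exp(rnorm(length(tt), 0, 0.03))
  c2[1] <- 0
  sel2 <- select_model(tt, c2, tr$dose)
  expect_identical(sel2$variant[1], "oral_first_order")
  # one-compartment truth
  c1 <- (3 * 500 / (30 * (3 - 0.25))) * (exp(-0.25 * tt) - exp(-3 * tt)) *
    exp(rnorm(length(tt), 0, 0.03))
  c1[1] <- 0
  sel1 <- select_model(tt, c1, 500)
  expect_identical(sel1$variant[1], "oral_one_compartment")
  expect_equal(sel1$delta_aicc[1], 0)
})

test_that("study-level fitting returns one row per subject with tidy accessors", {
  st <- simulate_bioeq_study(rabbit_cipro_truth(0, 0.05),
                             brands = c("A", "F"), n_subjects = 2, seed = 4)
  fits <- fit_pk_study(st)
  expect_identical(nrow(fits), 4L)
  expect_true(all(c("brand", "subject_id", "alpha", "beta", "cl_f",
                    "fit") %in% names(fits)))
  td <- tidy(fits$fit[[1]])
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fits$fit[[1]])
  expect_identical(gl$variant, "oral_first_order")
  expect_true(gl$converged)
})
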