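test_that("trapezoidal areas match simple geometry and a loop oracle", {
  expect_equal(auc_trapezoid(c(0, 1), c(10, 10)), 10)
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 10, 0)), 10)
  expect_equal(aumc_trapezoid(c(0, 1, 2), c(0, 10, 0)), 10)
  # constant concentration c over [0, T]: AUMC = c T^2 / 2
  expect_equal(aumc_trapezoid(c(0, 2, 5, 8), rep(3, 4)), 3 * 8^2 / 2)
  set.seed(7)
  for (i in 1:25) {
    tt <- sort(runif(9, 0, 24))
    cc <- runif(9, 0, 12)
    auc_loop <- 0
    aumc_loop <- 0
    for (j in 2:9) {
      dt <- tt[j] - tt[j - 1]
      auc_loop <- auc_loop + dt * (cc[j] + cc[j - 1]) / 2
      aumc_loop <- aumc_loop + dt * (tt[j] * cc[j] + tt[j - 1] * cc[j - 1]) / 2
    }
    expect_equal(auc_trapezoid(tt, cc), auc_loop, tolerance = 1e-12)
    expect_equal(aumc_trapezoid(tt, cc), aumc_loop, tolerance = 1e-12)
  }
  expect_error(auc_trapezoid(c(1), c(1)), "2 points")
})

test_that("log-down trapezoid is exact on exponential decay segments", {
  tt <- c(0, 2, 4, 8)
  cc <- 10 * exp(-0.3 * tt)
  exact <- 10 / 0.3 * (1 - exp(-0.3 * 8))
  expect_equal(auc_trapezoid(tt, cc, method = "linear-log"), exact,
               tolerance = 1e-12)
  expect_gt(auc_trapezoid(tt, cc), exact) # linear rule overestimates decay
})

test_that("terminal slope is exact on a monoexponential and close on a biexponential tail", {
  tt <- c(1, 4, 8, 12, 24)
  cc <- 10 * exp(-0.2 * tt)
  lam <- estimate_lambda_z(tt, cc)
  expect_equal(lam$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(lam$hl, log(2) / 0.2, tolerance = 1e-10)
  expect_equal(lam$r2, 1)
  # biexponential sampled late: recovered slope within 5% of beta = 0.16
  tt2 <- c(0.5, 1, 2, 4, 8, 12, 24)
  cc2 <- 12 * exp(-2 * tt2) + 11 * exp(-0.16 * tt2)
  lam2 <- estimate_lambda_z(tt2, cc2)
  expect_equal(lam2$lambda_z, 0.16, tolerance = 0.05)
})

test_that("terminal slope is flagged not-estimable when unsupported", {
  # fewer than 3 points after the peak
  res <- estimate_lambda_z(c(0, 1, 2, 3), c(0, 10, 8, 6))
  expect_identical(res$n_points, 0L)
  expect_true(is.na(res$lambda_z))
  # rising tail -> nonpositive slope
  res2 <- estimate_lambda_z(c(0, 1, 2, 4, 8), c(0, 5, 6, 7, 8))
  expect_true(is.na(res2$lambda_z))
})

test_that("full NCA obeys scale equivariance and the extrapolation inequality", {
  p <- noise_free_profile()
  r1 <- nca_profile(p$times, p$conc, dose = p$dose)
  r2 <- nca_profile(p$times, 2 * p$conc, dose = p$dose)
  for (col in c("auc_last", "auc_inf", "aumc_last", "cmax")) {
    expect_equal(r2[[col]], 2 * r1[[col]], tolerance = 1e-10)
  }
  for (col in c("mrt_last", "tmax", "lambda_z", "hl_lambda_z")) {
    expect_equal(r2[[col]], r1[[col]], tolerance = 1e-10)
  }
  expect_equal(r2$cl_f, r1$cl_f / 2, tolerance = 1e-10)
  expect_equal(r2$vz_f, r1$vz_f / 2, tolerance = 1e-10)
  expect_gt(r1$auc_inf, r1$auc_last)
  expect_equal(r1$css_24h, r1$auc_inf / 24, tolerance = 1e-9)
  expect_equal(r1$kel_eq2, 1 / r1$mrt_last, tolerance = 1e-12)
  expect_equal(r1$hl_eq2, 0.693 * r1$mrt_last, tolerance = 1e-12)
})

test_that("a leading (0, 0) sample never changes auc_last; ties go to the earliest tmax", {
  tt <- c(0.5, 1, 2, 4, 8, 12, 24)
  cc <- 12 * exp(-2 * tt) + 11 * exp(-0.16 * tt)
  with0 <- nca_profile(c(0, tt), c(0, cc), dose = 500)
  without <- nca_profile(tt, cc, dose = 500)
  expect_equal(with0$auc_last, without$auc_last, tolerance = 1e-12)
  tie <- nca_profile(c(0, 1, 2, 3, 5, 8, 12), c(0, 9, 9, 7, 4, 2, 1),
                     dose = 500)
  expect_equal(tie$tmax, 1)
})

test_that("censored samples are excluded from NCA", {
  p <- noise_free_profile()
  cens <- c(rep(FALSE, 9), TRUE) # censor the 24-hr sample
  conc_na <- p$conc
  conc_na[10] <- NA
  r_flag <- nca_profile(p$times, conc_na, dose = p$dose, censored = cens)
  r_drop <- nca_profile(p$times[1:9], p$conc[1:9], dose = p$dose)
  expect_equal(r_flag$auc_last, r_drop$auc_last, tolerance = 1e-12)
  expect_error(
    nca_profile(c(0, 1, 2), c(0, 1, 2), dose = 500,
                censored = c(FALSE, TRUE, TRUE)),
    class = "pkbioeq_insufficient_data"
  )
})

test_that("tabular NCA preserves brand/subject structure and summarises by brand", {
  st <- simulate_bioeq_study(rabbit_cipro_truth(), brands = c("A", "F"),
                             n_subjects = 3, seed = 8)
  res <- nca(st)
  expect_identical(nrow(res), 6L)
  expect_setequal(unique(res$brand), c("A", "F"))
  smry <- nca_summary(res)
  expect_true(all(c("brand", "parameter", "mean", "sd", "n") %in% names(smry)))
  expect_true("hl_of_mean_lambda_z" %in% smry$parameter)
  a_cmax <- smry[smry$brand == "A" & smry$parameter == "cmax", ]
  expect_equal(a_cmax$mean, mean(res$cmax[res$brand == "A"]))
  expect_identical(a_cmax$n, 3L)
})
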