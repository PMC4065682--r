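test_that("f1 matches hand evaluation and degenerate cases", {
  expect_identical(f1_factor(c(50, 80, 90), c(50, 80, 90)), 0)
  # sum|diff| = 22, sum ref = 220
  expect_equal(f1_factor(c(50, 80, 90), c(45, 72, 81)), 10.0)
  expect_error(f1_factor(c(0, 0), c(0, 0)), "undefined")
  expect_error(f1_factor(c(1, 2), c(1, 2, 3)), "same number")
})

test_that("f2 reproduces its closed forms", {
  p <- c(30, 55, 75, 88, 95)
  expect_equal(f2_factor(p, p), 100)
  # constant offset d at every point: f2 = 50*log10(100/sqrt(1 + d^2))
  ref <- c(40, 60, 75, 85, 92)
  expect_equal(f2_factor(ref, ref - 9), 50 * log10(100 / sqrt(82)),
               tolerance = 1e-12)
  expect_equal(f2_factor(ref, ref - 10), 50 * log10(100 / sqrt(101)),
               tolerance = 1e-12)
  expect_gte(f2_factor(ref, ref - 9), 50)
  expect_lt(f2_factor(ref, ref - 10), 50)
})

test_that("vectorized f1/f2 agree with a loop-based evaluation of the formulas", {
  set.seed(101)
  for (i in 1:50) {
    pp <- random_profile_pair()
    n <- length(pp$ref)
    num <- 0
    den <- 0
    ss <- 0
    for (j in seq_len(n)) {
      num <- num + abs(pp$ref[j] - pp$test[j])
      den <- den + pp$ref[j]
      ss <- ss + (pp$ref[j] - pp$test[j])^2
    }
    expect_equal(f1_factor(pp$ref, pp$test), 100 * num / den,
                 tolerance = 1e-12)
    expect_equal(f2_factor(pp$ref, pp$test),
                 50 * log10((1 + ss / n)^-0.5 * 100),
                 tolerance = 1e-12)
  }
})

test_that("f2 is symmetric, f1 is not, and f2 decreases with offset", {
  set.seed(202)
  asymmetric <- FALSE
  for (i in 1:20) {
    pp <- random_profile_pair()
    expect_equal(f2_factor(pp$ref, pp$test), f2_factor(pp$test, pp$ref),
                 tolerance = 1e-12)
    if (abs(f1_factor(pp$ref, pp$test) - f1_factor(pp$test, pp$ref)) > 1e-9) {
      asymmetric <- TRUE
    }
  }
  expect_true(asymmetric)
  ref <- c(40, 55, 70, 85, 95)
  f2s <- vapply(0:50, function(d) f2_factor(ref, ref - d), numeric(1))
  expect_true(all(diff(f2s) < 0))
})

test_that("85% truncation keeps at most one plateau point", {
  ref <- c(40, 70, 90, 95, 98)
  tst <- c(38, 68, 88, 94, 97)
  # full profile vs truncated at the first point where both exceed 85
  expect_equal(f2_factor(ref, tst, truncate_after_85 = TRUE),
               f2_factor(ref[1:3], tst[1:3]))
  cmp <- compare_dissolution(
    dissolution_tbl(c(5, 10, 15, 20, 30), R = ref, T = tst),
    reference = "R", truncate_after_85 = TRUE
  )
  expect_identical(cmp$n_points_used, 3L)
})

test_that("compare_dissolution applies the joint f1/f2 acceptance window", {
  times <- c(5, 10, 15, 20, 30)
  ref <- c(40, 60, 75, 85, 92)
  cmp <- compare_dissolution(
    dissolution_tbl(times, R = ref, S = ref, T = ref - 10),
    reference = "R"
  )
  same <- cmp[cmp$product_id == "S", ]
  offs <- cmp[cmp$product_id == "T", ]
  expect_equal(same$f1, 0)
  expect_equal(same$f2, 100)
  expect_true(same$similar)
  expect_false(offs$similar) # f2 just below 50
  bad <- dissolution_tbl(times, R = ref)
  bad <- rbind(bad, tibble::tibble(product_id = "X", time_min = times + 1,
                                   pct_dissolved = ref))
  expect_error(compare_dissolution(bad, reference = "R"), "time grid")
})

test_that("release classification follows the 15/30-minute rules with interpolation", {
  times <- c(5, 10, 15, 20, 30, 45)
  tbl <- dissolution_tbl(
    times,
    VR = c(50, 75, 90, 95, 98, 99),   # >85% at 15 min
    RA = c(30, 55, 70, 80, 86, 95),   # 85% reached by 30 min only
    NC = c(20, 35, 50, 62, 75, 85)    # below 80% at 30 min
  )
  cls <- classify_release(tbl)
  expect_equal(
    as.character(cls$category[match(c("VR", "RA", "NC"), cls$product_id)]),
    c("very_rapid", "rapid", "noncompliant")
  )
  # value at 15 min interpolated when not sampled there
  tbl2 <- dissolution_tbl(c(10, 20, 30), P = c(80, 94, 97))
  cls2 <- classify_release(tbl2)
  expect_equal(cls2$pct_15min, 87)
  expect_equal(as.character(cls2$category), "very_rapid")
  expect_error(classify_release(dissolution_tbl(c(5, 15), P = c(50, 80))),
               "bracket")
})

test_that("Weibull release matches its closed form and respects the asymptote", {
  # f_max (1 - exp(-(t/td)^b)) at t = td with b = 1 is 63.212% of f_max
  w <- weibull_release(c(0, 5, 1000), f_max = 100, td = 5, b = 1)
  expect_equal(w$pct_dissolved[1], 0)
  expect_equal(w$pct_dissolved[2], 100 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(w$pct_dissolved[3], 100, tolerance = 1e-6)
  # noise-free curves are monotone nondecreasing
  set.seed(3)
  for (i in 1:10) {
    w <- weibull_release(seq(0, 120, by = 5), f_max = runif(1, 50, 110),
                         td = runif(1, 2, 40), b = runif(1, 0.5, 3))
    expect_true(all(diff(w$pct_dissolved) >= 0))
  }
  expect_error(weibull_release(c(10, 5), 100, 5, 1), "increasing")
})

test_that("dissolution simulation is seed-deterministic and clipped", {
  prods <- data.frame(product_id = c("A", "B"), f_max = c(105, 95),
                      td = c(4, 9), b = c(1.2, 0.9), noise_sd = 5)
  d1 <- simulate_dissolution(prods, times = c(5, 10, 15, 30), seed = 42)
  d2 <- simulate_dissolution(prods, times = c(5, 10, 15, 30), seed = 42)
  expect_identical(d1, d2)
  expect_true(all(d1$pct_dissolved >= 0 & d1$pct_dissolved <= 110))
})
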