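#' Difference factor f1 between two dissolution profiles
#'
#' The difference factor measures the average relative error between a test
#' and a reference release curve, expressed in percent of the cumulative
#' reference release:
#' \deqn{f_1 = 100 \cdot \frac{\sum_t |R_t - T_t|}{\sum_t R_t}}
#' where \eqn{R_t} and \eqn{T_t} are the percent of label dissolved by the
#' reference and test product at each shared sampling time. Two profiles are
#' conventionally regarded as similar when \eqn{0 \le f_1 \le 15}.
#'
#' @param ref,test Numeric vectors of percent label dissolved, on the same
#'   time grid (percent units, 0--110).
#' @return A single numeric value in percent, `>= 0`.
#' @seealso [f2_factor()], [compare_dissolution()]
#' @examples
#' f1_factor(c(50, 80, 90), c(45, 72, 81))  # 10
#' @export
f1_factor <- function(ref, test) {
  check_profile_pair(ref, test)
  denom <- sum(ref)
  if (denom <= 0) {
    stop_input("Reference profile sums to zero; f1 is undefined.")
  }
  100 * sum(abs(ref - test)) / denom
}

#' Similarity factor f2 between two dissolution profiles
#'
#' The similarity factor is a logarithmic reciprocal square-root transform of
#' the mean squared difference between two release curves:
#' \deqn{f_2 = 50 \cdot \log_{10}\!\left(\left[1 + \tfrac{1}{n}\sum_t (R_t - T_t)^2\right]^{-0.5} \cdot 100\right)}
#' Identical curves give \eqn{f_2 = 100}; an average difference of 10
#' percentage points at every time gives just under 50, which is why
#' \eqn{f_2 \ge 50} is the regulatory similarity threshold.
#'
#' @inheritParams f1_factor
#' @param truncate_after_85 If `TRUE`, at most one sampling point where both
#'   profiles exceed 85\% dissolved is retained before computing the factor,
#'   the usual regulatory handling of the plateau. Default `FALSE`.
#' @return A single numeric value, `<= 100`.
#' @examples
#' f2_factor(c(40, 60, 85), c(40, 60, 85))  # 100
#' f2_factor(c(40, 60, 85), c(30, 50, 75))  # < 50
#' @export
f2_factor <- function(ref, test, truncate_after_85 = FALSE) {
  check_profile_pair(ref, test)
  if (isTRUE(truncate_after_85)) {
    keep <- truncation_mask(ref, test)
    ref <- ref[keep]
    test <- test[keep]
  }
  n <- length(ref)
  if (n < 1) {
    stop_input("No points left after 85% truncation.")
  }
  50 * log10((1 + sum((ref - test)^2) / n)^-0.5 * 100)
}

# Keep everything up to (and including) the first point at which both
# profiles exceed 85% dissolved; drop the rest of the plateau.
truncation_mask <- function(ref, test) {
  both_over <- ref > 85 & test > 85
  if (!any(both_over)) {
    return(rep(TRUE, length(ref)))
  }
  seq_along(ref) <= which(both_over)[1]
}

check_profile_pair <- function(ref, test) {
  check_numeric(ref, "ref")
  check_numeric(test, "test")
  if (length(ref) != length(test)) {
    stop_input("`ref` and `test` must have the same number of points.")
  }
  if (length(ref) < 1) {
    stop_input("At least one shared time point is required.")
  }
  invisible(NULL)
}

#' Compare dissolution profiles of several products against a reference
#'
#' Computes the difference factor `f1` and similarity factor `f2` of every
#' test product against the chosen reference and applies the joint acceptance
#' window (`0 <= f1 <= 15` and `50 <= f2 <= 100`) to produce a similarity
#' verdict per product.
#'
#' @param data A data frame of dissolution measurements in long format with
#'   columns `product_id`, `time_min`, and `pct_dissolved`. Every product
#'   must be measured on the identical time grid as the reference; mismatched
#'   grids are an error, never silently interpolated.
#' @param reference The `product_id` of the reference product.
#' @param truncate_after_85 Passed to [f2_factor()].
#' @return A tibble with one row per test product and columns `product_id`,
#'   `f1`, `f2`, `similar`, `n_points_used`.
#' @examples
#' d <- simulate_dissolution(
#'   products = data.frame(
#'     product_id = c("R", "T"), f_max = c(98, 95),
#'     td = c(6, 8), b = c(1.1, 1), noise_sd = 0
#'   ),
#'   times = c(5, 10, 15, 20, 30, 45, 60), seed = 1
#' )
#' compare_dissolution(d, reference = "R")
#' @export
compare_dissolution <- function(data, reference, truncate_after_85 = FALSE) {
  check_cols(data, c("product_id", "time_min", "pct_dissolved"))
  ids <- unique(data$product_id)
  if (!reference %in% ids) {
    stop_input(sprintf("Reference product '%s' not found in `data`.", reference))
  }
  ref_tbl <- data[data$product_id == reference, ]
  ref_tbl <- ref_tbl[order(ref_tbl$time_min), ]
  check_times(ref_tbl$time_min, "reference time grid")

  purrr::map_dfr(setdiff(ids, reference), function(id) {
    tst <- data[data$product_id == id, ]
    tst <- tst[order(tst$time_min), ]
    if (length(tst$time_min) != length(ref_tbl$time_min) ||
        any(tst$time_min != ref_tbl$time_min)) {
      stop_input(sprintf(
        "Product '%s' is not measured on the reference time grid.", id
      ))
    }
    n_used <- if (isTRUE(truncate_after_85)) {
      sum(truncation_mask(ref_tbl$pct_dissolved, tst$pct_dissolved))
    } else {
      length(ref_tbl$pct_dissolved)
    }
    f1 <- f1_factor(ref_tbl$pct_dissolved, tst$pct_dissolved)
    f2 <- f2_factor(ref_tbl$pct_dissolved, tst$pct_dissolved, truncate_after_85)
    tibble::tibble(
      product_id = id,
      f1 = f1,
      f2 = f2,
      similar = f1 >= 0 & f1 <= 15 & f2 >= 50 & f2 <= 100,
      n_points_used = n_used
    )
  })
}

#' Classify the release rate of a dissolution profile
#'
#' Applies the immediate-release decision rules used for biowaiver-style
#' assessment: a product is *very rapidly dissolving* when more than 85\% of
#' the label is dissolved within 15 minutes, *rapidly dissolving* when at
#' least 85\% is dissolved within 30 minutes, *compliant* when at least 80\%
#' is dissolved within 30 minutes, and *noncompliant* otherwise. Values at 15
#' and 30 minutes are obtained by linear interpolation between bracketing
#' sampling points when not measured directly.
#'
#' @inheritParams compare_dissolution
#' @return A tibble with columns `product_id`, `pct_15min`, `pct_30min`, and
#'   `category` (ordered factor `very_rapid > rapid > compliant_30min >
#'   noncompliant`).
#' @export
classify_release <- function(data) {
  check_cols(data, c("product_id", "time_min", "pct_dissolved"))
  purrr::map_dfr(unique(data$product_id), function(id) {
    p <- data[data$product_id == id, ]
    p <- p[order(p$time_min), ]
    if (max(p$time_min) < 30 || min(p$time_min) > 15) {
      stop_input(sprintf(
        "Profile for '%s' must bracket both 15 and 30 minutes.", id
      ))
    }
    v15 <- interp_at(p$time_min, p$pct_dissolved, 15)
    v30 <- interp_at(p$time_min, p$pct_dissolved, 30)
    category <- if (v15 > 85) {
      "very_rapid"
    } else if (v30 >= 85) {
      "rapid"
    } else if (v30 >= 80) {
      "compliant_30min"
    } else {
      "noncompliant"
    }
    tibble::tibble(
      product_id = id,
      pct_15min = v15,
      pct_30min = v30,
      category = factor(
        category,
        levels = c("noncompliant", "compliant_30min", "rapid", "very_rapid"),
        ordered = TRUE
      )
    )
  })
}
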