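# Cross-formulation statistics: relative bioavailability, one-way ANOVA and
# Tukey's honestly-significant-difference comparison of PK parameters.

#' Dose-corrected relative bioavailability
#'
#' \deqn{F_r = 100 \cdot \frac{AUC_T \cdot D_R}{AUC_R \cdot D_T}}
#' the percent ratio of test to reference exposure after correcting for any
#' dose difference.
#'
#' @param auc_t,auc_r Test and reference AUC, hr·mg/L.
#' @param dose_t,dose_r Test and reference dose, mg.
#' @return Relative bioavailability in percent.
#' @examples
#' relative_bioavailability(57.45, 62.24, 500, 500)
#' @export
relative_bioavailability <- function(auc_t, auc_r, dose_t = 1, dose_r = 1) {
  for (nm in c("auc_t", "auc_r", "dose_t", "dose_r")) {
    check_numeric(get(nm), nm, positive = TRUE)
  }
  100 * (auc_t * dose_r) / (auc_r * dose_t)
}

#' One-way analysis of variance on grouped values
#'
#' Standard between/within decomposition via [stats::aov()]. Accepts either a
#' list of numeric vectors (one per group) or a data frame with `value` and
#' `group` columns.
#'
#' @param groups A list of numeric vectors, or a data frame with columns
#'   `value` and `group`.
#' @return A one-row tibble with `f_statistic`, `p_value`, `df_between`,
#'   `df_within`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
#' @export
one_way_anova <- function(groups) {
  d <- as_group_frame(groups)
  k <- nlevels(d$group)
  n <- nrow(d)
  if (zero_within_variance(d)) {
    means <- tapply(d$value, d$group, mean)
    equal <- max(means) - min(means) == 0
    return(tibble::tibble(
      f_statistic = if (equal) 0 else Inf,
      p_value = if (equal) 1 else 0,
      df_between = k - 1L, df_within = n - k
    ))
  }
  tab <- anova(aov(value ~ group, data = d))
  tibble::tibble(
    f_statistic = tab$`F value`[1],
    p_value = tab$`Pr(>F)`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2]
  )
}

# Degenerate limit: every group internally constant (MSE = 0).
zero_within_variance <- function(d) {
  all(tapply(d$value, d$group, function(v) max(v) - min(v)) == 0)
}

#' Tukey's honestly-significant-difference test on grouped values
#'
#' All-pairs comparison after a one-way ANOVA using the studentized range
#' distribution (Tukey's A procedure), via [stats::TukeyHSD()]. The q
#' statistic reported per pair is the absolute mean difference divided by
#' `sqrt(MSE / n_harmonic)`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level, default 0.05.
#' @return A tibble with one row per pair: `group_1`, `group_2`, `diff`,
#'   `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1).")
  d <- as_group_frame(groups)
  if (zero_within_variance(d)) {
    # MSE = 0 limit: any mean difference is infinitely many SEs away
    means <- tapply(d$value, d$group, mean)
    cmb <- utils::combn(levels(d$group), 2)
    return(purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      g1 <- cmb[1, i]
      g2 <- cmb[2, i]
      dm <- means[[g2]] - means[[g1]]
      tibble::tibble(
        group_1 = g1, group_2 = g2, diff = dm,
        q = if (dm == 0) 0 else Inf,
        p_adj = if (dm == 0) 1 else 0,
        significant = dm != 0
      )
    }))
  }
  fit <- aov(value ~ group, data = d)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  mse <- anova(fit)["Residuals", "Mean Sq"]
  ns <- table(d$group)
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  purrr::map_dfr(seq_len(nrow(tk)), function(i) {
    g2 <- pairs[[i]][1] # TukeyHSD labels rows "g2-g1"
    g1 <- pairs[[i]][2]
    nh <- 2 / (1 / ns[[g1]] + 1 / ns[[g2]])
    q <- abs(tk[i, "diff"]) / sqrt(mse / nh)
    tibble::tibble(
      group_1 = g1, group_2 = g2,
      diff = tk[i, "diff"], q = q,
      p_adj = tk[i, "p adj"],
      significant = tk[i, "p adj"] < alpha
    )
  })
}

as_group_frame <- function(groups) {
  if (is.data.frame(groups)) {
    check_cols(groups, c("value", "group"), "groups")
    d <- data.frame(value = groups$value, group = factor(groups$group))
  } else if (is.list(groups)) {
    if (is.null(names(groups))) {
      names(groups) <- paste0("g", seq_along(groups))
    }
    d <- data.frame(
      value = unlist(groups, use.names = FALSE),
      group = factor(rep(names(groups), lengths(groups)))
    )
  } else {
    stop_input("`groups` must be a list of numeric vectors or a data frame.")
  }
  if (nlevels(d$group) < 2 || any(table(d$group) < 2)) {
    stop_input("At least 2 groups with at least 2 values each are required.")
  }
  d
}

BIOEQ_PARAMETERS <- c("auc_last", "auc_inf", "aumc_last", "cmax", "tmax",
                      "hl_lambda_z", "cl_f", "vz_f")

#' Brand-level bioequivalence comparison of noncompartmental results
#'
#' Aggregates per-subject NCA results by brand and compares formulations:
#' dose-corrected relative bioavailability of every test brand against the
#' reference (two conventions: the ratio of brand-mean AUCs, the default, and
#' the mean of subject-wise ratios formed by index pairing, which requires
#' equal group sizes), one-way ANOVA across brands for each PK parameter,
#' and Tukey HSD flags for every brand pair. A test brand is classed as
#' interchangeable when its (ratio-of-means) relative bioavailability is at
#' least 90 percent.
#'
#' @param nca_tbl Output of [nca()] with a `brand` column.
#' @param reference Brand label of the reference product.
#' @param alpha Significance level for ANOVA/Tukey flags.
#' @param auc Which AUC feeds the bioavailability ratio: `"auc_inf"`
#'   (default) or `"auc_last"`.
#' @param doses Optional named vector of per-brand doses (mg) for the dose
#'   correction; equal doses are assumed when omitted.
#' @param parameters PK parameters entering ANOVA/Tukey.
#' @return An object of class `bioeq_result` with elements `fr` (tibble:
#'   `brand`, `fr_ratio_of_means`, `fr_mean_of_ratios`, `interchangeable`),
#'   `summaries` (per-brand mean/sd/n), `anova` (per-parameter F and p),
#'   `tukey` (per-parameter pairwise flags), `reference`, `alpha`.
#' @examples
#' study <- simulate_bioeq_study(rabbit_cipro_truth(), seed = 1)
#' res <- run_bioeq_study(nca(study), reference = "F")
#' tidy(res)
#' @export
run_bioeq_study <- function(nca_tbl, reference, alpha = 0.05,
                            auc = c("auc_inf", "auc_last"), doses = NULL,
                            parameters = BIOEQ_PARAMETERS) {
  auc <- match.arg(auc)
  check_cols(nca_tbl, c("brand", auc), "nca_tbl")
  brands <- unique(nca_tbl$brand)
  if (!reference %in% brands) {
    stop_input(sprintf("Reference brand '%s' not present.", reference))
  }
  if (length(brands) < 2) stop_input("At least 2 brands are required.")
  if (is.null(doses)) {
    doses <- setNames(rep(1, length(brands)), brands)
  }
  ref_auc <- nca_tbl[[auc]][nca_tbl$brand == reference]
  fr <- purrr::map_dfr(setdiff(brands, reference), function(b) {
    t_auc <- nca_tbl[[auc]][nca_tbl$brand == b]
    rom <- relative_bioavailability(mean(t_auc), mean(ref_auc),
                                    doses[[b]], doses[[reference]])
    mor <- if (length(t_auc) == length(ref_auc)) {
      mean(relative_bioavailability(t_auc, ref_auc,
                                    doses[[b]], doses[[reference]]))
    } else {
      NA_real_
    }
    tibble::tibble(
      brand = b, fr_ratio_of_means = rom, fr_mean_of_ratios = mor,
      interchangeable = rom >= 90
    )
  })
  parameters <- intersect(parameters, names(nca_tbl))
  anova_tbl <- purrr::map_dfr(parameters, function(p) {
    d <- data.frame(value = nca_tbl[[p]], group = nca_tbl$brand)
    d <- d[complete.cases(d), ]
    res <- tryCatch(one_way_anova(d), error = function(e) {
      tibble::tibble(f_statistic = NA_real_, p_value = NA_real_,
                     df_between = NA_integer_, df_within = NA_integer_)
    })
    tibble::tibble(parameter = p, res)
  })
  tukey_tbl <- purrr::map_dfr(parameters, function(p) {
    d <- data.frame(value = nca_tbl[[p]], group = nca_tbl$brand)
    d <- d[complete.cases(d), ]
    res <- tryCatch(tukey_hsd(d, alpha = alpha), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(parameter = p, res)
  })
  structure(
    list(
      fr = fr,
      summaries = nca_summary(nca_tbl),
      anova = anova_tbl,
      tukey = tukey_tbl,
      reference = reference,
      alpha = alpha,
      auc = auc
    ),
    class = "bioeq_result"
  )
}

#' @describeIn run_bioeq_study Relative-bioavailability table.
#' @param x A `bioeq_result`.
#' @param ... Unused.
#' @export
tidy.bioeq_result <- function(x, ...) {
  x$fr
}

#' @describeIn run_bioeq_study One-row study overview.
#' @export
glance.bioeq_result <- function(x, ...) {
  tibble::tibble(
    n_brands = length(unique(x$summaries$brand)),
    reference = x$reference,
    alpha = x$alpha,
    auc = x$auc,
    min_fr = min(x$fr$fr_ratio_of_means),
    max_fr = max(x$fr$fr_ratio_of_means),
    all_interchangeable = all(x$fr$interchangeable),
    n_significant_pairs = sum(x$tukey$significant %||% logical(0))
  )
}

#' @export
print.bioeq_result <- function(x, ...) {
  cat(sprintf("Bioequivalence study vs reference '%s' (alpha = %g, %s)\n",
              x$reference, x$alpha, x$auc))
  cat("Relative bioavailability (%):\n")
  print(as.data.frame(x$fr), row.names = FALSE, digits = 4)
  sig <- x$tukey[x$tukey$significant, , drop = FALSE]
  cat(sprintf("Tukey-significant pairs: %d\n", nrow(sig)))
  invisible(x)
}
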