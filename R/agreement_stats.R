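#' Absolute relative percentage difference
#'
#' Agreement summary between a manual and an automated (ellipsoid-fit) mean
#' measurement: `100 * |ellipsoid - manual| / ellipsoid`. The automated value
#' is the denominator — the 3D measurement is treated as the reference the 2D
#' assessment under-reads. For integer report parity use
#' [round_half_away()]; full precision is returned.
#'
#' @param manual_mean,ellipsoid_mean Mean measurements in the same units;
#'   `ellipsoid_mean` must be positive.
#' @return Percentage difference (full precision).
#' @export
#' @examples
#' round_half_away(relative_pct_diff(0.74, 0.99))  # 25
relative_pct_diff <- function(manual_mean, ellipsoid_mean) {
  if (!is.numeric(ellipsoid_mean) || any(!is.finite(ellipsoid_mean)) ||
      any(ellipsoid_mean <= 0)) {
    lf_abort("`ellipsoid_mean` (the denominator) must be positive.", "domain")
  }
  if (!is.numeric(manual_mean) || any(!is.finite(manual_mean))) {
    lf_abort("`manual_mean` must be finite.", "validation")
  }
  100 * abs(ellipsoid_mean - manual_mean) / ellipsoid_mean
}

check_paired <- function(x, y, min_n = 2L) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    lf_abort("`x` and `y` must be numeric vectors of equal length.", "validation")
  }
  if (anyNA(x) || anyNA(y)) lf_abort("Missing values are not allowed.", "validation")
  if (length(x) < min_n) {
    lf_abort(sprintf("Need at least %d pairs (got %d).", min_n, length(x)),
             "validation")
  }
  invisible(NULL)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and 95% limits of agreement between two paired
#' measurement methods: differences `d = y - x`, bias `mean(d)`, limits
#' `bias +/- 1.96 * SD(d)` with the sample (n-1) standard deviation.
#'
#' @param x,y Paired numeric vectors (length >= 2); `y` is the method whose
#'   excess over `x` is reported.
#' @return One-row tibble with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
#' @examples
#' bland_altman(c(1, 2), c(2, 4))
bland_altman <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(
    bias = bias,
    loa_low = bias - 1.96 * s,
    loa_high = bias + 1.96 * s,
    sd_diff = s,
    n = length(d)
  )
}

#' Pearson correlation between paired measurements
#'
#' Sample product-moment correlation; constant input has no defined
#' correlation and raises an error rather than returning NA.
#'
#' @param x,y Paired numeric vectors (length >= 3), neither constant.
#' @return The correlation coefficient `r`.
#' @export
pearson_r <- function(x, y) {
  check_paired(x, y, min_n = 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    lf_abort("Correlation is undefined for constant input.", "undefined_correlation")
  }
  stats::cor(x, y)
}

#' Paired two-sided t-test
#'
#' Two-sided paired t on `d = y - x` with `n - 1` degrees of freedom. When
#' every difference is exactly zero the methods agree perfectly and the test
#' is defined as `t = 0, p = 1`; nonzero constant differences give an
#' infinite statistic with `p = 0`.
#'
#' @param x,y Paired numeric vectors (length >= 2).
#' @return One-row tibble with `t_stat`, `p_value`, `df`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  check_paired(x, y, min_n = 2L)
  d <- y - x
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t_stat = 0, p_value = 1, df = n - 1, mean_diff = 0))
    }
    return(tibble::tibble(t_stat = sign(mean(d)) * Inf, p_value = 0,
                          df = n - 1, mean_diff = mean(d)))
  }
  ht <- stats::t.test(y, x, paired = TRUE)
  tibble::tibble(
    t_stat = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    mean_diff = unname(ht$estimate)
  )
}

#' Normality test (Kolmogorov-Smirnov with estimated parameters)
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with the
#' sample's own mean and SD — the Lilliefors form, whose p-values account for
#' the estimated parameters (delegated to [nortest::lillie.test()]).
#'
#' @param x Numeric vector, length >= 5, not constant.
#' @return The p-value; small values indicate departure from normality.
#' @export
ks_normality <- function(x) {
  if (!is.numeric(x) || anyNA(x)) lf_abort("`x` must be numeric without NA.", "validation")
  if (length(x) < 5L) {
    lf_abort(sprintf("Need at least 5 observations (got %d).", length(x)), "validation")
  }
  if (stats::sd(x) == 0) lf_abort("Normality is undefined for constant input.", "validation")
  nortest::lillie.test(x)$p.value
}

#' Per-score summary of paired measurements
#'
#' Mean and sample (n-1) SD of the four measurement columns within each
#' initial PI-RADS score — the per-score summary table layout. Scores with a
#' single subject report the mean with SD absent (NA).
#'
#' @param table A cohort table (see [read_cohort_table()]).
#' @return A tibble with one row per `(score, measure)` pair, columns
#'   `initial_score`, `measure`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' co <- simulate_cohort(c("3" = 4, "4" = 4), seed = 2)
#' summarize_by_score(co)
summarize_by_score <- function(table) {
  tb <- validate_cohort_table(table)
  if (nrow(tb) == 0) lf_abort("Cohort table has no rows.", "empty_input")
  meas <- c("manual_tv_cc", "auto_tv_cc", "manual_tmd_cm", "auto_tmd_cm")
  tb |>
    tidyr::pivot_longer(dplyr::all_of(meas), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$initial_score, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(measure = factor(.data$measure, levels = meas)) |>
    dplyr::arrange(.data$initial_score, .data$measure) |>
    dplyr::mutate(measure = as.character(.data$measure))
}

#' Full manual-vs-automated agreement report
#'
#' The cohort-level comparison between the radiologist-style and automated 3D
#' measurements, for tumour volume and maximum diameter: paired t, Pearson r
#' (with its test p-value), Bland-Altman bias and limits of agreement,
#' normality of the differences, and the absolute relative percentage
#' difference of the means.
#'
#' @param table A cohort table (see [read_cohort_table()]).
#' @return A tibble with one row per measure (`tv_cc`, `tmd_cm`) and columns
#'   `n`, `manual_mean`, `auto_mean`, `bias`, `loa_low`, `loa_high`,
#'   `pearson_r`, `pearson_p`, `t_stat`, `p_value`, `ks_p`, `rel_pct_diff`.
#' @export
#' @examples
#' co <- simulate_cohort(c("3" = 5, "4" = 5, "5" = 5), seed = 3)
#' agreement_report(co)
agreement_report <- function(table) {
  tb <- validate_cohort_table(table)
  if (nrow(tb) < 3) lf_abort("Agreement report needs at least 3 subjects.", "validation")
  one <- function(measure, man, aut) {
    ba <- bland_altman(man, aut)
    tt <- paired_t(man, aut)
    ct <- stats::cor.test(man, aut)
    tibble::tibble(
      measure = measure,
      n = length(man),
      manual_mean = mean(man),
      auto_mean = mean(aut),
      bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
      pearson_r = pearson_r(man, aut),
      pearson_p = ct$p.value,
      t_stat = tt$t_stat, p_value = tt$p_value,
      ks_p = if (length(man) >= 5) ks_normality(aut - man) else NA_real_,
      rel_pct_diff = relative_pct_diff(mean(man), mean(aut))
    )
  }
  dplyr::bind_rows(
    one("tv_cc", tb$manual_tv_cc, tb$auto_tv_cc),
    one("tmd_cm", tb$manual_tmd_cm, tb$auto_tmd_cm)
  )
}
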