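#' Apply the PI-RADS v2.1 size criterion to a lesion
#'
#' PI-RADS v2.1 uses a tumour-size decision criterion — maximum diameter
#' `>= 1.5 cm` (inclusive) — to separate assessment score 5 from score 4.
#' A lesion whose 3D maximum diameter meets the threshold is assigned score
#' 5; scores never decrease. By default both score-3 and score-4 lesions are
#' eligible for the upgrade, matching the published cohort behaviour where
#' initially score-3 lesions with large 3D diameters were classified score 5;
#' `upgrade_from = 4` restricts to the strict guideline reading in which the
#' size rule formally separates only 4 from 5.
#'
#' @param initial_score Integer vector of initial scores, each 3, 4 or 5.
#' @param tmd_cm Positive numeric vector of tumour maximum diameters (cm).
#' @param threshold_cm Size cut-off in cm (default 1.5); comparison is `>=`.
#' @param upgrade_from Scores eligible for upgrade (default `c(3, 4)`).
#' @return Integer vector of final scores.
#' @export
#' @examples
#' apply_size_criterion(c(3, 4, 4, 5), c(1.67, 2.31, 1.49, 0.9))
apply_size_criterion <- function(initial_score, tmd_cm, threshold_cm = 1.5,
                                 upgrade_from = c(3, 4)) {
  if (!all(initial_score %in% 3:5)) {
    lf_abort("initial_score values must be 3, 4 or 5.", "validation")
  }
  if (!is.numeric(tmd_cm) || length(tmd_cm) != length(initial_score) ||
      any(!is.finite(tmd_cm)) || any(tmd_cm <= 0)) {
    lf_abort("`tmd_cm` must be positive numbers, one per score.", "validation")
  }
  check_scalar_positive(threshold_cm, "threshold_cm")
  if (!all(upgrade_from %in% c(3, 4))) {
    lf_abort("`upgrade_from` may only contain 3 and/or 4.", "validation")
  }
  as.integer(ifelse(initial_score %in% upgrade_from & tmd_cm >= threshold_cm,
                    5L, initial_score))
}

#' Rescore a cohort with the PI-RADS size criterion
#'
#' Applies [apply_size_criterion()] to every subject using the automated 3D
#' diameter column, and summarizes how many initially score-3 and score-4
#' subjects move to score 5. Percentages use the supplied whole-cohort
#' denominators (the table may contain only the subjects whose score changed,
#' as published rescoring tables do) and are rounded to the nearest integer,
#' halves away from zero.
#'
#' @param table A cohort table (see [read_cohort_table()]).
#' @param denominators Named numeric vector `c(score3_n = ..., score4_n = ...)`
#'   giving the total number of score-3 and score-4 subjects in the cohort.
#' @param threshold_cm Size cut-off in cm (default 1.5).
#' @param upgrade_from Scores eligible for upgrade (default `c(3, 4)`).
#' @param tmd_col Column holding the diameter to score on
#'   (default `"auto_tmd_cm"`).
#' @return An object of class `pirads_rescore`: a list with `table` (input
#'   plus `final_score` and `upgraded` columns) and `summary` (one-row tibble
#'   with `n_3_to_5`, `n_4_to_5`, `pct_3_to_5`, `pct_4_to_5`,
#'   `threshold_cm`). [generics::tidy()] returns the per-subject table,
#'   [generics::glance()] the summary.
#' @export
#' @examples
#' tb <- read_cohort_table(system.file("extdata", "table2.csv",
#'                                     package = "lesionfit3d"))
#' rescore_cohort(tb, denominators = c(score3_n = 10, score4_n = 18))
rescore_cohort <- function(table, denominators, threshold_cm = 1.5,
                           upgrade_from = c(3, 4), tmd_col = "auto_tmd_cm") {
  tb <- validate_cohort_table(table)
  if (!tmd_col %in% names(tb)) {
    lf_abort(sprintf("Column '%s' not found in the cohort table.", tmd_col), "schema")
  }
  den <- unlist(denominators)
  if (!all(c("score3_n", "score4_n") %in% names(den)) ||
      any(den[c("score3_n", "score4_n")] < 0)) {
    lf_abort("`denominators` must provide non-negative score3_n and score4_n.",
             "validation")
  }

  if (nrow(tb) > 0) {
    tb$final_score <- apply_size_criterion(tb$initial_score, tb[[tmd_col]],
                                           threshold_cm = threshold_cm,
                                           upgrade_from = upgrade_from)
  } else {
    tb$final_score <- integer(0)
  }
  tb$upgraded <- tb$final_score > tb$initial_score

  n35 <- sum(tb$initial_score == 3 & tb$final_score == 5)
  n45 <- sum(tb$initial_score == 4 & tb$final_score == 5)
  if (n35 > den[["score3_n"]] || n45 > den[["score4_n"]]) {
    lf_abort("Denominators are smaller than the observed upgrade counts.",
             "validation")
  }
  pct <- function(n, d) if (d > 0) round_half_away(100 * n / d) else NA_real_
  summary <- tibble::tibble(
    n_3_to_5 = n35, n_4_to_5 = n45,
    pct_3_to_5 = pct(n35, den[["score3_n"]]),
    pct_4_to_5 = pct(n45, den[["score4_n"]]),
    score3_n = den[["score3_n"]], score4_n = den[["score4_n"]],
    threshold_cm = threshold_cm
  )
  structure(list(table = tb, summary = summary), class = "pirads_rescore")
}

#' @export
print.pirads_rescore <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pirads_rescore> threshold %.2g cm: %d/%d score-3 (%g%%) and %d/%d score-4 (%g%%) upgraded to 5\n",
    s$threshold_cm, s$n_3_to_5, s$score3_n, s$pct_3_to_5,
    s$n_4_to_5, s$score4_n, s$pct_4_to_5
  ))
  invisible(x)
}
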