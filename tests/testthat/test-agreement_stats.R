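test_that("relative percentage difference uses the ellipsoid denominator", {
  expect_equal(round_half_away(relative_pct_diff(0.74, 0.99)), 25)
  expect_equal(round_half_away(relative_pct_diff(1.14, 1.97)), 42)
  expect_equal(relative_pct_diff(1, 1), 0)
  # invariant under common positive scaling
  expect_equal(relative_pct_diff(0.6, 0.9), relative_pct_diff(6, 9))
  expect_error(relative_pct_diff(1, 0), class = "lesionfit3d_error_domain")
  expect_error(relative_pct_diff(1, -2), class = "lesionfit3d_error_domain")
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(2.1, 3.4, 1.1, 5.6)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))

  ba <- bland_altman(c(1, 2), c(2, 4))
  expect_equal(ba$bias, 1.5)
  expect_equal(ba$loa_low, 1.5 - 1.96 / sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.5 + 1.96 / sqrt(2), tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.70711, tolerance = 1e-5)

  # interval contains the bias; width is exactly 2 * 1.96 * SD
  withr::local_seed(5)
  y <- x + rnorm(4)
  bb <- bland_altman(x, y)
  expect_lte(bb$loa_low, bb$bias)
  expect_gte(bb$loa_high, bb$bias)
  expect_equal(bb$loa_high - bb$loa_low, 2 * 1.96 * sd(y - x))

  expect_error(bland_altman(1, 2), class = "lesionfit3d_error_validation")
  expect_error(bland_altman(1:3, 1:4), class = "lesionfit3d_error_validation")
})

test_that("Pearson correlation identities and affine invariance", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  withr::local_seed(8)
  y <- x + rnorm(5)
  expect_equal(pearson_r(3 * x + 2, y), pearson_r(x, y))
  expect_equal(pearson_r(x, -2 * y + 7), -pearson_r(x, y))
  expect_error(pearson_r(x, rep(1, 5)),
               class = "lesionfit3d_error_undefined_correlation")
  expect_error(pearson_r(1:2, 1:2), class = "lesionfit3d_error_validation")
})

test_that("paired t matches the textbook formula", {
  x <- c(1, 2, 3); y <- c(2, 3, 5)
  # d = (1, 1, 2): mean 4/3, sd 1/sqrt(3), t = (4/3)/(1/3) = 4
  tt <- paired_t(x, y)
  expect_equal(tt$t_stat, 4)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value, 0.0572, tolerance = 1e-3)

  t0 <- paired_t(x, x)
  expect_equal(t0$t_stat, 0)
  expect_equal(t0$p_value, 1)

  tc <- paired_t(x, x + 2)
  expect_equal(tc$t_stat, Inf)
  expect_equal(tc$p_value, 0)

  expect_error(paired_t(1:3, 1:2), class = "lesionfit3d_error_validation")
})

test_that("normality test separates normal from uniform samples", {
  alpha <- 0.05
  reps <- 100
  p_norm <- p_unif <- numeric(reps)
  withr::local_seed(21)
  for (i in seq_len(reps)) {
    p_norm[i] <- ks_normality(rnorm(500))
    p_unif[i] <- ks_normality(runif(500, -sqrt(3), sqrt(3)))
  }
  expect_gte(mean(p_norm > alpha), 0.9)
  expect_gte(mean(p_unif < alpha), 0.9)
  expect_error(ks_normality(rnorm(3)), class = "lesionfit3d_error_validation")
})

test_that("per-score summaries use sample SD and handle singletons", {
  tb <- read_cohort_table(table2_path())[1:3, ]
  tb$initial_score <- c(3L, 3L, 4L)
  tb$auto_tv_cc <- c(0.4, 0.6, 1.0)
  s <- summarize_by_score(tb)
  row <- s[s$initial_score == 3 & s$measure == "auto_tv_cc", ]
  expect_equal(row$mean, 0.5)
  expect_equal(row$sd, 0.1414, tolerance = 1e-3)
  single <- s[s$initial_score == 4 & s$measure == "auto_tv_cc", ]
  expect_equal(single$n, 1L)
  expect_true(is.na(single$sd))
  expect_error(summarize_by_score(tb[0, ]), class = "lesionfit3d_error_empty_input")
})

test_that("agreement_report assembles consistent statistics", {
  co <- simulate_cohort(c("3" = 8, "4" = 8, "5" = 8), seed = 42)
  rep <- agreement_report(co)
  expect_equal(rep$measure, c("tv_cc", "tmd_cm"))
  for (i in 1:2) {
    expect_lte(rep$loa_low[i], rep$bias[i])
    expect_gte(rep$loa_high[i], rep$bias[i])
    expect_lte(abs(rep$pearson_r[i]), 1)
    expect_gte(rep$p_value[i], 0)
    expect_lte(rep$p_value[i], 1)
  }
  # the 3D-vs-2D signature: automated diameter exceeds axial manual diameter
  expect_gt(rep$auto_mean[rep$measure == "tmd_cm"],
            rep$manual_mean[rep$measure == "tmd_cm"])
})
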