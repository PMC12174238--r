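test_that("Wilcoxon exact p matches full sign-assignment enumeration", {
  # all-positive distinct differences, n = 6: the most extreme of the 2^6
  # equally likely sign assignments on each side, so p = 2/64
  x <- c(1.1, 2.3, 3.7, 5.2, 8.9, 13.4)
  y <- x + c(2.0, 1.1, 3.4, 0.6, 1.8, 2.6)
  res <- wilcoxon_signed_rank(y, x)
  expect_equal(res$p_value, 2 / 2^6)
  expect_equal(res$method, "exact")

  # independent oracle: enumerate all 2^n sign assignments of the ranks
  d <- c(0.8, -1.7, 2.9, -4.1, 5.3, 6.2)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- signs %*% r
  p_oracle <- mean(pmin(1, 2 * pmin(mean(v_all <= v_obs), mean(v_all >= v_obs))))
  res2 <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_equal(res2$p_value, p_oracle)
})

test_that("Wilcoxon returns p = 1 for a balanced symmetric configuration", {
  # positive ranks sum to n(n+1)/4 = 14 with n = 7
  d <- c(1, -2, -3, -4, -5, 6, 7)
  res <- wilcoxon_signed_rank(d, rep(0, 7))
  expect_equal(res$statistic, 14)
  expect_equal(res$p_value, 1)
})

test_that("Wilcoxon drops zero differences and flags degenerate pairings", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(1, 2, 3, 5, 7, 9, 11)  # three zero differences
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$n_effective, 4)
  expect_error(wilcoxon_signed_rank(x, x), "degenerate pairing")
})

test_that("large-sample Wilcoxon switches to the corrected normal approximation", {
  set.seed(9)
  x <- rnorm(40)
  res <- wilcoxon_signed_rank(x + 0.5, x)
  expect_equal(res$method, "normal approximation")
  ref <- suppressWarnings(wilcox.test(x + 0.5, x, paired = TRUE,
                                      exact = FALSE, correct = TRUE))
  expect_equal(res$p_value, ref$p.value)
})

test_that("ICC mean squares match an independent ANOVA decomposition", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  long <- data.frame(
    value = c(x, y),
    subject = factor(rep(seq_along(x), 2)),
    rater = factor(rep(c("a", "b"), each = length(x)))
  )
  an <- anova(lm(value ~ subject + rater, data = long))
  ms <- an[["Mean Sq"]]
  res <- icc_two_way_mixed(x, y, "consistency")
  expect_equal(res$ms_subjects, ms[1], tolerance = 1e-12)
  expect_equal(res$ms_raters, ms[2], tolerance = 1e-12)
  expect_equal(res$ms_error, ms[3], tolerance = 1e-12)
  expect_equal(res$icc, (ms[1] - ms[3]) / (ms[1] + ms[3]), tolerance = 1e-12)
  resa <- icc_two_way_mixed(x, y, "absolute_agreement")
  n <- length(x)
  expect_equal(resa$icc,
               (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / n),
               tolerance = 1e-12)
})

test_that("ICC identities: perfect agreement and pure mean shift", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(icc_two_way_mixed(x, x, "consistency")$icc, 1)
  expect_equal(icc_two_way_mixed(x, x, "absolute_agreement")$icc, 1)
  expect_equal(icc_two_way_mixed(x, x)$band, "excellent")
  shifted <- icc_two_way_mixed(x, x + 4, "consistency")
  expect_equal(shifted$icc, 1, tolerance = 1e-12)
  expect_lt(icc_two_way_mixed(x, x + 4, "absolute_agreement")$icc, 1)
  expect_error(icc_two_way_mixed(rep(2, 5), rep(2, 5)), "zero variance")
})

test_that("consistency ICC dominates absolute agreement for shifted noisy pairs", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15, 100, 20)
    y <- x + 10 + rnorm(15, 0, 5)
    cons <- icc_two_way_mixed(x, y, "consistency")$icc
    abs_ <- icc_two_way_mixed(x, y, "absolute_agreement")$icc
    expect_gte(cons, abs_ - 1e-12)
    expect_gt(cons, -1); expect_lte(cons, 1)
  }
})

test_that("ICC interpretation bands partition at 0.5, 0.75 and 0.9", {
  expect_equal(icc_band(0.776), "good")
  expect_equal(icc_band(0.509), "moderate")
  expect_equal(icc_band(c(0.49999, 0.5, 0.74999, 0.75, 0.89999, 0.9, 1)),
               c("poor", "moderate", "moderate", "good", "good",
                 "excellent", "excellent"))
})

test_that("parametric Bland-Altman reproduces hand-computed limits", {
  x <- c(0, 0, 0)
  y <- c(1, 2, 3)
  ba <- bland_altman(x, y, "parametric")
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_lower, 2 - 1.96)
  expect_equal(ba$loa_upper, 2 + 1.96)
  expect_equal(ba$bias_ci,
               2 + c(-1, 1) * qt(0.975, 2) * 1 / sqrt(3), tolerance = 1e-12)
  ident <- bland_altman(x, x, "parametric")
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))
})

test_that("parametric limits of agreement are consistent at large n", {
  set.seed(12)
  d <- rnorm(1e4)
  ba <- bland_altman(rep(0, 1e4), d, "parametric")
  expect_lt(abs(ba$loa_lower - (-1.96)), 0.05)
  expect_lt(abs(ba$loa_upper - 1.96), 0.05)
  coverage <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_lt(abs(coverage - 0.95), 0.01)
})

test_that("nonparametric Bland-Altman uses medians and percentile limits", {
  set.seed(5)
  d <- rt(201, df = 3)  # heavy tails: the use case for the percentile method
  ba <- bland_altman(rep(0, 201), d, "nonparametric")
  expect_equal(ba$bias, median(d))
  expect_equal(ba$loa_lower, quantile(d, 0.025, type = 7, names = FALSE))
  expect_equal(ba$loa_upper, quantile(d, 0.975, type = 7, names = FALSE))
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)
  # order-statistic CI for the median covers the truth here
  expect_true(ba$bias_ci[1] <= ba$bias && ba$bias <= ba$bias_ci[2])
})

test_that("OLS fit and R-squared match closed forms", {
  x <- c(1, 2, 3, 4)
  fit <- ols_r2(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(ols_r2(x, rep(3, 4))$r_squared, 0)
  worked <- ols_r2(c(1, 2, 3), c(1, 3, 2))
  expect_equal(worked$r_squared, 0.25)
  expect_error(ols_r2(rep(1, 4), x), "constant x")
})

test_that("agreement reports assemble all four statistics per metric and stratum", {
  set.seed(77)
  pairs <- dplyr::bind_rows(lapply(c("glass", "resin"), function(dev) {
    dplyr::bind_rows(lapply(c("mean_tumor_dose", "tn_ratio"), function(m) {
      x <- rlnorm(27, log(150), 0.4)
      tibble::tibble(metric = m, stratum = dev, case_id = 1:27,
                     value_x = x, value_y = x * rlnorm(27, 0, 0.15))
    }))
  }))
  rep <- agreement_report(pairs)
  res <- tidy(rep)
  expect_equal(nrow(res), 4)  # 2 metrics x 2 strata
  expect_true(all(is.finite(res$wilcoxon_p)))
  expect_true(all(is.finite(res$icc)))
  expect_true(all(res$icc_band == icc_band(res$icc)))
  expect_true(all(is.finite(res$r_squared)))
  expect_true(all(res$ba_loa_lower <= res$ba_bias &
                    res$ba_bias <= res$ba_loa_upper))
  expect_equal(glance(rep)$n_strata, 2)
})

test_that("degenerate pairings are flagged, not fatal, in reports", {
  pairs <- tibble::tibble(metric = "D50", stratum = "glass", case_id = 1:5,
                          value_x = c(1, 2, 3, 4, 5),
                          value_y = c(1, 2, 3, 4, 5))
  res <- tidy(agreement_report(pairs))
  expect_match(res$note, "degenerate")
  expect_true(is.na(res$wilcoxon_p))
  expect_equal(res$icc, 1)
})

test_that("Holm adjustment is available but off by default", {
  set.seed(3)
  pairs <- dplyr::bind_rows(lapply(paste0("m", 1:3), function(m) {
    x <- rnorm(10)
    tibble::tibble(metric = m, stratum = "all", case_id = 1:10,
                   value_x = x, value_y = x + rnorm(10, 0.3, 0.2))
  }))
  plain <- tidy(agreement_report(pairs))
  expect_false("wilcoxon_p_adj" %in% names(plain))
  adj <- tidy(agreement_report(pairs, p_adjust = "holm"))
  expect_true(all(adj$wilcoxon_p_adj >= adj$wilcoxon_p - 1e-15))
})
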