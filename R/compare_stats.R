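#' Paired Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon signed-rank test on paired measurements. Zero
#' differences are dropped (the classical Wilcoxon convention), tied
#' absolute differences are mid-ranked, the exact null distribution is used
#' for up to 25 non-zero pairs (when there are no ties), and the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A list with `statistic` (the signed-rank sum V), `p_value`,
#'   `n_effective` (pairs after zero removal) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate pairing: all differences are zero", call. = FALSE)
  if (n < 3) stop("need at least 3 non-zero differences", call. = FALSE)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_effective = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Two-way mixed-effects intraclass correlation (single measures)
#'
#' Agreement between two fixed raters (e.g. two imaging modalities) over n
#' subjects, from the two-way ANOVA mean squares: between-subject
#' \eqn{MS_R}, between-rater \eqn{MS_C} and residual \eqn{MS_E}. With k = 2
#' raters:
#' \deqn{ICC_{consistency} = \frac{MS_R - MS_E}{MS_R + MS_E}}
#' \deqn{ICC_{agreement} = \frac{MS_R - MS_E}{MS_R + MS_E + 2(MS_C - MS_E)/n}}
#' The p-value is from the F test of \eqn{MS_R / MS_E}. The interpretation
#' band follows the conventional partition: poor below 0.5, moderate in
#' [0.5, 0.75), good in [0.75, 0.9), excellent at or above 0.9.
#'
#' @param x,y Paired numeric vectors (one per rater), length >= 3.
#' @param definition `"absolute_agreement"` (default) or `"consistency"`.
#' @return A list with `icc`, `p_value`, `band`, and the mean squares
#'   (`ms_subjects`, `ms_raters`, `ms_error`).
#' @export
icc_two_way_mixed <- function(x, y,
                              definition = c("absolute_agreement",
                                             "consistency")) {
  definition <- match.arg(definition)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  subj_means <- rowMeans(dat)
  rater_means <- colMeans(dat)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_total <- sum((dat - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  ms_r <- ss_subj / (n - 1)
  ms_c <- ss_rater / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= 0)
    stop("zero variance across subjects: ICC is undefined", call. = FALSE)
  icc <- if (definition == "consistency") {
    (ms_r - ms_e) / (ms_r + ms_e)
  } else {
    (ms_r - ms_e) / (ms_r + ms_e + 2 * (ms_c - ms_e) / n)
  }
  p <- if (ms_e > 0) {
    pf(ms_r / ms_e, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else 0
  list(icc = icc, p_value = p, band = icc_band(icc),
       definition = definition,
       ms_subjects = ms_r, ms_raters = ms_c, ms_error = ms_e)
}

#' ICC interpretation band
#'
#' Classifies an ICC estimate: `"poor"` below 0.5, `"moderate"` in
#' [0.5, 0.75), `"good"` in [0.75, 0.9), `"excellent"` at or above 0.9.
#'
#' @param icc Numeric ICC estimate(s).
#' @return Character vector of band labels.
#' @examples
#' icc_band(c(0.776, 0.509))  # "good" "moderate"
#' @export
icc_band <- function(icc) {
  stopifnot(is.numeric(icc))
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as `d = y - x`. The parametric method reports
#' `bias = mean(d)` with t-based confidence intervals and limits of
#' agreement `bias +/- 1.96 sd(d)` (with the standard LoA standard error
#' `sd * sqrt(1/n + 1.96^2 / (2(n-1)))`). The nonparametric method reports
#' `bias = median(d)` with a distribution-free order-statistic confidence
#' interval and empirical 2.5th/97.5th percentile limits
#' (linear-interpolation quantiles, `type = 7`); quantile CIs use binomial
#' order-statistic bounds and are `NA` when the sample is too small to
#' bracket them.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param method `"nonparametric"` (default) or `"parametric"`.
#' @param conf_level Confidence level for the CIs. Default 0.95.
#' @return A list of class `bland_altman` with `bias`, `bias_ci`,
#'   `loa_lower`, `loa_upper`, `loa_lower_ci`, `loa_upper_ci`, `method`,
#'   `n`, and the differences `d`.
#' @export
bland_altman <- function(x, y, method = c("nonparametric", "parametric"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- y - x
  alpha <- 1 - conf_level
  if (method == "parametric") {
    bias <- mean(d)
    s <- sd(d)
    tq <- qt(1 - alpha / 2, n - 1)
    se_bias <- s / sqrt(n)
    se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
    loa_l <- bias - 1.96 * s
    loa_u <- bias + 1.96 * s
    out <- list(
      bias = bias, bias_ci = c(bias - tq * se_bias, bias + tq * se_bias),
      loa_lower = loa_l, loa_upper = loa_u,
      loa_lower_ci = c(loa_l - tq * se_loa, loa_l + tq * se_loa),
      loa_upper_ci = c(loa_u - tq * se_loa, loa_u + tq * se_loa)
    )
  } else {
    ds <- sort(d)
    out <- list(
      bias = median(d),
      bias_ci = order_stat_ci(ds, 0.5, conf_level),
      loa_lower = quantile(ds, alpha / 2, type = 7, names = FALSE),
      loa_upper = quantile(ds, 1 - alpha / 2, type = 7, names = FALSE),
      loa_lower_ci = order_stat_ci(ds, alpha / 2, conf_level),
      loa_upper_ci = order_stat_ci(ds, 1 - alpha / 2, conf_level)
    )
  }
  structure(c(out, list(method = method, n = n, d = d,
                        conf_level = conf_level)),
            class = "bland_altman")
}

# Distribution-free CI for the p-quantile from binomial order statistics;
# NA bounds when n is too small to bracket the quantile.
order_stat_ci <- function(sorted_d, p, conf_level) {
  n <- length(sorted_d)
  alpha <- 1 - conf_level
  lo <- qbinom(alpha / 2, n, p)        # largest l with P(X < l) <= alpha/2
  while (lo > 0 && pbinom(lo - 1, n, p) > alpha / 2) lo <- lo - 1
  hi <- qbinom(1 - alpha / 2, n, p) + 1  # smallest u with P(X >= u) <= alpha/2
  c(if (lo >= 1) sorted_d[lo] else NA_real_,
    if (hi <= n) sorted_d[hi] else NA_real_)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: %s> bias %.4g (%.0f%% CI %.4g to %.4g), LoA %.4g to %.4g\n",
    x$method, x$bias, 100 * x$conf_level, x$bias_ci[1], x$bias_ci[2],
    x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Ordinary least-squares fit with R-squared
#'
#' Least-squares regression of `y` on `x` with the coefficient of
#' determination `r_squared = 1 - SSE/SST`.
#'
#' @param x,y Numeric vectors, length >= 3; `x` must not be constant.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
ols_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (var(x) == 0) stop("constant x: regression is undefined", call. = FALSE)
  fit <- lm(y ~ x)
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (sst > 0) 1 - sse / sst else 0)
}

#' Method-agreement report over paired dose metrics
#'
#' Runs the four paired statistics (Wilcoxon signed-rank, two-way
#' mixed-effects ICC with interpretation band, Bland-Altman bias and limits
#' of agreement, OLS regression with R-squared) for every metric and device
#' stratum in a table of paired pre-/post-treatment dose metrics. No
#' multiple-testing adjustment is applied by default (p < 0.05 is reported
#' as-is); set `p_adjust = "holm"` to adjust across metrics within each
#' stratum. A degenerate Wilcoxon pairing (all differences zero) is flagged
#' in the `note` column rather than raised.
#'
#' @param pairs A data frame with columns `metric`, `stratum`, `value_x`
#'   and `value_y` (one row per case). Column names configurable via
#'   `x_col` / `y_col` (e.g. `value_spect` / `value_pet`).
#' @param icc_definition Passed to [icc_two_way_mixed()].
#' @param ba_method Passed to [bland_altman()].
#' @param p_adjust `"none"` (default) or a method accepted by
#'   [stats::p.adjust()] applied to the Wilcoxon p-values within strata.
#' @param x_col,y_col Names of the paired value columns.
#' @return An object of class `agreement_report`; `tidy()` returns the
#'   per-metric results tibble.
#' @export
agreement_report <- function(pairs,
                             icc_definition = "absolute_agreement",
                             ba_method = "nonparametric",
                             p_adjust = "none",
                             x_col = "value_x", y_col = "value_y") {
  stopifnot(is.data.frame(pairs),
            all(c("metric", x_col, y_col) %in% names(pairs)))
  pairs <- as_tibble(pairs)
  if (!"stratum" %in% names(pairs)) pairs$stratum <- "all"
  res <- pairs |>
    dplyr::group_by(.data$metric, .data$stratum) |>
    dplyr::group_modify(function(df, key) {
      x <- df[[x_col]]; y <- df[[y_col]]
      note <- character()
      grab <- function(expr) tryCatch(expr, error = function(e) {
        note <<- c(note, conditionMessage(e)); NULL
      })
      w_res <- grab(wilcoxon_signed_rank(x, y))
      icc_res <- grab(icc_two_way_mixed(x, y, icc_definition))
      ba_res <- grab(bland_altman(x, y, ba_method))
      reg_res <- grab(ols_r2(x, y))
      pick <- function(res, field, default = NA_real_)
        if (is.null(res)) default else res[[field]]
      tibble::tibble(
        n = length(x),
        wilcoxon_statistic = pick(w_res, "statistic"),
        wilcoxon_p = pick(w_res, "p_value"),
        icc = pick(icc_res, "icc"),
        icc_p = pick(icc_res, "p_value"),
        icc_band = pick(icc_res, "band", NA_character_),
        ba_bias = pick(ba_res, "bias"),
        ba_bias_ci_low = if (is.null(ba_res)) NA_real_ else ba_res$bias_ci[1],
        ba_bias_ci_high = if (is.null(ba_res)) NA_real_ else ba_res$bias_ci[2],
        ba_loa_lower = pick(ba_res, "loa_lower"),
        ba_loa_upper = pick(ba_res, "loa_upper"),
        slope = pick(reg_res, "slope"),
        intercept = pick(reg_res, "intercept"),
        r_squared = pick(reg_res, "r_squared"),
        note = paste(note, collapse = "; ")
      )
    }) |>
    dplyr::ungroup()
  if (p_adjust != "none") {
    res <- res |>
      dplyr::group_by(.data$stratum) |>
      dplyr::mutate(wilcoxon_p_adj = stats::p.adjust(.data$wilcoxon_p,
                                                     method = p_adjust)) |>
      dplyr::ungroup()
  }
  structure(list(results = res, icc_definition = icc_definition,
                 ba_method = ba_method, p_adjust = p_adjust, pairs = pairs,
                 x_col = x_col, y_col = y_col),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> ICC: %s; Bland-Altman: %s; p adjustment: %s\n",
              x$icc_definition, x$ba_method, x$p_adjust))
  print(x$results)
  invisible(x)
}

#' Tidy an agreement report
#'
#' @param x An [agreement_report()].
#' @param ... Unused.
#' @return `tidy()`: the per-metric, per-stratum results tibble.
#'   `glance()`: a one-row summary.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) x$results

#' @rdname tidy.agreement_report
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_metrics = dplyr::n_distinct(x$results$metric),
    n_strata = dplyr::n_distinct(x$results$stratum),
    icc_definition = x$icc_definition, ba_method = x$ba_method
  )
}
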