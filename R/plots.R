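#' Plot the cumulative DVH curves of a dose report
#'
#' @param object A [dose_report()].
#' @param roles Roles to plot (default: all in the report).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_report
#' @export
autoplot.dose_report <- function(object, roles = NULL, ...) {
  df <- object$dvh
  if (!is.null(roles)) df <- dplyr::filter(df, .data$role %in% roles)
  ggplot2::ggplot(df, ggplot2::aes(.data$dose_Gy, .data$volume_pct,
                                   colour = .data$role)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume receiving ≥ dose (%)",
                  colour = NULL,
                  title = sprintf("Cumulative DVH (%s)", object$modality)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Mean of each pair against the difference `y - x`, with the bias and the
#' limits of agreement as horizontal lines.
#'
#' @param object A [bland_altman()] result.
#' @param x_vals,y_vals The original paired values (needed for the x-axis
#'   means; defaults reconstruct means from the stored differences around
#'   zero when not supplied).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, x_vals = NULL, y_vals = NULL, ...) {
  means <- if (!is.null(x_vals) && !is.null(y_vals)) {
    (x_vals + y_vals) / 2
  } else seq_along(object$d)
  df <- tibble::tibble(mean = means, diff = object$d)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of pair", y = "Difference (y - x)",
                  title = sprintf("Bland-Altman (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Paired-metric agreement panels
#'
#' Scatter plots of the paired values per metric and stratum with the
#' identity line and the least-squares fit.
#'
#' @param object An [agreement_report()].
#' @param ... Unused.
#' @return A ggplot object faceted by metric and stratum.
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- object$pairs
  df$value_x <- df[[object$x_col]]
  df$value_y <- df[[object$y_col]]
  ggplot2::ggplot(df, ggplot2::aes(.data$value_x, .data$value_y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ metric + stratum, scales = "free") +
    ggplot2::labs(x = "SPECT-derived value", y = "PET-derived value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
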