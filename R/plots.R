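#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a meta-analysis
#'
#' Per-study estimates with 95% intervals, the pooled diamond and (when
#' defined) the prediction interval. For `proportion_meta()` results the
#' study rows are drawn on the proportion scale.
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_result <- function(object, ...) {
  z <- stats::qnorm(1 - (1 - object$level) / 2)
  est <- object$estimates
  lo <- est - z * sqrt(object$variances)
  hi <- est + z * sqrt(object$variances)
  if (object$scale == "logit") {
    est <- stats::plogis(est); lo <- stats::plogis(lo); hi <- stats::plogis(hi)
  }
  df <- tibble(label = factor(object$labels,
                              levels = rev(object$labels)),
               estimate = est, lo = lo, hi = hi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                        y = .data$label)) +
    ggplot2::geom_vline(xintercept = object$pooled,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, colour = "grey55") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(
      x = if (object$scale == "logit") "proportion" else "estimate",
      y = NULL,
      title = sprintf("Pooled %.3g [%.3g, %.3g], I² = %.0f%%",
                      object$pooled, object$ci_lower, object$ci_upper,
                      100 * object$i2)) +
    ggplot2::theme_minimal()
  if (!is.na(object$pi_lower)) {
    p <- p + ggplot2::annotate("rect", xmin = object$pi_lower,
                               xmax = object$pi_upper, ymin = -Inf,
                               ymax = Inf, alpha = 0.08, fill = "steelblue")
  }
  p
}

#' Country-level discounting score distribution
#'
#' Means with one-SD bars per country, ordered by mean score, in the style
#' of a by-country summary panel.
#'
#' @param country_summary Output of [summarize_countries()].
#' @return A ggplot object.
#' @export
plot_country_scores <- function(country_summary) {
  df <- country_summary |>
    arrange(.data$mean_score) |>
    mutate(country_id = factor(.data$country_id,
                               levels = .data$country_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_score,
                                   y = .data$country_id)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean_score - .data$sd_score,
                   xmax = .data$mean_score + .data$sd_score),
      height = 0, colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "discounting score (0-19)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-country anomaly prevalence
#'
#' Proportions of each anomaly by country as faceted bars, with the pooled
#' mean proportion marked per facet.
#'
#' @param country_summary Output of [summarize_countries()].
#' @return A ggplot object.
#' @export
plot_anomaly_prevalence <- function(country_summary) {
  prop_cols <- grep("^prop_", names(country_summary), value = TRUE)
  long <- country_summary |>
    select("country_id", dplyr::all_of(prop_cols)) |>
    tidyr::pivot_longer(-"country_id", names_to = "anomaly",
                        names_prefix = "prop_", values_to = "proportion")
  overall <- long |>
    group_by(.data$anomaly) |>
    summarise(mean_prop = mean(.data$proportion), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$proportion,
                                     y = .data$country_id)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_vline(data = overall,
                        ggplot2::aes(xintercept = .data$mean_prop),
                        colour = "steelblue") +
    ggplot2::facet_wrap(~anomaly, nrow = 1) +
    ggplot2::labs(x = "proportion with anomaly", y = NULL) +
    ggplot2::theme_minimal()
}
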