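#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot discrimination curves
#'
#' Faceted view of weighted sensitivity, specificity and PPV against the
#' risk threshold (per 1000), the standard way to read off the trade-off
#' a screening threshold implies.
#'
#' @param object An `eac_discrimination` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eac_discrimination
#' @export
autoplot.eac_discrimination <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves,
                              c("sensitivity", "specificity", "ppv"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("specificity", "sensitivity", "ppv"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1,
                        scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "10-year risk threshold (per 1000)", y = NULL,
      title = sprintf("Discrimination: AUC %.2f (%.0f%% CI %.2f-%.2f)",
                      object$auc, 100 * object$level,
                      object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a risk estimate in the context of competing mortality
#'
#' Log-scale dot plot of the individual's 10-year EAC risk (with CI)
#' alongside the demographic 10-year mortality from the comparator
#' causes — the static counterpart of a risk "thermometer".
#'
#' @param object An `eac_risk` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eac_risk
#' @export
autoplot.eac_risk <- function(object, ...) {
  comp <- object$comparator_mortality
  df <- dplyr::bind_rows(
    tibble::tibble(label = "EAC (this profile)",
                   per_1000 = 1000 * object$prob10,
                   lo = 1000 * object$ci_low, hi = 1000 * object$ci_high,
                   kind = "risk"),
    tibble::tibble(label = paste0("death: ", comp$cause),
                   per_1000 = 1000 * comp$prob10,
                   lo = NA_real_, hi = NA_real_, kind = "mortality")
  )
  df <- df[df$per_1000 > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$per_1000,
                                   y = stats::reorder(.data$label, .data$per_1000),
                                   colour = .data$kind)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "10-year probability (per 1000, log scale)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a fitted rate polynomial over its source table
#'
#' @param object A `rate_polynomial`.
#' @param table Optional source `rate_table` stratum to overlay as points.
#' @param ... Unused.
#' @return A ggplot with rates on a log scale.
#' @method autoplot rate_polynomial
#' @export
autoplot.rate_polynomial <- function(object, table = NULL, ...) {
  ages <- seq(object$age_min, object$age_max, by = 0.5)
  line <- tibble::tibble(age = ages, rate = evaluate_rate(object, ages))
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$age, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age (years)", y = "rate (per person-year, log scale)") +
    ggplot2::theme_minimal()
  if (!is.null(table)) {
    pts <- tibble::tibble(age = (table$age_lo + table$age_hi) / 2,
                          rate = table$rate)
    p <- p + ggplot2::geom_point(data = pts[pts$rate > 0, ])
  }
  p
}
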