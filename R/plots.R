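#' Plot a compliance scenario
#'
#' Stacked monthly bars of herd counts, either by SCC category of the
#' monthly adjusted geometric mean or by eligibility status.
#'
#' @param object An `scc_scenario` object.
#' @param what `"status"` (default) or `"category"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scc_scenario <- function(object, what = c("status", "category"), ...) {
  what <- match.arg(what)
  if (what == "status") {
    dat <- object$monthly_status_counts
    dat$fill_var <- dat$status
    lab <- "Eligibility status"
  } else {
    dat <- object$monthly_category_counts
    dat$fill_var <- dat$category
    lab <- "SCC category"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$month), y = .data$n_herds,
                                    fill = .data$fill_var)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Month", y = "Herds", fill = lab,
      title = sprintf("Herds by %s, %s (%s)", what, object$method, object$scenario)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a maximum non-compliance cross-tabulation
#'
#' Tile plot of the joint classification of herds with vs without the
#' seasonal adjustment; below-diagonal cells are structurally zero.
#'
#' @param object An `scc_crosstab` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scc_crosstab <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$level_without, y = .data$level_with,
                               fill = .data$n_herds)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_herds), colour = "grey20") +
    ggplot2::scale_y_discrete(limits = rev(noncompliance_levels())) +
    ggplot2::labs(x = "Max level without adjustment",
                  y = "Max level with adjustment", fill = "Herds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot monthly rolling geometric means for selected herds
#'
#' @param rolling A rolling-series tibble.
#' @param herds Optional herd ids to show (default: up to 12 herds).
#' @param thresholds Thresholds; the suspension threshold is drawn.
#' @return A ggplot object.
#' @export
plot_rolling_series <- function(rolling, herds = NULL,
                                thresholds = compliance_thresholds()) {
  if (is.null(herds)) herds <- head(unique(rolling$herd_id), 12)
  dat <- rolling %>% filter(.data$herd_id %in% herds)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$month, y = .data$rolling_geo_mean,
                                    colour = .data$herd_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = thresholds$suspension_threshold,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::labs(x = "Month", y = "3-month rolling geometric mean SCC (x1000 cells/mL)",
                  colour = "Herd") +
    ggplot2::theme_minimal()
}
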