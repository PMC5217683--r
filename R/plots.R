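# QC and result figures.

#' Plot the DNA-content histogram with the fitted mixture and G1 gate
#'
#' @param fit A [fit_hoechst_mixture()] result.
#' @param totals The Hoechst totals the mixture was fitted to.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_gate <- function(fit, totals, bins = 60) {
  df <- tibble(total = as.numeric(totals))
  grid <- tibble(x = seq(min(totals), max(totals), length.out = 400))
  dens <- map(1:2, function(k) {
    mutate(grid, component = factor(k),
           density = fit$weight[k] * dnorm(.data$x, fit$mean[k], fit$sd[k]))
  }) |> bind_rows()
  window <- c(fit$mean[1] - 2 * fit$sd[1], fit$mean[1] + 2 * fit$sd[1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = window, linetype = "dashed") +
    ggplot2::labs(x = "total nuclear Hoechst intensity (a.u.)", y = "density",
                  title = "DNA-content gate: first peak ± 2 SD") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_gate
#' @param object A `hoechst_mixture` (for `autoplot`).
#' @param ... Passed to [plot_gate()].
#' @export
autoplot.hoechst_mixture <- function(object, totals, ...) {
  plot_gate(object, totals, ...)
}

#' Plot normalised condition responses
#'
#' Mean +/- SD of the normalised (control = 0, canonical = 1) responses per
#' condition and readout channel.
#'
#' @param responses Output of [condition_response()].
#' @return A ggplot object.
#' @export
plot_responses <- function(responses) {
  ggplot2::ggplot(responses,
                  ggplot2::aes(x = .data$condition, y = .data$norm_mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$norm_mean - .data$norm_sd,
                                        ymax = .data$norm_mean + .data$norm_sd),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = NULL, y = "normalised response (control = 0, canonical = 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the crosstalk call matrix
#'
#' Tile plot of normalised effects, starred where p < alpha.
#'
#' @param calls Output of [build_crosstalk_matrix()].
#' @return A ggplot object.
#' @export
plot_crosstalk <- function(calls) {
  calls <- mutate(calls, label = ifelse(.data$significant, "*", ""))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$condition, y = .data$channel,
                                      fill = .data$norm_effect)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$type), scales = "free_x") +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "stimulating condition", y = "readout",
                  fill = "normalised\neffect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
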