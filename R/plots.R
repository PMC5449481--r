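#' Decision graph of a density-peak clustering
#'
#' Plots separation delta against local density rho; cluster centers (points
#' with simultaneously large rho and delta) are highlighted. Requires
#' ggplot2.
#'
#' @param res A `density_result`.
#' @return A ggplot object.
#' @export
plot_decision_graph <- function(res) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- data.frame(rho = res$rho, delta = res$delta,
                   center = seq_along(res$rho) %in% res$centers)
  ggplot2::ggplot(df, ggplot2::aes(x = rho, y = delta, colour = center)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = expression(rho ~ "(local density)"),
                  y = expression(delta ~ "(distance to denser point)"),
                  title = "Decision graph") +
    ggplot2::theme_minimal()
}

#' Amplitude-decay scatter of a clustered cell
#'
#' Log-log scatter of event amplitude against decay time, coloured by
#' cluster, with 2-D density contours to visualise the distribution peaks.
#'
#' @param events Event table with a `cluster` column (from [analyze_trace()])
#'   or plain events plus a `density_result` in `clustering`.
#' @param clustering Optional `density_result` supplying labels.
#' @return A ggplot object.
#' @export
plot_amplitude_decay <- function(events, clustering = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  labels <- if (!is.null(clustering)) clustering$labels
    else events$cluster %||% rep(1L, nrow(events))
  df <- data.frame(amplitude = events$amplitude_pA, decay = events$decay_ms,
                   cluster = factor(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = amplitude, y = decay)) +
    ggplot2::geom_point(ggplot2::aes(colour = cluster), alpha = 0.5) +
    ggplot2::geom_density_2d(colour = "black", linewidth = 0.3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "peak amplitude (pA)", y = "decay time (ms)") +
    ggplot2::theme_minimal()
}
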