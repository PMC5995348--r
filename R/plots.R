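# ggplot2 displays for simulation and fit objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated protocol
#'
#' Faceted traces of the canonical observables: buffer oxygen, membrane
#' potential, matrix NADH, and (when simulated) buffer rhodamine 123.
#'
#' @param object A `mito_sim`.
#' @param vars State columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_sim <- function(object,
                              vars = c("O2.e", "dPsi", "NADH.m", "R123.e"),
                              ...) {
  tr <- object$trajectory
  vars <- intersect(vars, names(tr))
  long <- tidyr::pivot_longer(tr[c("time", vars)], -"time",
                              names_to = "state", values_to = "value")
  labs <- c(O2.e = "buffer O2 (mM)", dPsi = "deltaPsi (mV)",
            NADH.m = "matrix NADH (mM)", R123.e = "buffer R123 (M)")
  long$state <- factor(long$state, levels = vars,
                       labels = ifelse(vars %in% names(labs),
                                       labs[vars], vars))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10)
  ev <- object$events
  if (!is.null(ev) && nrow(ev))
    p <- p + ggplot2::geom_vline(data = ev,
                                 ggplot2::aes(xintercept = .data$time),
                                 linetype = 3, colour = "grey40")
  p
}

#' Plot the convergence history of a GA fit
#'
#' @param object A `mito_fit`.
#' @param ... Unused.
#' @return A ggplot object: best objective per generation (log scale).
#' @export
autoplot.mito_fit <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$history),
                       best = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$best)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best objective (log10)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Heat-map display of a parameter correlation matrix
#'
#' @param CC Matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(CC) {
  df <- as.data.frame(as.table(CC))
  names(df) <- c("pi", "pj", "cc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pi, y = .data$pj,
                                   fill = .data$cc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "CC") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
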