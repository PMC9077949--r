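#' Plot a delivery timeline
#'
#' Gantt-style view of the delivery events: one horizontal segment per
#' event, colored by event kind, stacked by layer.
#'
#' @param object A `pbs_timeline`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbs_timeline <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$layer_lab <- factor(df$layer_index, levels = sort(unique(df$layer_index)))
  ggplot2::ggplot(df, ggplot2::aes(
    xmin = .data$start_ms / 1000,
    xmax = (.data$start_ms + .data$duration_ms) / 1000,
    ymin = as.integer(.data$layer_lab) - 0.4,
    ymax = as.integer(.data$layer_lab) + 0.4,
    fill = .data$kind
  )) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(df$layer_lab)),
                                labels = levels(df$layer_lab)) +
    ggplot2::labs(x = "time (s)", y = "energy layer", fill = "event",
                  title = "Delivery timeline") +
    ggplot2::theme_minimal()
}

#' Plot the D99 spread of an interplay evaluation
#'
#' One point per starting phase with the static (no motion) reference as a
#' dashed line; pass several results to [plot_interplay_comparison()] for
#' the boxplot comparison across machines and repainting numbers.
#'
#' @param object An `interplay_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interplay_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_phase, y = .data$d99)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "static_d99"),
                        linetype = "dashed") +
    ggplot2::labs(x = "starting phase", y = "target D99 (MU)",
                  title = sprintf("Interplay: %s, N_vol = %d",
                                  attr(object, "machine_label"),
                                  attr(object, "n_repaint"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.interplay_result
#' @param results A named list of `interplay_result` objects.
#' @export
plot_interplay_comparison <- function(results) {
  df <- dplyr::bind_rows(lapply(names(results), function(nm) {
    dplyr::mutate(tibble::as_tibble(results[[nm]]), scenario = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$d99)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "target D99 (MU)",
                  title = "Interplay D99 across starting phases") +
    ggplot2::theme_minimal()
}

#' Plot the spot-switching time models
#'
#' The fast-axis (modified softplus) and slow-axis (three-piece) switching
#' curves over a distance range.
#'
#' @inheritParams critical_interval
#' @param max_distance Upper distance, mm.
#' @return A ggplot.
#' @export
plot_switching_models <- function(machine = proteus_one(),
                                  max_distance = 250) {
  d <- seq(0, max_distance, by = 0.5)
  df <- dplyr::bind_rows(
    tibble::tibble(distance_mm = d, axis = "x (fast)",
                   time_ms = xswitch_time(d, machine)),
    tibble::tibble(distance_mm = d, axis = "y (slow)",
                   time_ms = yswitch_time(d, machine))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm, y = .data$time_ms,
                                   color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "scan distance (mm)", y = "switching time (ms)",
                  color = "axis", title = "Spot-switching time models") +
    ggplot2::theme_minimal()
}
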