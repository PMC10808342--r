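#' Plot recall errors with the fitted mixture density
#'
#' Histogram of signed recall errors (optionally faceted by condition)
#' with the fitted uniform + von Mises mixture density overlaid.
#'
#' @param trials Tibble with `error_deg` (and `condition` for faceting).
#' @param fit Optional `mixture_fit` whose density to overlay.
#' @param by_condition Facet by condition?
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(trials, fit = NULL,
                                    by_condition = FALSE) {
  p <- ggplot2::ggplot(trials, ggplot2::aes(x = .data$error_deg)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      breaks = seq(-180, 180, by = 12),
      fill = "grey75", colour = "grey40") +
    ggplot2::labs(x = "recall error (deg)", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(error_deg = seq(-180, 180, length.out = 361))
    # density per degree = density per radian * pi / 180
    grid$density <- ((1 - fit$p_u) *
                       vonmises_density(deg2rad(grid$error_deg), fit$kappa) +
                       fit$p_u / (2 * pi)) * pi / 180
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = .data$density),
                                colour = "orange", linewidth = 1)
  }
  if (by_condition) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' @export
autoplot.mixture_fit <- function(object, ...) {
  grid <- tibble::tibble(error_deg = seq(-180, 180, length.out = 361))
  grid$density <- ((1 - object$p_u) *
                     vonmises_density(deg2rad(grid$error_deg), object$kappa) +
                     object$p_u / (2 * pi)) * pi / 180
  ggplot2::ggplot(grid, ggplot2::aes(.data$error_deg, .data$density)) +
    ggplot2::geom_line(colour = "orange", linewidth = 1) +
    ggplot2::labs(x = "recall error (deg)", y = "density",
                  title = sprintf("p_t = %.2f, kappa = %.1f",
                                  object$p_t, object$kappa)) +
    ggplot2::theme_minimal()
}

#' Plot a single-trial pupil trace with event markers
#'
#' @param traces Long trace tibble.
#' @param events Marker table (one row per trial).
#' @param participant,trial Which trial to show.
#' @return A ggplot object.
#' @export
plot_pupil_trace <- function(traces, events, participant, trial) {
  tr <- dplyr::filter(traces, .data$participant == !!participant,
                      .data$trial_index == !!trial)
  ev <- dplyr::filter(events, .data$participant == !!participant,
                      .data$trial_index == !!trial)
  marks <- tibble::tibble(
    event = c("item onset", "choice onset", "anticipation on",
              "anticipation off"),
    t_s = c(ev$item_onset_s, ev$choice_onset_s, ev$anticip_onset_s,
            ev$anticip_offset_s)
  )
  ggplot2::ggplot(tr, ggplot2::aes(.data$t_s, .data$diameter_mm)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(data = dplyr::filter(tr, !.data$valid),
                        ggplot2::aes(y = min(tr$diameter_mm, na.rm = TRUE)),
                        colour = "red", shape = 4, na.rm = TRUE) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$t_s),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "pupil diameter (mm)") +
    ggplot2::theme_minimal()
}

#' Condition means with participant lines for an epoch measure
#'
#' @param epochs Epoch tibble from [extract_epochs()].
#' @param measure Column to summarise (string), e.g. `"anticip_change_mm"`.
#' @return A ggplot object.
#' @export
plot_condition_means <- function(epochs, measure = "anticip_change_mm") {
  means <- epochs |>
    dplyr::filter(is.finite(.data[[measure]])) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(value = mean(.data[[measure]]), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       colour = "grey70") +
    ggplot2::geom_point(colour = "grey50") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "black") +
    ggplot2::labs(x = NULL, y = measure) +
    ggplot2::theme_minimal()
}
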