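# ggplot2 displays for runs, load-response curves, and fits -------------------

#' Plot the main diagnostics of a run
#'
#' Time series of chlorophyll a, total P, macrophyte coverage and surface
#' oxygen.
#'
#' @param object A `lake_run`.
#' @param variables Diagnostics to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lake_run <- function(object, variables = c("chl", "tp", "cover",
                                                    "o2_surf"), ...) {
  d <- tidy(object) |> dplyr::filter(.data$variable %in% variables)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day / 365, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot load-response curves
#'
#' One panel per response variable, external P load on the x axis, one
#' curve per branch — the standard bifurcation display for critical-load
#' analysis.
#'
#' @param object A `load_response` tibble.
#' @param variables Response variables to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.load_response <- function(object, variables = c("chl", "cover",
                                                         "tp",
                                                         "depth_limit_aug_m"),
                                   ...) {
  d <- object |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$load_p_mg_m2_d, y = .data$value,
                                  colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "external P load (mg P m⁻² d⁻¹)",
                  y = NULL, colour = "branch") +
    ggplot2::theme_minimal()
}

#' Observed versus simulated values
#'
#' @param run A `lake_run`.
#' @param obs An `observation_set`.
#' @param variables Variables to display.
#' @return A ggplot of paired time series.
#' @export
plot_fit <- function(run, obs, variables = unique(obs$variable)) {
  matched <- depth_matched_extract(run, obs) |>
    dplyr::filter(.data$variable %in% variables)
  ggplot2::ggplot(matched, ggplot2::aes(x = .data$day / 365)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim), colour = "black",
                       linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), colour = "grey40",
                        size = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal()
}
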