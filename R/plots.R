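#' Plot methods
#'
#' `autoplot.q10_fit()` shows the flux-temperature scatter with the fitted
#' exponential response; `autoplot.closure_qc()` shows a sample of closure
#' concentration traces with rejected records highlighted (the visual QC
#' check applied to automated chamber data); `plot_flux_series()` draws
#' hourly treatment-mean efflux through time.
#'
#' @param object Fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name chamberflux-plots
NULL

#' @rdname chamberflux-plots
#' @export
autoplot.q10_fit <- function(object, ...) {
  d <- object$fit$model
  grid <- data.frame(t = seq(min(d$t), max(d$t), length.out = 200))
  grid$flux <- predict(object, grid$t)
  ggplot2::ggplot(data.frame(t = d$t, flux = exp(d$lf)),
                  ggplot2::aes(x = .data$t, y = .data$flux)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "Soil temperature at 5 cm (°C)",
      y = expression("Soil CO"[2] * " efflux (" * mu * "mol m"^-2 * " s"^-1 * ")"),
      title = sprintf("Q10 = %.2f (flux at %.0f °C: %.2f)",
                      object$q10, object$t_ref, object$r_ref)
    ) +
    ggplot2::theme_minimal()
}

#' @param n_closures Number of closures to display (sampled evenly).
#' @rdname chamberflux-plots
#' @export
autoplot.closure_qc <- function(object, n_closures = 6, ...) {
  ids <- unique(object$closures$closure)
  ids <- ids[unique(round(seq(1, length(ids), length.out = n_closures)))]
  rec <- dplyr::filter(object$records, .data$closure %in% ids) %>%
    dplyr::mutate(
      status = ifelse(.data$qc_keep, "retained",
                      dplyr::coalesce(.data$qc_reason, "rejected")),
      label = paste0("ch ", .data$chamber, " @ ",
                     format(floor_hour(.data$timestamp), "%m-%d %H:00"))
    )
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$offset_s, y = .data$co2_ppm,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "Time since lid closure (s)",
                  y = expression("CO"[2] * " (ppm)"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @param fluxes Flux table from [compute_fluxes()].
#' @rdname chamberflux-plots
#' @export
plot_flux_series <- function(fluxes, ...) {
  h <- fluxes %>%
    dplyr::filter(.data$usable) %>%
    dplyr::mutate(hour = floor_hour(.data$time)) %>%
    dplyr::group_by(.data$hour, .data$treatment) %>%
    dplyr::summarise(flux = mean(.data$flux), .groups = "drop")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$hour, y = .data$flux,
                                  colour = .data$treatment)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = NULL,
      y = expression("Soil CO"[2] * " efflux (" * mu * "mol m"^-2 * " s"^-1 * ")"),
      colour = "Treatment"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
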