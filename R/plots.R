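#' Plot a simulated trajectory
#'
#' Total adults and wild-type females over time, one panel per deme, with
#' the pre-release equilibrium marked.  Wild-type females matter because,
#' with a fully dominant refractory cargo, they are the only individuals
#' able to transmit pathogens.
#'
#' @param object A `drive_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drive_sim <- function(object, ...) {
  dat <- population_series(object) %>%
    tidyr::pivot_longer(c("total", "wt_female"), names_to = "series",
                        values_to = "count") %>%
    mutate(series = dplyr::recode(.data$series, total = "all adults",
                                  wt_female = "wild-type females"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$t, .data$count,
                                    colour = .data$series)) +
    ggplot2::geom_hline(yintercept = object$N_star, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~deme, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time since release (days)", y = "adult mosquitoes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a threshold scan
#'
#' @param object A `drive_scan`.
#' @param ... Unused.
#' @return A ggplot: criterion outcome over the (theta, eps) grid, with the
#'   refined threshold curve overlaid when present.
#' @export
autoplot.drive_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(.data$theta, .data$eps,
                                    fill = .data$criterion_met)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "release ratio (theta)",
                  y = "relative fitness per construct (eps)",
                  fill = "drives") +
    ggplot2::theme_minimal()
  if (any(!is.na(object$thresholds$eps_star))) {
    p <- p + ggplot2::geom_line(
      data = object$thresholds,
      ggplot2::aes(.data$theta, .data$eps_star),
      inherit.aes = FALSE, colour = "black"
    )
  }
  p
}
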