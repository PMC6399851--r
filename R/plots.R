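#' Plot a payload trajectory
#'
#' Concentration-versus-time curves for the three payload compartments
#' and their intracellular total.
#'
#' @param object A `payload_trajectory` from [simulate_payload()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.payload_trajectory <- function(object, ...) {
  long <- tidy.bystandr_trajectory(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (days)", y = "payload concentration (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a tumor growth inhibition trajectory
#'
#' Tumor size curves for the Ag+ (`T1`), Ag- (`T2`) and total
#' compartments.
#'
#' @param object A `tgi_trajectory` or `age_trajectory`.
#' @param normalized If `TRUE`, plot the percent change relative to each
#'   compartment's initial size instead of absolute sizes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tgi_trajectory <- function(object, normalized = FALSE, ...) {
  df <- as_tibble(as.data.frame(object))[, c("time_days", "T1", "T2", "T_total")]
  ylab <- "tumor size (mm^3)"
  if (normalized) {
    for (cl in c("T1", "T2", "T_total")) {
      df[[cl]] <- normalized_percent_change(df[[cl]], df[[cl]][1])
    }
    ylab <- "change from initial size (%)"
  }
  long <- tidyr::pivot_longer(df, cols = -"time_days",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_days, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (days)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tgi_trajectory
#' @export
autoplot.age_trajectory <- autoplot.tgi_trajectory

#' Plot a bystander-killing suppression gap
#'
#' The difference between bystander-off and bystander-on total tumor
#' size, relative to the initial tumor size, as produced by
#' [bystander_gap()] or the paired figure sweeps. A `beta` column, if
#' present, maps to colour.
#'
#' @param gap Tibble with `time_days`, `gap_pct` and optionally `beta`.
#' @return A ggplot object.
#' @export
plot_bystander_gap <- function(gap) {
  stopifnot(is.data.frame(gap),
            all(c("time_days", "gap_pct") %in% names(gap)))
  aes <- if ("beta" %in% names(gap)) {
    ggplot2::aes(x = .data$time_days, y = .data$gap_pct,
                 colour = factor(.data$beta))
  } else {
    ggplot2::aes(x = .data$time_days, y = .data$gap_pct)
  }
  ggplot2::ggplot(gap, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (days)",
                  y = "extra suppression by bystander killing (% of T0)",
                  colour = "Ag+ fraction") +
    ggplot2::theme_minimal()
}

#' Plot a payload parameter sweep
#'
#' Faceted payload curves from the `"fig2"` sweep of [run_figure()]:
#' one facet per efflux ratio `k`, coloured by the Ag+ fraction.
#'
#' @param sweep Tibble from `run_figure("fig2")`.
#' @param series Which concentration column to show.
#' @return A ggplot object.
#' @export
plot_payload_sweep <- function(sweep,
                               series = c("C_int_p", "C_int_n",
                                          "total_intracellular", "C_ext_p")) {
  series <- match.arg(series)
  stopifnot(is.data.frame(sweep),
            all(c("time_days", "k", "beta", series) %in% names(sweep)))
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$time_days, y = .data[[series]],
                               colour = factor(.data$beta))) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$k),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (days)", y = paste(series, "(nM)"),
                  colour = "Ag+ fraction") +
    ggplot2::theme_minimal()
}
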